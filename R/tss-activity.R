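#' Normalize TSS tag counts to tags per million (TPM)
#'
#' TPM is the tag count scaled to a library total of one million:
#' \code{tpm[t, s] = counts[t, s] / total[s] * 1e6}. Library totals default
#' to the matrix column sums (in which case every column of the result sums
#' to 1e6); pass genome-wide library sizes via \code{totals} when the matrix
#' covers only a locus. An optional median-of-ratios scaling-factor
#' adjustment (in the spirit of relative-log-expression normalization) can
#' be applied on top with \code{method = "rle"}.
#'
#' @param counts Non-negative integer matrix, TSSs in rows, samples in
#'   columns.
#' @param totals Optional named numeric vector of per-sample library totals.
#' @param method "per-million" (default) or "rle" (per-million divided by
#'   each sample's median ratio to the row-geometric-mean reference,
#'   computed over rows positive in all samples).
#' @return Numeric matrix of TPM values, same dimensions as \code{counts}.
#' @export
tpmNormalize <- function(counts, totals = NULL, method = c("per-million", "rle")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("normalization error: negative counts")
  if (is.null(totals)) {
    totals <- colSums(counts)
  } else {
    if (!is.null(names(totals)) && !is.null(colnames(counts)))
      totals <- totals[colnames(counts)]
    if (length(totals) != ncol(counts))
      stop("normalization error: totals do not match samples")
  }
  zero <- which(totals <= 0)
  if (length(zero)) {
    nm <- if (!is.null(colnames(counts))) colnames(counts)[zero[1]] else zero[1]
    stop(sprintf("normalization error: sample '%s' has zero library total", nm))
  }
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  if (method == "rle") {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (any(pos)) {
      ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
      sf <- apply(sweep(counts[pos, , drop = FALSE], 1, ref, "/"), 2, stats::median)
      sf <- sf / exp(mean(log(sf)))
      tpm <- sweep(tpm, 2, sf, "/")
    }
  }
  tpm
}

#' Summarize TSS activity per sample group
#'
#' Per (TSS, group): arithmetic mean TPM, standard error of the mean
#' (sample standard deviation with n-1 denominator divided by sqrt(n); 0
#' when n = 1), and the number of samples.
#'
#' @param tpm TPM matrix (TSSs x samples).
#' @param meta data.frame with columns \code{sample} and \code{group}
#'   covering every column of \code{tpm}.
#' @return data.frame with columns tss, group, mean_tpm, se, n.
#' @export
summarizeActivity <- function(tpm, meta) {
  tpm <- as.matrix(tpm)
  missing <- setdiff(colnames(tpm), meta$sample)
  if (length(missing))
    stop(sprintf("metadata error: sample(s) without group: %s",
                 paste(missing, collapse = ", ")))
  groups <- meta$group[match(colnames(tpm), meta$sample)]
  out <- list()
  for (g in unique(groups)) {
    sub <- tpm[, groups == g, drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    se <- if (n == 1) rep(0, nrow(sub)) else apply(sub, 1, stats::sd) / sqrt(n)
    out[[g]] <- data.frame(tss = rownames(tpm), group = g, mean_tpm = m,
                           se = se, n = n, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Rank TSSs by mean activity within a group
#'
#' Descending by mean TPM; ties broken by ascending genomic position, then
#' lexicographic TSS id, so the ordering is deterministic and stable under
#' shuffling of the input.
#'
#' @param summaries data.frame as produced by \code{\link{summarizeActivity}}
#'   (or the packaged activity table).
#' @param group Group name to rank within.
#' @param positions Optional named vector of TSS positions for tie-breaking.
#' @return data.frame (tss, mean_tpm) sorted by rank; zero rows if the
#'   group is absent.
#' @export
rankTss <- function(summaries, group, positions = NULL) {
  sub <- summaries[summaries$group == group, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(tss = character(0), mean_tpm = numeric(0)))
  pos <- if (is.null(positions)) rep(NA_real_, nrow(sub)) else
    as.numeric(positions[sub$tss])
  o <- order(-sub$mean_tpm, pos, sub$tss)
  data.frame(tss = sub$tss[o], mean_tpm = sub$mean_tpm[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign positioned TSSs to named, non-overlapping features
#'
#' Each positioned TSS receives the label of the unique feature containing
#' it, or "unassigned". Records without a position keep their existing
#' label (a warning notes how many were skipped).
#'
#' @param tss TSS record table (columns tss_id, chrom, pos, ue) or the
#'   \code{DataFrame} from \code{\link{tssRecords}}.
#' @param features Named \code{GRanges}; must be mutually non-overlapping.
#' @return The table with an added/updated \code{assigned} column.
#' @export
assignTssToFeatures <- function(tss, features) {
  if (length(features) > 1) {
    ov <- GenomicRanges::findOverlaps(features, drop.self = TRUE)
    if (length(ov))
      stop("configuration error: features overlap; containment would be ambiguous")
  }
  tss <- as.data.frame(tss)
  assigned <- if (!is.null(tss$ue)) as.character(tss$ue) else
    rep("unassigned", nrow(tss))
  has_pos <- !is.na(tss$pos)
  if (any(!has_pos))
    warning(sprintf("%d TSS record(s) without position keep their prior label",
                    sum(!has_pos)))
  if (any(has_pos)) {
    gr <- GenomicRanges::GRanges(tss$chrom[has_pos],
                                 IRanges::IRanges(tss$pos[has_pos], tss$pos[has_pos]))
    hits <- GenomicRanges::findOverlaps(gr, features)
    lab <- rep("unassigned", sum(has_pos))
    lab[S4Vectors::queryHits(hits)] <- names(features)[S4Vectors::subjectHits(hits)]
    assigned[has_pos] <- lab
  }
  tss$assigned <- assigned
  tss
}
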