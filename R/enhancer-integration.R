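#' Corroborate enhancer candidates across independent call sets
#'
#' For each candidate from the origin set, support is the set of sources
#' with at least one call overlapping it by \code{min_overlap} bp (any-bp by
#' default; presence/absence, not reciprocal fraction). The origin source is
#' always part of its own support.
#'
#' @param candidates \code{GRanges} of candidate enhancers (the origin
#'   set's calls).
#' @param callSets Named list of \code{GRanges}, one per source (should
#'   include the origin under \code{origin} name).
#' @param origin Name of the origin source.
#' @param min_overlap Minimum shared bp to count as support (default 1).
#' @param hc_threshold Support count at or above which a candidate is
#'   labelled high-confidence; defaults to the number of human sources.
#' @return The candidates with metadata columns \code{support}
#'   (CharacterList), \code{support_count}, \code{origin} and
#'   \code{high_confidence}.
#' @export
corroborate <- function(candidates, callSets, origin = names(callSets)[1],
                        min_overlap = 1, hc_threshold = NULL) {
  if (length(callSets) < 1) stop("at least one call set is required")
  if (is.null(hc_threshold)) {
    species <- vapply(callSets, function(s) {
      sp <- S4Vectors::metadata(s)$species
      if (is.null(sp)) "human" else sp
    }, character(1))
    hc_threshold <- sum(species == "human")
  }
  hit_mat <- vapply(callSets, function(calls) {
    if (length(calls) == 0) return(rep(FALSE, length(candidates)))
    IRanges::overlapsAny(candidates, calls, minoverlap = min_overlap,
                         ignore.strand = TRUE)
  }, logical(length(candidates)))
  hit_mat <- matrix(hit_mat, nrow = length(candidates),
                    dimnames = list(NULL, names(callSets)))
  # when candidates are the origin's own calls, the origin is in its own
  # support by construction (a call overlaps itself)
  support <- lapply(seq_along(candidates), function(i)
    sort(names(callSets)[hit_mat[i, ]]))
  out <- GenomicRanges::granges(candidates)
  if (!is.null(candidates$name)) out$name <- candidates$name
  out$support <- IRanges::CharacterList(support)
  out$support_count <- lengths(support)
  out$origin <- origin
  out$high_confidence <- out$support_count >= hc_threshold
  out
}

#' Classify enhancer proximity to the gene's coding sequence
#'
#' Distance is the minimum gap in bp between the candidate and the CDS span
#' (0 when they overlap or directly abut). Categories by thresholds:
#' distance <= \code{near} is "near", <= \code{far} is "intermediate",
#' otherwise "far".
#'
#' @param candidates \code{GRanges} of enhancer candidates.
#' @param geneModel A \code{\link{GeneModel}}.
#' @param near,far Thresholds in bp, \code{0 < near <= far}
#'   (defaults 300 kb / 700 kb).
#' @return Candidates with added \code{distance_bp} and \code{proximity}
#'   columns.
#' @export
classifyProximity <- function(candidates, geneModel, near = 3e5, far = 7e5) {
  stopifnot(near > 0, near <= far)
  cds <- cdsSpan(geneModel)
  same <- as.character(GenomicRanges::seqnames(candidates)) ==
    as.character(GenomicRanges::seqnames(cds))
  if (any(!same))
    stop("distance undefined error: candidate(s) on a different chromosome from the CDS")
  d <- GenomicRanges::distance(candidates, cds, ignore.strand = TRUE)
  candidates$distance_bp <- d
  candidates$proximity <- ifelse(d <= near, "near",
                                 ifelse(d <= far, "intermediate", "far"))
  candidates
}

#' Link enhancers to promoters through chromatin-interaction anchors
#'
#' A link (promoter, enhancer, cell type) is created when at least one loop
#' of that cell type has one anchor overlapping the promoter and the other
#' overlapping the enhancer, in either anchor orientation. Output ordering
#' is deterministic: by promoter name, enhancer position, cell type.
#'
#' @param loops \code{Pairs} of anchors with \code{cell_type} and
#'   \code{loop_id} metadata (cis-only).
#' @param promoters Named \code{GRanges} of promoter regions.
#' @param candidates \code{GRanges} of enhancer candidates.
#' @param min_overlap Minimum anchor overlap in bp (default 1).
#' @return data.frame with columns promoter, enh_chrom, enh_start, enh_end,
#'   cell_type, n_loops, loop_ids.
#' @export
linkInteractions <- function(loops, promoters, candidates, min_overlap = 1) {
  empty <- data.frame(promoter = character(0), enh_chrom = character(0),
                      enh_start = integer(0), enh_end = integer(0),
                      cell_type = character(0), n_loops = integer(0),
                      loop_ids = character(0), stringsAsFactors = FALSE)
  if (length(loops) == 0 || length(promoters) == 0 || length(candidates) == 0)
    return(empty)
  a <- S4Vectors::first(loops)
  b <- S4Vectors::second(loops)
  m <- S4Vectors::mcols(loops)
  ovw <- function(x, y) {
    # per-pair overlap width >= min_overlap, x recycled over loops
    hit <- matrix(FALSE, length(x), length(y))
    for (j in seq_along(y)) {
      w <- pmin(GenomicRanges::end(x), GenomicRanges::end(y[j])) -
        pmax(GenomicRanges::start(x), GenomicRanges::start(y[j])) + 1
      samechr <- as.character(GenomicRanges::seqnames(x)) ==
        as.character(GenomicRanges::seqnames(y[j]))
      hit[, j] <- samechr & w >= min_overlap
    }
    hit
  }
  pa <- ovw(a, promoters); pb <- ovw(b, promoters)
  ea <- ovw(a, candidates); eb <- ovw(b, candidates)
  rows <- list()
  for (p in seq_along(promoters)) {
    for (e in seq_along(candidates)) {
      supp <- (pa[, p] & eb[, e]) | (pb[, p] & ea[, e])
      if (!any(supp)) next
      cells <- m$cell_type[supp]
      for (ct in sort(unique(cells))) {
        ids <- m$loop_id[supp & m$cell_type == ct]
        rows[[length(rows) + 1]] <- data.frame(
          promoter = names(promoters)[p],
          enh_chrom = as.character(GenomicRanges::seqnames(candidates[e])),
          enh_start = GenomicRanges::start(candidates[e]),
          enh_end = GenomicRanges::end(candidates[e]),
          cell_type = ct, n_loops = length(ids),
          loop_ids = paste(ids, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$promoter, out$enh_start, out$cell_type), , drop = FALSE]
}

#' Tabulate promoter-enhancer links by cell type
#'
#' Complete table over all (cell type, promoter) pairs, zero-filled where no
#' link exists.
#'
#' @param links data.frame from \code{\link{linkInteractions}}.
#' @param cell_types,promoters Row/column universes; default to the values
#'   present in \code{links}.
#' @return Integer matrix, cell types in rows, promoters in columns, values
#'   = number of linked enhancer candidates.
#' @export
linkTableByCellType <- function(links, cell_types = NULL, promoters = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(links$cell_type))
  if (is.null(promoters)) promoters <- sort(unique(links$promoter))
  tab <- matrix(0L, length(cell_types), length(promoters),
                dimnames = list(cell_types, promoters))
  if (nrow(links)) {
    for (i in seq_len(nrow(links))) {
      ct <- links$cell_type[i]; p <- links$promoter[i]
      if (ct %in% cell_types && p %in% promoters)
        tab[ct, p] <- tab[ct, p] + 1L
    }
  }
  tab
}
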