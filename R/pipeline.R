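#' Run the end-to-end locus integration
#'
#' Orchestrates the full analysis over an evidence catalogue: promoter
#' derivation (or, when the catalogue carries no constraint track, the
#' packaged reference promoter annotation, with a logged note that
#' algorithmic derivation was skipped), TSS activity summarization and
#' ranking (from the counts matrix when present, otherwise the catalogue's
#' pre-computed summaries), enhancer corroboration and proximity
#' classification, interaction linking, and the cell-type link table.
#' Outputs are written as plain-text tracks plus a machine-readable JSON
#' report; re-running over the same inputs reproduces identical bytes
#' except for the provenance timestamp.
#'
#' @param catalogue An \code{\link{EvidenceCatalogue}}, or a directory to
#'   load one from.
#' @param out_dir Output directory (created if needed); \code{NULL} skips
#'   file output.
#' @param params \code{\link{derivationParams}} for promoter derivation.
#' @param near,far Proximity thresholds in bp.
#' @param min_overlap Minimum overlap (bp) for corroboration and anchor
#'   matching.
#' @param origin Origin enhancer source; defaults to the catalogue's first
#'   set.
#' @param verbose Log progress to stderr.
#' @return Invisibly, the report: a list with promoters, activity,
#'   rankings, enhancers, links, link_table and provenance.
#' @export
runPipeline <- function(catalogue, out_dir = NULL,
                        params = derivationParams(),
                        near = 3e5, far = 7e5, min_overlap = 1,
                        origin = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[regulocus] ", sprintf(...))
  if (is.character(catalogue)) {
    if (!dir.exists(catalogue))
      stop(sprintf("configuration error: catalogue directory '%s' does not exist",
                   catalogue))
    say("loading catalogue from %s", catalogue)
    catalogue <- loadCatalogue(catalogue)
  }
  viol <- validateCatalogue(catalogue)
  if (length(viol))
    stop(sprintf("stage 'validate' failed: %s", paste(viol, collapse = "; ")))

  ## promoters
  if (!is.null(constraintTrack(catalogue))) {
    say("deriving promoter regions from the constraint track")
    promoters <- deriveAll(catalogue, params)
  } else if (!is.null(promotersRef(catalogue))) {
    say("no constraint track in catalogue: reporting the packaged reference promoter annotation (algorithmic derivation skipped)")
    promoters <- promotersRef(catalogue)
    promoters$name <- names(promoters)
  } else {
    stop("stage 'promoters' failed: neither a constraint track nor a reference annotation is available")
  }

  ## activity
  counts <- tssCounts(catalogue)
  if (!is.null(counts)) {
    say("normalizing %d x %d count matrix to TPM", nrow(counts), ncol(counts))
    meta <- sampleMeta(catalogue)
    totals <- if (!is.null(meta$lib_total))
      stats::setNames(meta$lib_total, meta$sample) else NULL
    tpm <- tpmNormalize(counts, totals = totals)
    activity <- summarizeActivity(tpm, meta)
  } else if (!is.null(activitySummaries(catalogue))) {
    say("no counts in catalogue: passing through packaged activity summaries")
    activity <- activitySummaries(catalogue)
  } else {
    activity <- NULL
  }
  rankings <- NULL
  if (!is.null(activity)) {
    tssdf <- as.data.frame(tssRecords(catalogue))
    pos <- stats::setNames(tssdf$pos, tssdf$tss_id)
    rankings <- lapply(stats::setNames(nm = unique(activity$group)),
                       function(g) rankTss(activity, g, positions = pos))
  }

  ## enhancers
  sets <- enhancerSets(catalogue)
  enhancers <- NULL
  if (length(sets)) {
    if (is.null(origin)) origin <- names(sets)[1]
    say("corroborating %d '%s' calls across %d sources",
        length(sets[[origin]]), origin, length(sets))
    enhancers <- corroborate(sets[[origin]], sets, origin = origin,
                             min_overlap = min_overlap)
    enhancers <- classifyProximity(enhancers, catGeneModel(catalogue),
                                   near = near, far = far)
  }

  ## links
  loops <- loopRecords(catalogue)
  links <- linkInteractions(loops, promoters,
                            if (is.null(enhancers)) GenomicRanges::GRanges()
                            else enhancers,
                            min_overlap = min_overlap)
  cell_types <- if (length(loops))
    sort(unique(S4Vectors::mcols(loops)$cell_type)) else character(0)
  link_table <- linkTableByCellType(links, cell_types = cell_types,
                                    promoters = names(promoters))

  report <- list(
    promoters = promoters, activity = activity, rankings = rankings,
    enhancers = enhancers, links = links, link_table = link_table,
    provenance = list(
      package = "regulocus",
      version = as.character(utils::packageVersion("regulocus")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      params = unclass(params),
      thresholds = list(near = near, far = far, min_overlap = min_overlap)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    say("writing outputs to %s", out_dir)
    pb <- GenomicRanges::granges(promoters)
    pb$name <- promoters$name
    if (!is.null(promoters$n_bins)) pb$score <- promoters$n_bins
    writeBed(pb, file.path(out_dir, "promoters.bed"))
    if (!is.null(activity))
      utils::write.table(activity, file.path(out_dir, "activity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enhancers)) {
      edf <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(enhancers)),
        start = GenomicRanges::start(enhancers),
        end = GenomicRanges::end(enhancers),
        name = if (!is.null(enhancers$name)) enhancers$name else
          sprintf("enh%02d", seq_along(enhancers)),
        support = vapply(enhancers$support, paste, character(1), collapse = ","),
        support_count = enhancers$support_count,
        high_confidence = enhancers$high_confidence,
        distance_bp = enhancers$distance_bp,
        proximity = enhancers$proximity)
      utils::write.table(edf, file.path(out_dir, "enhancers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(links, file.path(out_dir, "links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json <- list(
      promoters = toExternal(promoters),
      link_table = as.data.frame.table(link_table,
                                       responseName = "n_links"),
      provenance = report$provenance)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
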