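.findFile <- function(dir, candidates, required = TRUE) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  if (required)
    stop(sprintf("catalogue load error: none of [%s] found in %s",
                 paste(candidates, collapse = ", "), dir))
  NULL
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' Read a gene model from BED12 plus a UE naming table
#'
#' Exons are reconstructed from the BED12 blocks; an exon is flagged
#' translated when it overlaps the thick (CDS) region. The UE table names
#' the untranslated first exons (1-based inclusive coordinates) so they can
#' be referenced by the rest of the evidence.
#'
#' @param bed12_path Path to a BED12 file of reference transcripts.
#' @param ues_path Path to a TSV with columns name, chrom, start, end.
#' @param geneName Gene symbol for the model.
#' @return A \code{\link{GeneModel}}.
#' @export
readGeneModel <- function(bed12_path, ues_path, geneName = "gene") {
  tx <- rtracklayer::import(bed12_path, format = "BED")
  if (length(tx) == 0) stop("catalogue load error: empty gene model BED12")
  strand_ <- as.character(GenomicRanges::strand(tx))[1]
  exlist <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    blocks <- tx$blocks[[i]]
    ex <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(tx)[i],
      IRanges::shift(blocks, GenomicRanges::start(tx)[i] - 1L)
    )
    thick <- tx$thick[i]
    ex$translated <- IRanges::overlapsAny(
      IRanges::ranges(ex), thick
    )
    exlist[[i]] <- ex
  }
  names(exlist) <- tx$name
  transcripts <- GenomicRanges::GRangesList(exlist)
  ue_df <- .readTsv(ues_path)
  ues <- GenomicRanges::GRanges(ue_df$chrom, IRanges::IRanges(ue_df$start, ue_df$end))
  names(ues) <- ue_df$name
  # CDS span: hull of the thick regions
  thick_all <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx), tx$thick)
  cds <- range(GenomicRanges::`strand<-`(thick_all, value = "*"))
  GeneModel(geneName = geneName, geneStrand = strand_,
            transcripts = transcripts, ues = ues, cdsSpan = cds)
}

#' Reconstruct an experimental construct interval upstream of its UE
#'
#' Published promoter constructs are specified only as "X kb upstream of
#' <UE>"; the interval is rebuilt strand-aware from the UE's upstream edge
#' (for a minus-strand gene, upstream means higher coordinate).
#'
#' @param ue Length-1 \code{GRanges} of the anchor UE.
#' @param kb Construct length in kb.
#' @param geneStrand "+" or "-".
#' @return Length-1 \code{GRanges}.
#' @export
constructInterval <- function(ue, kb, geneStrand) {
  len <- round(kb * 1000)
  if (len <= 0) stop("construct length must be positive")
  if (geneStrand == "-") {
    fromExternal(as.character(GenomicRanges::seqnames(ue)),
                 GenomicRanges::end(ue) + 1, GenomicRanges::end(ue) + len)
  } else {
    if (GenomicRanges::start(ue) - len < 1)
      stop("construct extends past position 1")
    fromExternal(as.character(GenomicRanges::seqnames(ue)),
                 GenomicRanges::start(ue) - len, GenomicRanges::start(ue) - 1)
  }
}

#' Load an evidence catalogue from a directory of plain-text tracks
#'
#' Expects the fixed layout written by \code{\link{writeCatalogue}} and
#' shipped with the SCN1A fixture: locus.tsv (key/value: gene, strand,
#' assembly), a gene-model BED12 + UE table, tss.tsv, constructs.tsv, a PLS
#' BED, a sources.tsv manifest with one BED per enhancer source, and
#' optionally a constraint bedGraph, a loops BEDPE, activity_summaries.tsv,
#' a reference promoter BED, and counts.tsv/samples.tsv.
#'
#' @param dir Directory containing the catalogue files.
#' @return An \code{\link{EvidenceCatalogue}}.
#' @export
loadCatalogue <- function(dir) {
  if (!dir.exists(dir))
    stop(sprintf("catalogue load error: directory '%s' does not exist", dir))
  locus <- .readKv(.findFile(dir, "locus.tsv"))
  gm <- readGeneModel(
    .findFile(dir, c("gene_model.bed12", "gene_model_synthetic.bed12")),
    .findFile(dir, c("ues.tsv", "ues_synthetic.tsv")),
    geneName = locus[["gene"]]
  )
  tss <- .readTsv(.findFile(dir, "tss.tsv"))
  tss$pos <- suppressWarnings(as.integer(tss$pos))
  tss$discordant <- as.logical(tss$discordant)

  cons_df <- .readTsv(.findFile(dir, "constructs.tsv"))
  constructs <- GenomicRanges::GRanges()
  for (i in seq_len(nrow(cons_df))) {
    ue <- ueRanges(gm)[cons_df$ue[i]]
    ci <- constructInterval(ue, cons_df$kb[i], geneStrand(gm))
    ci$kb <- cons_df$kb[i]
    ci$ue <- cons_df$ue[i]
    ci$citation <- cons_df$citation[i]
    constructs <- c(constructs, ci)
  }

  pls_path <- .findFile(dir, c("pls.bed", "pls_synthetic.bed"), required = FALSE)
  pls <- if (is.null(pls_path)) GenomicRanges::GRanges() else readBed(pls_path)

  constraint <- NULL
  cg <- .findFile(dir, "constraint.bedgraph", required = FALSE)
  if (!is.null(cg)) {
    bins <- readBedGraph(cg)
    bw <- if (length(bins) > 1) as.integer(stats::median(GenomicRanges::width(bins))) else 10L
    constraint <- ConstraintTrack(bins, binWidth = bw)
  }

  sets <- list()
  src_path <- .findFile(dir, "sources.tsv", required = FALSE)
  if (!is.null(src_path)) {
    src <- .readTsv(src_path)
    for (i in seq_len(nrow(src))) {
      calls <- GenomicRanges::sort(readBed(file.path(dir, src$path[i])))
      S4Vectors::metadata(calls)$species <- src$species[i]
      sets[[src$source[i]]] <- calls
    }
  }

  loops_path <- .findFile(dir, "loops.bedpe", required = FALSE)
  loops <- if (is.null(loops_path)) emptyLoops() else readBedpe(loops_path)

  act_path <- .findFile(dir, "activity_summaries.tsv", required = FALSE)
  act <- if (is.null(act_path)) NULL else .readTsv(act_path)

  prom_path <- .findFile(dir, "promoters_revised.bed", required = FALSE)
  promRef <- NULL
  if (!is.null(prom_path)) {
    p <- readBed(prom_path)
    promRef <- GenomicRanges::granges(p)
    names(promRef) <- p$name
  }

  counts <- NULL; smeta <- NULL
  cpath <- .findFile(dir, "counts.tsv", required = FALSE)
  if (!is.null(cpath)) {
    cdf <- utils::read.table(cpath, sep = "\t", header = TRUE, row.names = 1,
                             check.names = FALSE)
    counts <- as.matrix(cdf)
    smeta <- .readTsv(.findFile(dir, "samples.tsv"))
  }

  EvidenceCatalogue(geneModel = gm, tss = tss, pls = pls,
                    constructs = constructs, constraint = constraint,
                    enhancerSets = sets, loops = loops,
                    activitySummaries = act, counts = counts,
                    sampleMeta = smeta, promotersRef = promRef,
                    assembly = locus[["assembly"]])
}

.readKv <- function(path) {
  kv <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  stats::setNames(kv[[2]], kv[[1]])
}

#' Load the packaged SCN1A evidence catalogue
#'
#' The catalogue transcribes the published SCN1A integration: seven CAGE
#' TSS records (three h1a-, three h1b-labelled, one gene-body; positions
#' stored only where printed), three experimental promoter constructs
#' (2.5 kb upstream of h1a, 1.2 kb upstream of h1b, 1 kb upstream of h1c),
#' one PLS element near h1b, nine GRN enhancer calls (seven near, two far),
#' six enhancer sources for corroboration, the revised promoter annotation
#' P1a*/P1b*/P1c*, and the printed per-group TPM activity summaries. Gene
#' model and enhancer coordinates that were never printed ship as documented
#' synthetic stand-ins (see the fixture's README.txt). No constraint track
#' and no loops ship with the fixture.
#'
#' @param dir Fixture directory; defaults to the copy installed with the
#'   package.
#' @return An \code{\link{EvidenceCatalogue}}.
#' @examples
#' cat <- loadScn1aCatalogue()
#' nrow(tssRecords(cat))
#' @export
loadScn1aCatalogue <- function(dir = system.file("extdata", "scn1a",
                                                 package = "regulocus")) {
  if (!nzchar(dir) || !dir.exists(dir))
    stop("catalogue load error: packaged SCN1A fixture not found")
  loadCatalogue(dir)
}

#' Validate an evidence catalogue
#'
#' Checks every type invariant of the bundle and returns violations as data
#' (an empty character vector means the catalogue is clean). Each violation
#' names the offending record.
#'
#' @param cat An \code{\link{EvidenceCatalogue}}.
#' @return Character vector of violation messages (possibly empty).
#' @export
validateCatalogue <- function(cat) {
  v <- character(0)
  gm_ok <- validObject(cat@geneModel, test = TRUE)
  if (!isTRUE(gm_ok)) v <- c(v, paste("gene model:", gm_ok))

  t <- cat@tss
  if (anyDuplicated(t$tss_id)) v <- c(v, "duplicate TSS ids")
  if (!is.null(t$pos_end)) {
    bad <- which(!is.na(t$pos) & !is.na(t$pos_end) & t$pos_end != t$pos)
    for (i in bad)
      v <- c(v, sprintf("TSS '%s' spans more than one bp", t$tss_id[i]))
  }
  known_ues <- c(names(ueRanges(cat@geneModel)), "gene-body", "unassigned")
  bad_ue <- setdiff(stats::na.omit(unique(t$ue)), known_ues)
  for (u in bad_ue)
    v <- c(v, sprintf("TSS references unknown UE '%s'", u))

  cs <- cat@constructs
  for (i in seq_along(cs)) {
    if (cs$kb[i] <= 0)
      v <- c(v, sprintf("construct %d has non-positive length", i))
    ue <- ueRanges(cat@geneModel)[cs$ue[i]]
    up_ok <- if (geneStrand(cat@geneModel) == "-") {
      GenomicRanges::start(cs[i]) >= GenomicRanges::start(ue)
    } else {
      GenomicRanges::end(cs[i]) <= GenomicRanges::end(ue)
    }
    if (!up_ok)
      v <- c(v, sprintf("construct %d is not upstream of / containing UE '%s'", i, cs$ue[i]))
  }

  if (!is.null(cat@constraint)) {
    ct_ok <- validObject(cat@constraint, test = TRUE)
    if (!isTRUE(ct_ok)) v <- c(v, paste("constraint track:", paste(ct_ok, collapse = "; ")))
  }

  for (nm in names(cat@enhancerSets)) {
    calls <- cat@enhancerSets[[nm]]
    if (length(calls) > 1 && is.unsorted(GenomicRanges::start(calls)))
      v <- c(v, sprintf("enhancer set '%s' not sorted", nm))
  }

  lp <- cat@loops
  if (length(lp)) {
    cis <- as.character(GenomicRanges::seqnames(S4Vectors::first(lp))) ==
      as.character(GenomicRanges::seqnames(S4Vectors::second(lp)))
    for (i in which(!cis))
      v <- c(v, sprintf("loop '%s' is trans-chromosomal", S4Vectors::mcols(lp)$loop_id[i]))
  }

  a <- cat@activitySummaries
  if (!is.null(a)) {
    bad_n <- which(!is.na(a$n) & a$n < 1)
    for (i in bad_n) v <- c(v, sprintf("activity summary row %d has n < 1", i))
    bad_se <- which(!is.na(a$se) & a$se < 0)
    for (i in bad_se) v <- c(v, sprintf("activity summary row %d has SE < 0", i))
    bad_se1 <- which(!is.na(a$se) & !is.na(a$n) & a$n == 1 & a$se != 0)
    for (i in bad_se1) v <- c(v, sprintf("activity summary row %d has n = 1 but SE != 0", i))
  }

  if (!is.null(cat@counts)) {
    if (any(cat@counts < 0) || any(cat@counts != round(cat@counts)))
      v <- c(v, "counts matrix contains negative or non-integer values")
    if (!is.null(cat@sampleMeta) &&
        !all(colnames(cat@counts) %in% cat@sampleMeta$sample))
      v <- c(v, "counts matrix has samples absent from sample metadata")
  }
  v
}

#' Write an evidence catalogue to a directory of plain-text tracks
#'
#' Inverse of \code{\link{loadCatalogue}}; used by the simulator and the
#' pipeline so simulated loci round-trip through the same file layout as the
#' packaged fixture.
#'
#' @param cat An \code{\link{EvidenceCatalogue}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCatalogue <- function(cat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- cat@geneModel
  writeLines(sprintf("%s\t%s", c("gene", "strand", "assembly"),
                     c(geneName(gm), geneStrand(gm), cat@assembly)),
             file.path(dir, "locus.tsv"))
  .writeBed12(gm, file.path(dir, "gene_model.bed12"))
  ue <- ueRanges(gm)
  utils::write.table(
    data.frame(name = names(ue),
               chrom = as.character(GenomicRanges::seqnames(ue)),
               start = GenomicRanges::start(ue), end = GenomicRanges::end(ue)),
    file.path(dir, "ues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cat@tss), file.path(dir, "tss.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(ue = cat@constructs$ue, kb = cat@constructs$kb,
               citation = cat@constructs$citation),
    file.path(dir, "constructs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cat@pls)) writeBed(cat@pls, file.path(dir, "pls.bed"))
  if (!is.null(cat@constraint))
    writeBedGraph(constraintBins(cat@constraint), file.path(dir, "constraint.bedgraph"))
  if (length(cat@enhancerSets)) {
    paths <- sprintf("enhancers_src%02d.bed", seq_along(cat@enhancerSets))
    species <- vapply(cat@enhancerSets, function(s) {
      sp <- S4Vectors::metadata(s)$species
      if (is.null(sp)) "human" else sp
    }, character(1))
    for (i in seq_along(cat@enhancerSets))
      writeBed(cat@enhancerSets[[i]], file.path(dir, paths[i]))
    utils::write.table(
      data.frame(source = names(cat@enhancerSets), path = paths, species = species),
      file.path(dir, "sources.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(cat@loops)) writeBedpe(cat@loops, file.path(dir, "loops.bedpe"))
  if (!is.null(cat@activitySummaries))
    utils::write.table(cat@activitySummaries, file.path(dir, "activity_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cat@promotersRef)) {
    p <- cat@promotersRef
    p$name <- names(p)
    writeBed(p, file.path(dir, "promoters_revised.bed"))
  }
  if (!is.null(cat@counts)) {
    df <- data.frame(tss = rownames(cat@counts), cat@counts, check.names = FALSE)
    utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cat@sampleMeta, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

.writeBed12 <- function(gm, path) {
  lines <- character(0)
  for (nm in names(gm@transcripts)) {
    ex <- gm@transcripts[[nm]]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    s0 <- GenomicRanges::start(ex) - 1L
    e <- GenomicRanges::end(ex)
    txs <- min(s0); txe <- max(e)
    thick_s <- GenomicRanges::start(gm@cdsSpan) - 1L
    thick_e <- GenomicRanges::end(gm@cdsSpan)
    lines <- c(lines, paste(
      chrom, txs, txe, nm, 0, gm@geneStrand,
      max(thick_s, txs), min(thick_e, txe), 0, length(ex),
      paste0(paste(e - s0, collapse = ","), ","),
      paste0(paste(s0 - txs, collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
}
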