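#' @import methods
#' @importFrom BiocGenerics start end strand width
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' ConstraintTrack: fixed-width binned sequence-constraint scores
#'
#' Holds a binned constraint score track with CDTS semantics: the lower the
#' score the more constrained (less tolerant to variation) the bin; negative
#' scores flag highly constrained, likely functional sequence. Bins are
#' non-overlapping, sorted, and width-uniform (the last bin of a contig may
#' be short).
#'
#' @slot bins A \code{GRanges} with a numeric \code{score} metadata column.
#' @slot binWidth Integer bin width in bp (default 10).
#' @export
setClass("ConstraintTrack",
  representation(bins = "GRanges", binWidth = "integer"),
  prototype(binWidth = 10L)
)

setValidity("ConstraintTrack", function(object) {
  msgs <- character(0)
  b <- object@bins
  if (is.null(b$score) || !is.numeric(b$score))
    msgs <- c(msgs, "bins must carry a numeric 'score' column")
  if (length(object@binWidth) != 1 || is.na(object@binWidth) || object@binWidth < 1)
    msgs <- c(msgs, "binWidth must be a single positive integer")
  if (length(b) > 1) {
    bysq <- split(b, as.character(GenomicRanges::seqnames(b)))
    for (nm in names(bysq)) {
      x <- bysq[[nm]]
      s <- GenomicRanges::start(x); e <- GenomicRanges::end(x)
      o <- order(s)
      s <- s[o]; e <- e[o]
      if (any(s[-1] <= e[-length(e)]))
        msgs <- c(msgs, sprintf("overlapping constraint bins on %s", nm))
      w <- e - s + 1
      if (any(w[-length(w)] != object@binWidth))
        msgs <- c(msgs, sprintf("non-uniform bin widths on %s (only the last bin may be short)", nm))
      if (w[length(w)] > object@binWidth)
        msgs <- c(msgs, sprintf("last bin wider than binWidth on %s", nm))
    }
  }
  if (length(b) > 0 && is.unsorted(GenomicRanges::start(b)) &&
      length(unique(as.character(GenomicRanges::seqnames(b)))) == 1)
    msgs <- c(msgs, "constraint bins must be sorted by start")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConstraintTrack
#'
#' @param bins \code{GRanges} with numeric \code{score}; sorted uniform bins.
#' @param binWidth Bin width in bp.
#' @return A \code{ConstraintTrack}.
#' @export
ConstraintTrack <- function(bins, binWidth = 10L) {
  new("ConstraintTrack", bins = bins, binWidth = as.integer(binWidth))
}

#' @describeIn ConstraintTrack-class Bins with scores.
#' @param x,object A \code{ConstraintTrack}.
#' @export
constraintBins <- function(x) x@bins

#' @describeIn ConstraintTrack-class Bin width in bp.
#' @export
binWidth <- function(x) x@binWidth

setMethod("show", "ConstraintTrack", function(object) {
  cat("ConstraintTrack with", length(object@bins), "bins of width",
      object@binWidth, "bp\n")
  if (length(object@bins)) {
    sc <- object@bins$score
    cat(sprintf("  score range [%.3f, %.3f]; %d negative (constrained) bins\n",
                min(sc), max(sc), sum(sc < 0)))
  }
})

#' GeneModel: transcripts, untranslated first exons and CDS span of a locus
#'
#' The gene model anchors promoter derivation: each named untranslated exon
#' (UE; e.g. SCN1A's h1a/h1b/h1c alternative first exons) seeds one derived
#' promoter region, and the CDS span is the reference point for enhancer
#' proximity classification. "Upstream"/"downstream" are strand-aware: for a
#' minus-strand gene, upstream means higher coordinate.
#'
#' @slot geneName Gene symbol.
#' @slot geneStrand "+" or "-".
#' @slot transcripts A \code{GRangesList}, one element per transcript, exons
#'   sorted by start with a logical \code{translated} metadata column.
#' @slot ues Named \code{GRanges} of untranslated first exons.
#' @slot cdsSpan Length-1 \code{GRanges}, hull of the translated sequence.
#' @export
setClass("GeneModel",
  representation(geneName = "character", geneStrand = "character",
                 transcripts = "GRangesList", ues = "GRanges",
                 cdsSpan = "GRanges")
)

setValidity("GeneModel", function(object) {
  msgs <- character(0)
  if (!object@geneStrand %in% c("+", "-"))
    msgs <- c(msgs, "geneStrand must be '+' or '-'")
  if (length(object@cdsSpan) != 1)
    msgs <- c(msgs, "cdsSpan must be a single interval")
  if (is.null(names(object@ues)) || anyDuplicated(names(object@ues)))
    msgs <- c(msgs, "UEs must carry unique names")
  for (i in seq_along(object@transcripts)) {
    ex <- object@transcripts[[i]]
    if (is.null(ex$translated))
      msgs <- c(msgs, sprintf("transcript %d lacks 'translated' flags", i))
    if (length(ex) > 1) {
      s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
      if (is.unsorted(s, strictly = TRUE) || any(s[-1] <= e[-length(e)]))
        msgs <- c(msgs, sprintf("transcript %d exons overlap or are unsorted", i))
    }
  }
  # every named UE must coincide with an untranslated exon of some transcript
  allex <- unlist(object@transcripts)
  untr <- allex[!allex$translated]
  for (nm in names(object@ues)) {
    u <- object@ues[nm]
    hit <- any(GenomicRanges::start(untr) == GenomicRanges::start(u) &
                 GenomicRanges::end(untr) == GenomicRanges::end(u))
    if (!hit)
      msgs <- c(msgs, sprintf("UE '%s' matches no untranslated exon of any transcript", nm))
  }
  # CDS span must lie within the hull of translated exons
  tr <- allex[allex$translated]
  if (length(tr) && length(object@cdsSpan) == 1) {
    hull <- range(GenomicRanges::`strand<-`(tr, value = "*"))
    if (!(GenomicRanges::start(object@cdsSpan) >= GenomicRanges::start(hull) &&
          GenomicRanges::end(object@cdsSpan) <= GenomicRanges::end(hull)))
      msgs <- c(msgs, "cdsSpan not covered by the hull of translated exons")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModel
#'
#' @param geneName Gene symbol.
#' @param geneStrand "+" or "-".
#' @param transcripts \code{GRangesList} of exons with \code{translated} flags.
#' @param ues Named \code{GRanges} of untranslated first exons.
#' @param cdsSpan Length-1 \code{GRanges}.
#' @return A \code{GeneModel}.
#' @export
GeneModel <- function(geneName, geneStrand, transcripts, ues, cdsSpan) {
  new("GeneModel", geneName = geneName, geneStrand = geneStrand,
      transcripts = transcripts, ues = ues, cdsSpan = cdsSpan)
}

#' @describeIn GeneModel-class Named untranslated-exon GRanges.
#' @param x,object A \code{GeneModel}.
#' @export
ueRanges <- function(x) x@ues

#' @describeIn GeneModel-class CDS span (length-1 GRanges).
#' @export
cdsSpan <- function(x) x@cdsSpan

#' @describeIn GeneModel-class Gene strand ("+" or "-").
#' @export
geneStrand <- function(x) x@geneStrand

#' @describeIn GeneModel-class Gene symbol.
#' @export
geneName <- function(x) x@geneName

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel for", object@geneName, "(", object@geneStrand, "strand ) with",
      length(object@transcripts), "transcript(s),",
      length(object@ues), "UE(s):", paste(names(object@ues), collapse = ", "), "\n")
})

#' EvidenceCatalogue: a locus's full regulatory-evidence bundle
#'
#' Aggregates every input the integration consumes: the gene model, TSS
#' records (positioned or placeholder), promoter-like-signature (PLS)
#' elements, experimental promoter constructs, the binned constraint track,
#' per-source enhancer call sets, chromatin-interaction loops, and (when the
#' evidence comes from a published catalogue rather than raw counts)
#' pre-computed activity summaries and a reference promoter annotation.
#'
#' TSS records are kept as a \code{DataFrame} (columns \code{tss_id},
#' \code{chrom}, \code{pos}, \code{source}, \code{ue}, \code{discordant})
#' because positions may be unknown (\code{NA}): such records keep their UE
#' label but are skipped, with a warning, by position-based operations.
#'
#' @slot geneModel A \code{GeneModel}.
#' @slot tss A \code{DataFrame} of TSS records.
#' @slot pls \code{GRanges} of PLS elements.
#' @slot constructs \code{GRanges} of experimentally assayed promoter
#'   constructs (metadata: \code{kb}, \code{ue}, \code{citation}).
#' @slot constraint A \code{ConstraintTrack} or \code{NULL}.
#' @slot enhancerSets Named list of \code{GRanges}, one per source; each
#'   carries a \code{species} metadata attribute ("human" or "mouse-lifted").
#' @slot loops \code{Pairs} of anchor \code{GRanges} with \code{cell_type},
#'   \code{source}, \code{loop_id} metadata.
#' @slot activitySummaries \code{data.frame} (tss, group, mean_tpm, se, n)
#'   or \code{NULL}.
#' @slot counts TSS-by-sample integer matrix or \code{NULL}.
#' @slot sampleMeta \code{data.frame} (sample, group, lib_total) or \code{NULL}.
#' @slot promotersRef Named \code{GRanges} reference promoter annotation, or
#'   \code{NULL}.
#' @slot assembly Assembly tag shared by all records.
#' @export
setClass("EvidenceCatalogue",
  representation(geneModel = "GeneModel", tss = "DataFrame", pls = "GRanges",
                 constructs = "GRanges", constraint = "ANY",
                 enhancerSets = "list", loops = "Pairs",
                 activitySummaries = "ANY", counts = "ANY",
                 sampleMeta = "ANY", promotersRef = "GRangesOrNULL",
                 assembly = "character")
)

#' Construct an EvidenceCatalogue
#'
#' @param geneModel,tss,pls,constructs,constraint,enhancerSets,loops
#'   See the class slots.
#' @param activitySummaries,counts,sampleMeta,promotersRef,assembly
#'   See the class slots.
#' @return An \code{EvidenceCatalogue}.
#' @export
EvidenceCatalogue <- function(geneModel, tss, pls = GenomicRanges::GRanges(),
                              constructs = GenomicRanges::GRanges(),
                              constraint = NULL, enhancerSets = list(),
                              loops = emptyLoops(),
                              activitySummaries = NULL, counts = NULL,
                              sampleMeta = NULL, promotersRef = NULL,
                              assembly = "GRCh38.p13") {
  if (is.data.frame(tss)) tss <- S4Vectors::DataFrame(tss)
  new("EvidenceCatalogue", geneModel = geneModel, tss = tss, pls = pls,
      constructs = constructs, constraint = constraint,
      enhancerSets = enhancerSets, loops = loops,
      activitySummaries = activitySummaries, counts = counts,
      sampleMeta = sampleMeta, promotersRef = promotersRef,
      assembly = assembly)
}

#' @describeIn EvidenceCatalogue-class The gene model.
#' @param x,object An \code{EvidenceCatalogue}.
#' @export
catGeneModel <- function(x) x@geneModel

#' @describeIn EvidenceCatalogue-class TSS record table (DataFrame).
#' @export
tssRecords <- function(x) x@tss

#' @describeIn EvidenceCatalogue-class Positioned TSSs as single-bp GRanges
#'   (placeholder records with unknown position are dropped with a warning).
#' @export
tssRanges <- function(x) {
  t <- x@tss
  drop <- is.na(t$pos)
  if (any(drop))
    warning(sprintf("%d TSS record(s) have no printed position and are skipped", sum(drop)))
  t <- t[!drop, , drop = FALSE]
  gr <- GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$pos, t$pos))
  gr$tss_id <- t$tss_id
  gr$ue <- t$ue
  gr
}

#' @describeIn EvidenceCatalogue-class PLS elements.
#' @export
plsElements <- function(x) x@pls

#' @describeIn EvidenceCatalogue-class Experimental promoter constructs.
#' @export
experimentalConstructs <- function(x) x@constructs

#' @describeIn EvidenceCatalogue-class The constraint track (or NULL).
#' @export
constraintTrack <- function(x) x@constraint

#' @describeIn EvidenceCatalogue-class Named list of enhancer call sets.
#' @export
enhancerSets <- function(x) x@enhancerSets

#' @describeIn EvidenceCatalogue-class Interaction loops (Pairs).
#' @export
loopRecords <- function(x) x@loops

#' @describeIn EvidenceCatalogue-class Activity summary table (or NULL).
#' @export
activitySummaries <- function(x) x@activitySummaries

#' @describeIn EvidenceCatalogue-class Reference promoter annotation (or NULL).
#' @export
promotersRef <- function(x) x@promotersRef

#' @describeIn EvidenceCatalogue-class TSS-by-sample count matrix (or NULL).
#' @export
tssCounts <- function(x) x@counts

#' @describeIn EvidenceCatalogue-class Sample metadata (or NULL).
#' @export
sampleMeta <- function(x) x@sampleMeta

setMethod("show", "EvidenceCatalogue", function(object) {
  cat("EvidenceCatalogue [", object@assembly, "] for",
      object@geneModel@geneName, "\n")
  cat("  ", nrow(object@tss), "TSS record(s) (",
      sum(!is.na(object@tss$pos)), "positioned ),",
      length(object@pls), "PLS element(s),",
      length(object@constructs), "experimental construct(s)\n")
  cat("  constraint track:",
      if (is.null(object@constraint)) "absent"
      else paste(length(object@constraint@bins), "bins"), "\n")
  cat("  enhancer sources:", length(object@enhancerSets), "(",
      paste(names(object@enhancerSets), collapse = ", "), ")\n")
  cat("  loops:", length(object@loops), " | reference promoters:",
      if (is.null(object@promotersRef)) "none"
      else paste(names(object@promotersRef), collapse = ", "), "\n")
})
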