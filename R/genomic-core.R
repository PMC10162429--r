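#' Build a GRanges from external 1-based inclusive coordinates
#'
#' Genomic positions quoted in prose and supplementary tables (e.g.
#' "GRCh38.p13:166148180-166151550") are 1-based fully-closed. This helper
#' validates such coordinates and returns the corresponding
#' \link[GenomicRanges]{GRanges}, which uses the same convention, so the
#' mapping is the identity plus validation. Width equals
#' \code{end - start + 1}. BED and bedGraph files on disk are 0-based
#' half-open per their standards and are converted by the readers below.
#'
#' @param chrom Chromosome name (character).
#' @param start,end 1-based inclusive positions, positive integers with
#'   \code{start <= end}.
#' @param strand "+", "-" or "*" (unstranded). Recycled.
#' @return A \code{GRanges} of the same length as the inputs.
#' @examples
#' fromExternal("chr2", 166148180, 166151550, "-")
#' @export
fromExternal <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("coordinate error: non-numeric start/end")
  if (any(start < 1) || any(end < 1))
    stop("coordinate error: positions must be positive (1-based)")
  if (any(start != round(start)) || any(end != round(end)))
    stop("coordinate error: positions must be integers")
  if (any(start > end))
    stop("coordinate error: start > end (inverted interval)")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Report external 1-based inclusive coordinates for a GRanges
#'
#' Inverse of \code{\link{fromExternal}}; returns a data.frame with columns
#' \code{chrom}, \code{start}, \code{end}, \code{strand} on the external
#' convention. Round-tripping through \code{fromExternal} is lossless.
#'
#' @param gr A \code{GRanges}.
#' @return A data.frame with one row per range.
#' @export
toExternal <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Any-basepair overlap between two interval sets
#'
#' Strand-blind, same-chromosome, >= 1 bp shared. Adjacent intervals (zero
#' intervening bases) do not overlap.
#'
#' @param a,b \code{GRanges} (recycled pairwise if one has length 1,
#'   otherwise compared elementwise; lengths must match or be 1).
#' @return Logical vector.
#' @export
intervalsOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  same &
    (pmax(GenomicRanges::start(a), GenomicRanges::start(b)) <=
       pmin(GenomicRanges::end(a), GenomicRanges::end(b)))
}

#' Merge intervals, bridging gaps up to a size
#'
#' Intervals separated by at most \code{gap} intervening bases are unioned.
#' With \code{gap = 0} only overlapping or directly abutting intervals merge.
#' Output is sorted, strand-blind, and idempotent.
#'
#' @param gr A \code{GRanges}.
#' @param gap Non-negative integer, maximum bridged gap in bp.
#' @return A sorted, reduced \code{GRanges}.
#' @export
mergeWithGap <- function(gr, gap = 0) {
  if (gap < 0) stop("gap must be >= 0")
  if (length(gr) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(
    GenomicRanges::sort(GenomicRanges::`strand<-`(gr, value = "*")),
    min.gapwidth = gap + 1
  )
}

#' Is an interval abutted on both sides by flanking intervals?
#'
#' Formalizes "encompassed by": \code{a} is encompassed by \code{flankers}
#' when some flanker ends exactly at the base before \code{a}'s start AND
#' some flanker starts exactly at the base after \code{a}'s end (strict
#' abutment, no gap). Used by the promoter-derivation rule to decide whether
#' a non-constrained segment sits inside constrained context.
#'
#' @param a A length-1 \code{GRanges}.
#' @param flankers A \code{GRanges} of candidate flanking intervals on the
#'   same chromosome.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
encompassedBy <- function(a, flankers) {
  stopifnot(length(a) == 1)
  if (length(flankers) == 0) return(FALSE)
  onchrom <- as.character(GenomicRanges::seqnames(flankers)) ==
    as.character(GenomicRanges::seqnames(a))
  f <- flankers[onchrom]
  if (length(f) == 0) return(FALSE)
  any(GenomicRanges::end(f) == GenomicRanges::start(a) - 1) &&
    any(GenomicRanges::start(f) == GenomicRanges::end(a) + 1)
}

.checkLines <- function(path, min_fields, what) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  if (length(lines)) {
    nf <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
    bad <- which(nf < min_fields)
    if (length(bad)) {
      stop(sprintf("parse error in %s '%s': line %d has %d field(s), expected >= %d",
                   what, path, which(keep)[bad[1]], nf[bad[1]], min_fields))
    }
  }
  which(keep)
}

#' Read a BED file (BED3/BED6/BED12)
#'
#' Thin wrapper over \code{rtracklayer::import}: tab-delimited, 0-based
#' half-open on disk, "#"/track/browser lines skipped. Malformed lines are
#' reported with their line number before import is attempted.
#'
#' @param path Path to a plain-text BED file.
#' @return A \code{GRanges}; name/score columns as metadata when present.
#' @export
readBed <- function(path) {
  kept <- .checkLines(path, 3L, "BED")
  if (length(kept) == 0) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "BED")
}

#' Write a GRanges to BED
#'
#' @param gr A \code{GRanges}; \code{name} and \code{score} metadata columns
#'   are written when present.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph file into a scored GRanges
#'
#' @param path Path to a plain-text bedGraph (chrom, start, end, value).
#' @return A \code{GRanges} with a numeric \code{score} column.
#' @export
readBedGraph <- function(path) {
  kept <- .checkLines(path, 4L, "bedGraph")
  if (length(kept) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a scored GRanges to bedGraph
#'
#' @param gr A \code{GRanges} with a numeric \code{score} column.
#' @param path Output path.
#' @export
writeBedGraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read chromatin-interaction loops from BEDPE
#'
#' Tab-delimited BEDPE: chrom1 start1 end1 chrom2 start2 end2, with the cell
#' type in column 7 and an optional source label in column 8. Coordinates on
#' disk are 0-based half-open. Trans-chromosomal pairs are rejected unless
#' \code{allow_trans = TRUE} (all interactions handled by this package are
#' cis). No installed package parses BEDPE, so this reader is local.
#'
#' @param path Path to a plain-text BEDPE file.
#' @param allow_trans Keep anchor pairs on different chromosomes.
#' @return A \code{S4Vectors::Pairs} of \code{GRanges} with metadata columns
#'   \code{cell_type}, \code{source} and \code{loop_id}.
#' @export
readBedpe <- function(path, allow_trans = FALSE) {
  kept <- .checkLines(path, 6L, "BEDPE")
  if (length(kept) == 0) return(emptyLoops())
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = paste0("V", 1:10), fill = TRUE)
  a <- GenomicRanges::GRanges(df$V1, IRanges::IRanges(df$V2 + 1L, df$V3))
  b <- GenomicRanges::GRanges(df$V4, IRanges::IRanges(df$V5 + 1L, df$V6))
  cell <- if (!all(is.na(df$V7))) as.character(df$V7) else rep(NA_character_, nrow(df))
  src <- if (!all(is.na(df$V8))) as.character(df$V8) else rep(NA_character_, nrow(df))
  cis <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  if (!allow_trans && any(!cis)) {
    stop(sprintf("parse error in BEDPE '%s': %d trans-chromosomal pair(s); cis-only expected",
                 path, sum(!cis)))
  }
  p <- S4Vectors::Pairs(a, b, cell_type = cell, source = src,
                        loop_id = sprintf("loop%04d", seq_len(nrow(df))))
  p
}

#' Write loops to BEDPE
#'
#' @param loops A \code{Pairs} of \code{GRanges} as returned by
#'   \code{\link{readBedpe}}.
#' @param path Output path.
#' @export
writeBedpe <- function(loops, path) {
  a <- S4Vectors::first(loops)
  b <- S4Vectors::second(loops)
  m <- S4Vectors::mcols(loops)
  df <- data.frame(
    as.character(GenomicRanges::seqnames(a)),
    GenomicRanges::start(a) - 1L, GenomicRanges::end(a),
    as.character(GenomicRanges::seqnames(b)),
    GenomicRanges::start(b) - 1L, GenomicRanges::end(b),
    if (!is.null(m$cell_type)) m$cell_type else ".",
    if (!is.null(m$source)) m$source else "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' An empty loop set
#' @return A zero-length \code{Pairs} with the loop metadata columns.
#' @export
emptyLoops <- function() {
  S4Vectors::Pairs(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                   cell_type = character(0), source = character(0),
                   loop_id = character(0))
}
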