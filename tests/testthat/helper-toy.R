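# Builders for small deterministic fixtures used across test files.

# A constraint track from a score vector, bins of width `bw` starting at
# `origin` on `chrom`.
toyTrack <- function(scores, bw = 10, chrom = "chr1", origin = 1) {
  s <- origin + (seq_along(scores) - 1) * bw
  bins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + bw - 1))
  bins$score <- scores
  ConstraintTrack(bins, binWidth = bw)
}

# A minimal single-UE gene model on chr1: one transcript with a translated
# exon at [1,20] (CDS [5,15]) and the UE as an untranslated exon.
toyGeneModel <- function(ue_start = 61, ue_end = 90, strand = "+",
                         chrom = "chr1") {
  ue <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ue_start, ue_end))
  names(ue) <- "h1"
  ex <- c(GenomicRanges::GRanges(chrom, IRanges::IRanges(1, 20)), ue)
  ex <- GenomicRanges::sort(ex)
  ex$translated <- GenomicRanges::start(ex) == 1
  GeneModel(geneName = "TOY", geneStrand = strand,
            transcripts = GenomicRanges::GRangesList(TX1 = ex),
            ues = ue,
            cdsSpan = GenomicRanges::GRanges(chrom, IRanges::IRanges(5, 15)))
}

emptyTssTable <- function() {
  data.frame(tss_id = character(0), chrom = character(0), pos = integer(0),
             source = character(0), ue = character(0), discordant = logical(0),
             stringsAsFactors = FALSE)
}

# The worked toy locus: 20 bins of width 10 over [1,200]; negative scores on
# [1,120] and [151,200], non-negative on [121,150]; UE [61,90];
# an experimental construct and a PLS element as given.
toyCatalogue <- function(exp_start = 41, exp_end = 160,
                         pls_start = 56, pls_end = 95,
                         scores = c(rep(-1, 12), rep(2, 3), rep(-1, 5))) {
  gm <- toyGeneModel()
  track <- toyTrack(scores)
  constructs <- GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(exp_start, exp_end))
  constructs$kb <- (exp_end - exp_start + 1) / 1000
  constructs$ue <- "h1"
  constructs$citation <- "toy"
  pls <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pls_start, pls_end))
  pls$name <- "PLS_toy"
  EvidenceCatalogue(geneModel = gm, tss = emptyTssTable(), pls = pls,
                    constructs = constructs, constraint = track,
                    assembly = "toy")
}

# Independent brute-force oracles ------------------------------------------

# Overlap by explicit base-membership intersection.
bruteOverlap <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, e1), seq(s2, e2))) > 0
}

# Merge-with-gap via a boolean occupancy mask: mark covered bases, close
# gaps <= gap, read off connected components.
bruteMerge <- function(starts, ends, gap, limit = max(ends) + gap + 2) {
  mask <- rep(FALSE, limit)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  if (gap > 0) {
    runs <- rle(mask)
    off <- cumsum(c(1, runs$lengths))
    for (j in which(!runs$values & runs$lengths <= gap)) {
      if (j == 1 || j == length(runs$values)) next
      mask[off[j]:(off[j + 1] - 1)] <- TRUE
    }
  }
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1
  cbind(start = s[r$values], end = e[r$values])
}

# Sign runs by walking bins one at a time.
bruteSignRuns <- function(scores, bw = 10, origin = 1) {
  out <- NULL
  cur_sign <- NULL; cur_start <- NULL; n <- 0
  for (i in seq_along(scores)) {
    sgn <- if (scores[i] < 0) "negative" else "non-negative"
    if (is.null(cur_sign) || sgn != cur_sign) {
      if (!is.null(cur_sign))
        out <- rbind(out, data.frame(start = cur_start,
                                     end = origin + (i - 1) * bw - 1,
                                     sign = cur_sign, n_bins = n))
      cur_sign <- sgn; cur_start <- origin + (i - 1) * bw; n <- 0
    }
    n <- n + 1
  }
  rbind(out, data.frame(start = cur_start,
                        end = origin + length(scores) * bw - 1,
                        sign = cur_sign, n_bins = n))
}
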