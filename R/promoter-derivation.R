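#' Parameters for promoter-region derivation
#'
#' @param seed_pad Pad, in bp, applied on both sides of each positioned TSS
#'   point when it enters the seed (default 50).
#' @param bridge_gap Maximum gap, in bp, between negative constraint runs
#'   bridged without evidence (default 0: strict abutment only).
#' @param downstream_ext Strand-aware extension of the UE in the downstream
#'   direction, in bp (default 500). Captures regulatory sequence known to
#'   sit downstream of untranslated first exons without an established
#'   extent.
#' @param require_experimental Must a non-negative (unconstrained) run
#'   overlap experimental promoter evidence to be bridged? (default TRUE,
#'   matching the integration rule.)
#' @return A validated list of class \code{DerivationParams}.
#' @export
derivationParams <- function(seed_pad = 50, bridge_gap = 0,
                             downstream_ext = 500,
                             require_experimental = TRUE) {
  stopifnot(seed_pad >= 0, bridge_gap >= 0, downstream_ext >= 0,
            is.logical(require_experimental))
  structure(list(seed_pad = seed_pad, bridge_gap = bridge_gap,
                 downstream_ext = downstream_ext,
                 require_experimental = require_experimental),
            class = "DerivationParams")
}

#' Classify a constraint track into maximal sign runs
#'
#' Partitions the track into maximal runs of genomically consecutive bins
#' that are all negative (score < 0: highly constrained) or all
#' non-negative. Runs break at coverage gaps; adjacent runs differ in sign.
#'
#' @param track A \code{\link{ConstraintTrack}}.
#' @return A \code{GRanges} with metadata columns \code{sign} ("negative" /
#'   "non-negative") and \code{n_bins}, ordered along the track.
#' @export
classifySignRuns <- function(track) {
  b <- constraintBins(track)
  if (length(b) == 0) stop("sign-run classification requires a non-empty track")
  b <- GenomicRanges::sort(b)
  chrom <- as.character(GenomicRanges::seqnames(b))
  s <- GenomicRanges::start(b); e <- GenomicRanges::end(b)
  neg <- b$score < 0
  # new run when sign flips, chromosome changes, or bins are not contiguous
  brk <- c(TRUE, neg[-1] != neg[-length(neg)] |
             chrom[-1] != chrom[-length(chrom)] |
             s[-1] != e[-length(e)] + 1)
  idx <- which(brk)
  last <- c(idx[-1] - 1L, length(s))
  out <- GenomicRanges::GRanges(chrom[idx],
                                IRanges::IRanges(s[idx], e[last]))
  out$sign <- ifelse(neg[idx], "negative", "non-negative")
  out$n_bins <- as.integer(last - idx + 1L)
  out
}

#' Build the evidence seed for one untranslated exon
#'
#' The seed is the coordinate hull of every piece of direct promoter
#' evidence anchored to the UE: the UE itself, positioned TSS points padded
#' by \code{seed_pad}, promoter-like-signature elements, experimentally
#' assayed construct intervals, and the UE extended downstream (strand-
#' aware) by \code{downstream_ext}.
#'
#' @param ue Length-1 \code{GRanges} of the untranslated exon.
#' @param tss \code{GRanges} of positioned TSSs assigned to this UE (may be
#'   empty).
#' @param pls \code{GRanges} of PLS elements to include (may be empty).
#' @param experimental \code{GRanges} of experimental construct intervals
#'   (may be empty).
#' @param params A \code{\link{derivationParams}} list.
#' @param geneStrand "+" or "-"; downstream is towards lower coordinates on
#'   the minus strand.
#' @return List with \code{hull} (length-1 \code{GRanges}) and
#'   \code{components} (\code{GRanges} with a \code{kind} column).
#' @export
buildSeed <- function(ue, tss = GenomicRanges::GRanges(),
                      pls = GenomicRanges::GRanges(),
                      experimental = GenomicRanges::GRanges(),
                      params = derivationParams(), geneStrand = "+") {
  if (length(ue) != 1 || GenomicRanges::width(ue) < 1)
    stop("derivation error: seed requires exactly one valid UE interval")
  comp <- GenomicRanges::granges(ue)
  kind <- "ue"
  if (params$downstream_ext > 0) {
    down <- if (geneStrand == "-") {
      GenomicRanges::GRanges(GenomicRanges::seqnames(ue),
        IRanges::IRanges(max(1, GenomicRanges::start(ue) - params$downstream_ext),
                         GenomicRanges::end(ue)))
    } else {
      GenomicRanges::GRanges(GenomicRanges::seqnames(ue),
        IRanges::IRanges(GenomicRanges::start(ue),
                         GenomicRanges::end(ue) + params$downstream_ext))
    }
    comp <- c(comp, down); kind <- c(kind, "downstream_ext")
  }
  if (length(tss)) {
    padded <- GenomicRanges::resize(GenomicRanges::granges(tss),
                                    width = GenomicRanges::width(tss) + 2 * params$seed_pad,
                                    fix = "center")
    GenomicRanges::start(padded) <- pmax(1L, GenomicRanges::start(padded))
    comp <- c(comp, padded); kind <- c(kind, rep("tss", length(padded)))
  }
  if (length(pls)) {
    comp <- c(comp, GenomicRanges::granges(pls))
    kind <- c(kind, rep("pls", length(pls)))
  }
  if (length(experimental)) {
    comp <- c(comp, GenomicRanges::granges(experimental))
    kind <- c(kind, rep("experimental", length(experimental)))
  }
  comp <- GenomicRanges::`strand<-`(comp, value = "*")
  comp$kind <- kind
  hull <- range(comp)
  if (length(hull) != 1)
    stop("derivation error: seed components span multiple chromosomes")
  list(hull = hull, components = comp)
}

#' Derive the promoter-activity region for one untranslated exon
#'
#' Formalization of the constraint-first integration rule: the region is
#' grown from the evidence seed over the sign-run partition of the
#' constraint track. (1) Classify sign runs. (2) Include every negative
#' (constrained) run overlapping the seed hull. (3) Include a non-negative
#' run iff it is abutted on both sides by currently-included negative runs
#' and (when \code{require_experimental}) overlaps experimental promoter
#' evidence; once such a run is bridged, negative runs beyond it that touch
#' the grown region become includable and step (2) re-applies. Iterate to a
#' fixpoint. (4) The region is the hull of all included runs and seed
#' components, snapped outward to bin boundaries.
#'
#' @param ueName Name of the UE in the catalogue's gene model.
#' @param cat An \code{\link{EvidenceCatalogue}} with a constraint track
#'   covering the seed.
#' @param params A \code{\link{derivationParams}} list.
#' @return Length-1 \code{GRanges} with metadata columns \code{name},
#'   \code{ue}, \code{n_bins} and a \code{provenance} list column recording
#'   every seed component and included run.
#' @export
derivePromoterRegion <- function(ueName, cat, params = derivationParams()) {
  gm <- catGeneModel(cat)
  if (!ueName %in% names(ueRanges(gm)))
    stop(sprintf("derivation error: UE '%s' not in gene model", ueName))
  ue <- ueRanges(gm)[ueName]
  track <- constraintTrack(cat)
  if (is.null(track))
    stop(sprintf("coverage error: no constraint track available for UE '%s'", ueName))

  tssdf <- as.data.frame(tssRecords(cat))
  disc <- if (!is.null(tssdf$discordant)) tssdf$discordant %in% TRUE else
    rep(FALSE, nrow(tssdf))
  keep <- !is.na(tssdf$pos) & tssdf$ue == ueName & !disc
  tss <- if (any(keep))
    GenomicRanges::GRanges(tssdf$chrom[keep],
                           IRanges::IRanges(tssdf$pos[keep], tssdf$pos[keep]))
  else GenomicRanges::GRanges()
  constructs <- experimentalConstructs(cat)
  exp_ue <- if (length(constructs) && !is.null(constructs$ue))
    constructs[constructs$ue == ueName] else constructs
  # preliminary hull (without PLS) selects which PLS elements belong here
  pre <- buildSeed(ue, tss, GenomicRanges::GRanges(), exp_ue, params, geneStrand(gm))
  pls_all <- plsElements(cat)
  pls <- if (length(pls_all))
    pls_all[IRanges::overlapsAny(pls_all, pre$hull, ignore.strand = TRUE)]
  else pls_all
  seed <- buildSeed(ue, tss, pls, exp_ue, params, geneStrand(gm))

  bins <- constraintBins(track)
  covered <- GenomicRanges::reduce(GenomicRanges::granges(bins))
  hit <- IRanges::overlapsAny(seed$hull, covered, type = "within", ignore.strand = TRUE)
  if (!hit)
    stop(sprintf("coverage error: constraint track does not cover the seed for UE '%s'",
                 ueName))

  runs <- classifySignRuns(track)
  runs <- runs[as.character(GenomicRanges::seqnames(runs)) ==
                 as.character(GenomicRanges::seqnames(ue))]
  neg <- runs$sign == "negative"
  rs <- GenomicRanges::start(runs); re <- GenomicRanges::end(runs)
  n <- length(runs)
  hull_s <- GenomicRanges::start(seed$hull); hull_e <- GenomicRanges::end(seed$hull)
  # pre-compute which non-negative runs overlap experimental evidence
  exp_ok <- if (!params$require_experimental) rep(TRUE, n) else {
    if (length(exp_ue) == 0) rep(FALSE, n) else {
      xs <- GenomicRanges::start(exp_ue); xe <- GenomicRanges::end(exp_ue)
      vapply(seq_len(n), function(i)
        any(xs <= re[i] & xe >= rs[i]), logical(1))
    }
  }
  # a run is abutted by its partition neighbour when there is no coverage gap
  abuts_prev <- c(FALSE, rs[-1] == re[-n] + 1)
  abuts_next <- c(rs[-1] == re[-n] + 1, FALSE)
  included <- rep(FALSE, n)
  gap <- params$bridge_gap
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > n + 2)
      stop("internal error: derivation fixpoint not reached")
    changed <- FALSE
    # (2) negative runs overlapping the seed, or touching the grown region
    region_s <- c(hull_s, rs[included]); region_e <- c(hull_e, re[included])
    for (i in which(neg & !included)) {
      touch <- (hull_s <= re[i] && hull_e >= rs[i]) ||
        any(region_s <= re[i] + gap + 1 & region_e >= rs[i] - gap - 1)
      if (touch) { included[i] <- TRUE; changed <- TRUE }
    }
    # (3) non-negative runs encompassed by included negative runs on both
    # sides (strict abutment) and supported by experimental evidence
    prev_inc <- c(FALSE, included[-n] & neg[-n])
    next_inc <- c(included[-1] & neg[-1], FALSE)
    bridge <- !neg & !included & prev_inc & next_inc &
      abuts_prev & abuts_next & exp_ok
    if (any(bridge)) { included[bridge] <- TRUE; changed <- TRUE }
    if (!changed) break
  }

  pieces <- c(GenomicRanges::granges(seed$components),
              GenomicRanges::granges(runs[included]))
  hull <- range(GenomicRanges::`strand<-`(pieces, value = "*"))
  # snap outward to bin boundaries relative to the track origin
  bw <- binWidth(track)
  origin <- min(GenomicRanges::start(bins[as.character(GenomicRanges::seqnames(bins)) ==
                                            as.character(GenomicRanges::seqnames(ue))]))
  s <- origin + floor((GenomicRanges::start(hull) - origin) / bw) * bw
  e <- origin + ceiling((GenomicRanges::end(hull) - origin + 1) / bw) * bw - 1
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(hull),
                                IRanges::IRanges(max(1, s), e))
  out$name <- .promoterName(ueName)
  out$ue <- ueName
  out$n_bins <- sum(runs$n_bins[included])
  prov <- c(GenomicRanges::granges(seed$components),
            GenomicRanges::granges(runs[included]))
  prov$kind <- c(seed$components$kind,
                 paste0("run_", runs$sign[included]))
  out$provenance <- S4Vectors::SimpleList(prov)
  out
}

.promoterName <- function(ueName) {
  if (grepl("^h", ueName)) paste0(sub("^h", "P", ueName), "*")
  else paste0("P_", ueName, "*")
}

#' Derive promoter regions for every UE in a catalogue
#'
#' One region per named untranslated exon; a warning is logged when derived
#' regions overlap each other.
#'
#' @param cat An \code{\link{EvidenceCatalogue}} with a constraint track.
#' @param params A \code{\link{derivationParams}} list.
#' @return \code{GRanges} of derived regions (metadata as in
#'   \code{\link{derivePromoterRegion}}).
#' @export
deriveAll <- function(cat, params = derivationParams()) {
  ues <- names(ueRanges(catGeneModel(cat)))
  regions <- lapply(ues, derivePromoterRegion, cat = cat, params = params)
  out <- do.call(c, regions)
  if (length(out) > 1) {
    ov <- GenomicRanges::findOverlaps(out, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov))
      warning(sprintf("derived promoter regions overlap: %s",
                      paste(sprintf("%s/%s", out$name[S4Vectors::queryHits(ov)],
                                    out$name[S4Vectors::subjectHits(ov)]),
                            collapse = ", ")))
  }
  names(out) <- out$name
  out
}
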