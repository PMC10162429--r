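#' Parameters for the synthetic locus simulator
#'
#' The generator emulates the statistical structure of the evidence the
#' integration consumes: a strand-aware gene model with alternative
#' untranslated first exons, a 10 bp binned constraint track with negative
#' troughs over functional elements on a positive noisy baseline,
#' negative-binomial CAGE tag counts with cell-type-specific activity,
#' per-source enhancer call sets with configurable sensitivity and
#' false-positive rate, and interaction loops joining enhancer truth to
#' promoter truth with cell-type structure. Defaults mirror the study
#' conditions: four sample groups of sizes 3/3/3/24 with two active groups,
#' six enhancer sources (one mouse-lifted) at sensitivity 0.9 and 1 false
#' positive per Mb, and three interaction cell types.
#'
#' @param locus_length Locus size in bp (default 4e5).
#' @param n_ues Number of untranslated first exons / promoters (default 3).
#' @param strand Gene strand (default "-").
#' @param ue_width,promoter_up,promoter_down Ranges (bp) for UE width and
#'   the upstream/downstream margins of the true promoter around its UE.
#' @param bin_width Constraint bin width in bp (default 10).
#' @param baseline_mean,baseline_sd Constraint score distribution outside
#'   functional elements (default N(0.5, 0.3)).
#' @param depressed_mean,depressed_sd Constraint score distribution over
#'   true promoters and enhancers (default N(-1.5, 0.3)).
#' @param groups Named integer vector of samples per group.
#' @param active_groups Groups with non-zero TSS activity.
#' @param activity_range Per-(TSS, active group) mean TPM is drawn uniformly
#'   from this range.
#' @param nb_dispersion Negative-binomial size parameter for tag counts.
#' @param depth_range Per-sample library depth range.
#' @param n_enhancers Number of true enhancers (default 5).
#' @param enhancer_width Enhancer width range (bp).
#' @param n_sources Number of enhancer call sources (the last is flagged
#'   mouse-lifted).
#' @param sensitivity Per-source probability of calling a true enhancer.
#' @param fp_per_mb Poisson rate of false-positive calls per Mb per source.
#' @param edge_jitter_sd SD (bp) of Gaussian jitter on called enhancer
#'   edges.
#' @param cell_types Interaction cell types.
#' @param p_link Probability that a (cell type, promoter, enhancer) triple
#'   is a true link.
#' @param loop_tp_rate Probability that a true link is represented by a
#'   loop.
#' @param background_loops Expected background (noise) loops per cell type.
#' @param seed Default random seed for \code{\link{simulateLocus}}.
#' @return A validated list of class \code{SimulationParams}.
#' @export
simulationParams <- function(locus_length = 4e5, n_ues = 3, strand = "-",
                             ue_width = c(200, 400),
                             promoter_up = c(800, 2500),
                             promoter_down = c(500, 800),
                             bin_width = 10,
                             baseline_mean = 0.5, baseline_sd = 0.3,
                             depressed_mean = -1.5, depressed_sd = 0.3,
                             groups = c(neuron = 3, `astrocyte-cortex` = 3,
                                        `astrocyte-cerebellum` = 3,
                                        `iPSC-neuron` = 24),
                             active_groups = c("neuron", "astrocyte-cortex"),
                             activity_range = c(1, 50),
                             nb_dispersion = 10,
                             depth_range = c(5e5, 2e6),
                             n_enhancers = 5,
                             enhancer_width = c(400, 1500),
                             n_sources = 6,
                             sensitivity = 0.9, fp_per_mb = 1,
                             edge_jitter_sd = 30,
                             cell_types = c("neuron", "oligodendrocyte",
                                            "microglia"),
                             p_link = 0.3, loop_tp_rate = 0.95,
                             background_loops = 2, seed = 0) {
  p <- as.list(environment())
  stopifnot(p$locus_length > 0, p$n_ues >= 1, p$bin_width >= 1,
            p$sensitivity >= 0, p$sensitivity <= 1,
            p$p_link >= 0, p$p_link <= 1,
            p$loop_tp_rate >= 0, p$loop_tp_rate <= 1,
            p$fp_per_mb >= 0, p$background_loops >= 0,
            all(p$depth_range > 0), all(p$ue_width > 0),
            p$nb_dispersion > 0)
  structure(p, class = "SimulationParams")
}

.runifInt <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Simulate a synthetic locus with known truth
#'
#' Deterministic under a fixed seed: each stage (geometry, constraint,
#' counts, enhancer calls, loops) reseeds from \code{seed + k} for stage
#' index k = 1..5 so stages can be re-simulated independently.
#'
#' @param params A \code{\link{simulationParams}} list.
#' @param seed Integer seed; defaults to \code{params$seed}.
#' @return List with elements \code{catalogue} (an
#'   \code{\link{EvidenceCatalogue}}) and \code{truth} (gene model, true
#'   promoters, enhancers, links, TSS activities).
#' @export
simulateLocus <- function(params = simulationParams(), seed = params$seed) {
  L <- params$locus_length
  bw <- params$bin_width
  chrom <- "chrS"

  ## stage 1: geometry -------------------------------------------------
  set.seed(seed + 1)
  cds_s <- floor(0.62 * L) + 1
  cds_e <- floor(0.80 * L)
  ue_names <- if (params$n_ues == 3) c("h1a", "h1b", "h1c") else
    paste0("h", seq_len(params$n_ues))
  spacing <- 25000
  max_prom <- params$promoter_down[2] + params$ue_width[2] +
    params$promoter_up[2] + bw
  need <- cds_e + 10000 + (params$n_ues - 1) * spacing + max_prom
  if (need > L)
    stop("simulation error: locus too short for the requested geometry")
  ue_list <- GenomicRanges::GRanges()
  truth_prom <- GenomicRanges::GRanges()
  tss_all <- data.frame()
  pls <- GenomicRanges::GRanges()
  constructs <- GenomicRanges::GRanges()
  for (i in seq_len(params$n_ues)) {
    b <- cds_e + 10000 + (i - 1) * spacing
    down <- .runifInt(1, params$promoter_down[1], params$promoter_down[2])
    ue_w <- .runifInt(1, params$ue_width[1], params$ue_width[2])
    up <- .runifInt(1, params$promoter_up[1], params$promoter_up[2])
    raw_s <- b
    raw_e <- b + down + ue_w + up - 1
    snap_s <- floor((raw_s - 1) / bw) * bw + 1
    snap_e <- ceiling(raw_e / bw) * bw
    truth_prom <- c(truth_prom,
                    GenomicRanges::GRanges(chrom, IRanges::IRanges(snap_s, snap_e)))
    ue_s <- b + down
    ue <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ue_s, ue_s + ue_w - 1))
    names(ue) <- ue_names[i]
    ue_list <- c(ue_list, ue)
    k <- .runifInt(1, 1, 3)
    pos <- sort(.runifInt(k, ue_s, ue_s + ue_w - 1))
    pos <- unique(pos)
    tss_all <- rbind(tss_all, data.frame(
      tss_id = sprintf("TSS:%d", pos), chrom = chrom, pos = pos,
      source = "CAGE", ue = ue_names[i], discordant = FALSE,
      stringsAsFactors = FALSE))
    if (stats::runif(1) < 0.7) {
      ps <- max(snap_s, ue_s - 100); pe <- min(snap_e, ue_s + ue_w + 99)
      pg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ps, pe))
      pg$name <- paste0("PLS_", ue_names[i])
      pls <- c(pls, pg)
    }
    ci <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ue_s + ue_w, raw_e))
    ci$kb <- GenomicRanges::width(ci) / 1000
    ci$ue <- ue_names[i]
    ci$citation <- "simulated-assay"
    constructs <- c(constructs, ci)
  }
  names(truth_prom) <- vapply(ue_names, .promoterName, character(1))

  ex1 <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cds_s, cds_s + 1999))
  ex2 <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cds_e - 1999, cds_e))
  tx <- lapply(seq_len(params$n_ues), function(i) {
    ex <- c(ex1, ex2, GenomicRanges::granges(ue_list[i]))
    ex <- GenomicRanges::sort(ex)
    ex$translated <- GenomicRanges::start(ex) <= cds_e &
      GenomicRanges::end(ex) >= cds_s
    ex
  })
  names(tx) <- paste0("TX_", ue_names)
  gm <- GeneModel(geneName = "SIMGENE", geneStrand = params$strand,
                  transcripts = GenomicRanges::GRangesList(tx),
                  ues = ue_list,
                  cdsSpan = GenomicRanges::GRanges(chrom,
                                                   IRanges::IRanges(cds_s, cds_e)))

  # true enhancers in the distal zone downstream of the CDS
  zone_s <- cds_s - 240000
  zone_e <- cds_s - 30000
  slot <- floor((zone_e - zone_s + 1) / params$n_enhancers)
  enh <- GenomicRanges::GRanges()
  for (i in seq_len(params$n_enhancers)) {
    w <- .runifInt(1, params$enhancer_width[1], params$enhancer_width[2])
    s0 <- zone_s + (i - 1) * slot + .runifInt(1, 0, slot - w - 1)
    enh <- c(enh, GenomicRanges::GRanges(chrom, IRanges::IRanges(s0, s0 + w - 1)))
  }
  names(enh) <- sprintf("ENH_%02d", seq_along(enh))

  ## stage 2: constraint track ------------------------------------------
  set.seed(seed + 2)
  nbin <- ceiling(L / bw)
  bs <- (seq_len(nbin) - 1) * bw + 1
  be <- pmin(bs + bw - 1, L)
  bins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(bs, be))
  score <- stats::rnorm(nbin, params$baseline_mean, params$baseline_sd)
  functional <- GenomicRanges::reduce(c(GenomicRanges::granges(truth_prom),
                                        GenomicRanges::granges(enh)))
  dep <- IRanges::overlapsAny(bins, functional)
  score[dep] <- stats::rnorm(sum(dep), params$depressed_mean, params$depressed_sd)
  bins$score <- score
  track <- ConstraintTrack(bins, binWidth = bw)

  ## stage 3: tag counts -------------------------------------------------
  set.seed(seed + 3)
  n_tss <- nrow(tss_all)
  gnames <- names(params$groups)
  activities <- matrix(0, n_tss, length(gnames),
                       dimnames = list(tss_all$tss_id, gnames))
  for (g in intersect(params$active_groups, gnames))
    activities[, g] <- stats::runif(n_tss, params$activity_range[1],
                                    params$activity_range[2])
  samples <- unlist(lapply(gnames, function(g)
    sprintf("%s_s%02d", g, seq_len(params$groups[[g]]))))
  sgroup <- rep(gnames, times = unlist(params$groups))
  depth <- .runifInt(length(samples), params$depth_range[1], params$depth_range[2])
  counts <- matrix(0L, n_tss, length(samples),
                   dimnames = list(tss_all$tss_id, samples))
  for (j in seq_along(samples)) {
    mu <- activities[, sgroup[j]] * depth[j] / 1e6
    counts[, j] <- ifelse(mu == 0, 0L,
                          stats::rnbinom(n_tss, size = params$nb_dispersion, mu = mu))
  }
  smeta <- data.frame(sample = samples, group = sgroup, lib_total = depth,
                      stringsAsFactors = FALSE)

  ## stage 4: enhancer call sets ----------------------------------------
  set.seed(seed + 4)
  src_names <- paste0("source", seq_len(params$n_sources))
  species <- c(rep("human", params$n_sources - 1), "mouse-lifted")
  sets <- list()
  for (k in seq_len(params$n_sources)) {
    det <- stats::runif(length(enh)) < params$sensitivity
    calls <- GenomicRanges::GRanges()
    if (any(det)) {
      ds <- GenomicRanges::start(enh[det]) +
        round(stats::rnorm(sum(det), 0, params$edge_jitter_sd))
      de <- GenomicRanges::end(enh[det]) +
        round(stats::rnorm(sum(det), 0, params$edge_jitter_sd))
      ds <- pmax(1, pmin(ds, de - 1))
      calls <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ds, pmax(de, ds + 1)))
    }
    nfp <- stats::rpois(1, params$fp_per_mb * L / 1e6)
    if (nfp > 0) {
      w <- .runifInt(nfp, params$enhancer_width[1], params$enhancer_width[2])
      s0 <- .runifInt(nfp, 1, L - max(w) - 1)
      calls <- c(calls, GenomicRanges::GRanges(chrom, IRanges::IRanges(s0, s0 + w - 1)))
    }
    calls <- GenomicRanges::sort(calls)
    S4Vectors::metadata(calls)$species <- species[k]
    sets[[src_names[k]]] <- calls
  }

  ## stage 5: interaction loops ------------------------------------------
  set.seed(seed + 5)
  links <- expand.grid(cell_type = params$cell_types,
                       promoter = names(truth_prom),
                       enhancer = seq_along(enh),
                       stringsAsFactors = FALSE)
  links <- links[stats::runif(nrow(links)) < params$p_link, , drop = FALSE]
  a_list <- GenomicRanges::GRanges(); b_list <- GenomicRanges::GRanges()
  cells <- character(0)
  if (nrow(links)) {
    has_loop <- stats::runif(nrow(links)) < params$loop_tp_rate
    for (i in which(has_loop)) {
      pa <- GenomicRanges::granges(truth_prom[links$promoter[i]])
      pb <- GenomicRanges::granges(enh[links$enhancer[i]])
      if (stats::runif(1) < 0.5) { tmp <- pa; pa <- pb; pb <- tmp }
      a_list <- c(a_list, pa); b_list <- c(b_list, pb)
      cells <- c(cells, links$cell_type[i])
    }
  }
  for (ct in params$cell_types) {
    nbg <- stats::rpois(1, params$background_loops)
    if (nbg > 0) {
      s1 <- .runifInt(nbg, 1, L - 1000)
      s2 <- .runifInt(nbg, 1, L - 1000)
      a_list <- c(a_list, GenomicRanges::GRanges(chrom, IRanges::IRanges(s1, s1 + 999)))
      b_list <- c(b_list, GenomicRanges::GRanges(chrom, IRanges::IRanges(s2, s2 + 999)))
      cells <- c(cells, rep(ct, nbg))
    }
  }
  loops <- if (length(a_list))
    S4Vectors::Pairs(a_list, b_list, cell_type = cells,
                     source = rep("simulated", length(cells)),
                     loop_id = sprintf("loop%04d", seq_along(cells)))
  else emptyLoops()

  catalogue <- EvidenceCatalogue(
    geneModel = gm, tss = tss_all, pls = pls, constructs = constructs,
    constraint = track, enhancerSets = sets, loops = loops,
    counts = counts, sampleMeta = smeta, assembly = "simulated")
  truth <- structure(list(
    gene_model = gm, promoters = truth_prom, enhancers = enh,
    links = links, tss = tss_all, activities = activities,
    seed = seed), class = "LocusTruth")
  list(catalogue = catalogue, truth = truth)
}

#' Base-pair Jaccard index between two interval sets
#'
#' \code{|A intersect B| / |A union B|} in bp; 0 when the union is empty.
#'
#' @param a,b \code{GRanges}.
#' @return Numeric in [0, 1].
#' @export
intervalJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(GenomicRanges::`strand<-`(GenomicRanges::granges(a), value = "*"))
  b <- GenomicRanges::reduce(GenomicRanges::`strand<-`(GenomicRanges::granges(b), value = "*"))
  u <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
  if (u == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::intersect(a, b))) / u
}

#' Score derived outputs against simulated truth
#'
#' Promoter boundaries are scored per region by base-pair Jaccard; enhancer
#' detection by precision/recall of corroborated candidates at a support
#' threshold (any-overlap matching against true enhancers); links by
#' precision/recall of detected (cell type, promoter, enhancer) triples
#' against true links, a predicted link matching when its enhancer interval
#' overlaps the true link's enhancer.
#'
#' @param derived_promoters Named \code{GRanges} of derived regions.
#' @param truth A \code{LocusTruth} from \code{\link{simulateLocus}}.
#' @param candidates Optional corroborated candidates (with
#'   \code{support_count}).
#' @param links Optional predicted link table from
#'   \code{\link{linkInteractions}}.
#' @param support_threshold Minimum support count for an enhancer
#'   prediction (default 2: corroborated by at least two sources).
#' @return List of metrics, all in [0, 1] (NA where undefined).
#' @export
recoveryReport <- function(derived_promoters, truth, candidates = NULL,
                           links = NULL, support_threshold = 2) {
  pj <- vapply(names(truth$promoters), function(nm) {
    if (!nm %in% names(derived_promoters)) return(0)
    intervalJaccard(derived_promoters[nm], truth$promoters[nm])
  }, numeric(1))
  out <- list(promoter_jaccard = pj, mean_jaccard = mean(pj))
  if (!is.null(candidates)) {
    pred <- GenomicRanges::reduce(
      GenomicRanges::granges(candidates[candidates$support_count >= support_threshold]))
    out$enhancer_precision <- if (length(pred) == 0) NA_real_ else
      mean(IRanges::overlapsAny(pred, truth$enhancers))
    out$enhancer_recall <- if (length(truth$enhancers) == 0) NA_real_ else
      mean(IRanges::overlapsAny(truth$enhancers, pred))
  }
  if (!is.null(links)) {
    tl <- truth$links
    if (nrow(links) == 0) {
      out$link_precision <- NA_real_
      out$link_recall <- if (nrow(tl) == 0) NA_real_ else 0
    } else {
      pred_gr <- GenomicRanges::GRanges(links$enh_chrom,
                                        IRanges::IRanges(links$enh_start, links$enh_end))
      match_pred <- vapply(seq_len(nrow(links)), function(i) {
        sel <- tl$cell_type == links$cell_type[i] & tl$promoter == links$promoter[i]
        any(sel) && any(IRanges::overlapsAny(truth$enhancers[tl$enhancer[sel]],
                                             pred_gr[i]))
      }, logical(1))
      match_truth <- vapply(seq_len(nrow(tl)), function(i) {
        sel <- links$cell_type == tl$cell_type[i] & links$promoter == tl$promoter[i]
        any(sel) && any(IRanges::overlapsAny(pred_gr[sel],
                                             truth$enhancers[tl$enhancer[i]]))
      }, logical(1))
      out$link_precision <- mean(match_pred)
      out$link_recall <- if (nrow(tl) == 0) NA_real_ else mean(match_truth)
    }
  }
  out
}
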