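test_that("sign runs partition the track into maximal same-sign blocks", {
  runs <- classifySignRuns(toyTrack(c(-1, -1, 2, -3)))
  expect_equal(start(runs), c(1, 21, 31))
  expect_equal(end(runs), c(20, 30, 40))
  expect_equal(runs$sign, c("negative", "non-negative", "negative"))
  expect_equal(runs$n_bins, c(2L, 1L, 1L))

  allneg <- classifySignRuns(toyTrack(rep(-0.5, 8)))
  expect_equal(length(allneg), 1)
  expect_equal(c(start(allneg), end(allneg)), c(1, 80))

  set.seed(19)
  for (i in 1:120) {
    sc <- rnorm(sample.int(30, 1))
    got <- classifySignRuns(toyTrack(sc))
    want <- bruteSignRuns(sc)
    expect_equal(start(got), want$start)
    expect_equal(end(got), want$end)
    expect_equal(got$sign, want$sign)
    expect_equal(got$n_bins, want$n_bins)
    # runs partition the track extent, alternating in sign
    expect_equal(sum(width(got)), length(sc) * 10)
    if (length(got) > 1)
      expect_true(all(got$sign[-1] != got$sign[-length(got)]))
  }
})

test_that("the seed is the hull of the UE, evidence, and downstream extension", {
  ue <- fromExternal("chr1", 101, 130)
  exper <- fromExternal("chr1", 41, 160)
  # plus strand, downstream extension 20 extends right but hull already covers
  s <- buildSeed(ue, experimental = exper, geneStrand = "+",
                 params = derivationParams(downstream_ext = 20))
  expect_equal(c(start(s$hull), end(s$hull)), c(41, 160))

  # minus strand: downstream piece extends the hull leftward
  s2 <- buildSeed(ue, geneStrand = "-",
                  params = derivationParams(downstream_ext = 20))
  expect_equal(c(start(s2$hull), end(s2$hull)), c(81, 130))

  expect_error(buildSeed(GenomicRanges::GRanges()), "derivation error")

  set.seed(23)
  for (i in 1:100) {
    ue_s <- sample(200:400, 1); ue_e <- ue_s + sample.int(50, 1)
    n_t <- sample(0:3, 1); n_e <- sample(0:2, 1)
    tpos <- if (n_t) sample(150:500, n_t) else integer(0)
    es <- if (n_e) sample(100:450, n_e) else integer(0)
    pad <- sample(0:80, 1); ext <- sample(0:200, 1)
    strand_ <- sample(c("+", "-"), 1)
    tss <- if (n_t) fromExternal("chr1", tpos, tpos) else GenomicRanges::GRanges()
    exper <- if (n_e) fromExternal("chr1", es, es + 30) else GenomicRanges::GRanges()
    s <- buildSeed(fromExternal("chr1", ue_s, ue_e), tss = tss,
                   experimental = exper, geneStrand = strand_,
                   params = derivationParams(seed_pad = pad, downstream_ext = ext))
    # brute-force min/max over all component endpoints
    lo <- c(ue_s, if (n_t) pmax(1, tpos - pad), if (n_e) es,
            if (ext > 0 && strand_ == "-") max(1, ue_s - ext))
    hi <- c(ue_e, if (n_t) tpos + pad, if (n_e) es + 30,
            if (ext > 0 && strand_ == "+") ue_e + ext)
    expect_equal(c(start(s$hull), end(s$hull)), c(min(lo), max(hi)))
  }
})

test_that("the worked constraint locus derives by the stated rule", {
  # negative on [1,120] and [151,200], non-negative on [121,150]; UE [61,90];
  # experimental [41,160] overlaps the non-negative run -> it is bridged and
  # the far negative run joins: output is the whole locus
  p <- derivePromoterRegion("h1", toyCatalogue(),
                            derivationParams(downstream_ext = 0))
  expect_equal(c(start(p), end(p)), c(1, 200))
  expect_equal(p$n_bins, 20L)
  expect_equal(p$name, "P1*")
  prov <- p$provenance[[1]]
  expect_setequal(unique(prov$kind),
                  c("ue", "pls", "experimental", "run_negative",
                    "run_non-negative"))

  # experimental ending at 110 no longer overlaps the non-negative run:
  # no bridge, the far negative run stays out
  p2 <- derivePromoterRegion("h1", toyCatalogue(exp_end = 110),
                             derivationParams(downstream_ext = 0))
  expect_equal(c(start(p2), end(p2)), c(1, 120))
  expect_false("run_non-negative" %in% p2$provenance[[1]]$kind)

  # an all-negative track collapses the rule to the single run's extent
  p3 <- derivePromoterRegion("h1", toyCatalogue(scores = rep(-1, 20)),
                             derivationParams(downstream_ext = 0))
  expect_equal(c(start(p3), end(p3)), c(1, 200))
})

test_that("derivation invariants hold: containment, monotonicity, determinism", {
  params <- derivationParams(downstream_ext = 0)
  cat1 <- toyCatalogue(exp_end = 110)
  p1 <- derivePromoterRegion("h1", cat1, params)
  ue <- ueRanges(catGeneModel(cat1))["h1"]
  expect_true(start(p1) <= start(ue) && end(p1) >= end(ue))
  # experimental evidence overlapping the output is never truncated
  cons <- experimentalConstructs(cat1)
  expect_true(start(p1) <= start(cons) && end(p1) >= end(cons))

  # enlarging the experimental evidence never shrinks the region
  p_big <- derivePromoterRegion("h1", toyCatalogue(exp_end = 160), params)
  expect_true(start(p_big) <= start(p1) && end(p_big) >= end(p1))

  # without experimental evidence, no non-negative bins beyond the seed hull
  cat_noexp <- toyCatalogue()
  cat_noexp@constructs <- GenomicRanges::GRanges()
  p_ne <- derivePromoterRegion("h1", cat_noexp, params)
  runs <- classifySignRuns(constraintTrack(cat_noexp))
  pos_runs <- runs[runs$sign == "non-negative"]
  seed_hull <- fromExternal("chr1", 56, 95)  # hull of UE and PLS
  outside <- GenomicRanges::setdiff(pos_runs, seed_hull, ignore.strand = TRUE)
  expect_equal(sum(width(GenomicRanges::intersect(
    GenomicRanges::granges(p_ne), outside, ignore.strand = TRUE))), 0)

  # bit-identical reruns
  expect_identical(ranges(derivePromoterRegion("h1", cat1, params)),
                   ranges(p1))
})

test_that("derivation errors are specific about the failing UE", {
  cat <- toyCatalogue()
  expect_error(derivePromoterRegion("h9", cat), "h9")
  # constraint track not covering the seed
  short <- toyCatalogue(scores = rep(-1, 3))  # track [1,30] only
  expect_error(derivePromoterRegion("h1", short, derivationParams()),
               "coverage error.*h1")
  nocons <- toyCatalogue()
  nocons@constraint <- NULL
  expect_error(derivePromoterRegion("h1", nocons), "coverage error")
})

test_that("per-UE derivation covers a whole simulated locus", {
  sim <- simulateLocus(simulationParams(), seed = 0)
  pr <- deriveAll(sim$catalogue)
  expect_equal(length(pr), 3)
  ues <- ueRanges(catGeneModel(sim$catalogue))
  for (i in seq_along(pr)) {
    u <- ues[pr$ue[i]]
    expect_true(start(pr[i]) <= start(u) && end(pr[i]) >= end(u))
  }
  # regions are bin-aligned to the 10 bp track
  expect_true(all((start(pr) - 1) %% 10 == 0))
  expect_true(all(end(pr) %% 10 == 0))
})
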