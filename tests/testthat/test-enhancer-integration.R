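test_that("corroboration counts supporting sources by any-bp overlap", {
  cand <- fromExternal("chr1", c(1000, 5000), c(1500, 5400))
  sets <- list(
    A = cand,                                   # origin
    B = fromExternal("chr1", c(1400, 5300), c(1600, 5600)),
    C = fromExternal("chr1", 900, 1100),
    D = fromExternal("chr1", 8000, 9000)
  )
  got <- corroborate(cand, sets, origin = "A")
  expect_equal(got$support_count, c(3L, 2L))
  expect_identical(as.list(got$support), list(c("A", "B", "C"), c("A", "B")))
  expect_true(all(vapply(as.list(got$support), function(s) "A" %in% s,
                         logical(1))))  # origin in its own support

  solo <- corroborate(cand[1], list(A = cand[1]), origin = "A")
  expect_equal(solo$support_count, 1L)

  # support is monotone non-decreasing in the call sets supplied
  fewer <- corroborate(cand, sets[1:2], origin = "A")
  expect_true(all(got$support_count >= fewer$support_count))

  # a minimum-overlap threshold can demand more than one shared bp
  one_bp <- list(A = cand[1], B = fromExternal("chr1", 1500, 1600))
  expect_equal(corroborate(cand[1], one_bp, "A")$support_count, 2L)
  expect_equal(corroborate(cand[1], one_bp, "A", min_overlap = 2)$support_count, 1L)
})

test_that("the SCN1A far enhancers lack high-confidence and mouse support", {
  cat <- loadScn1aCatalogue()
  sets <- enhancerSets(cat)
  got <- corroborate(sets$GRN, sets, origin = "GRN")
  far <- grepl("far", got$name)
  expect_equal(sum(far), 2)
  expect_equal(unique(got$support_count[far]), 4L)
  for (s in as.list(got$support[far])) {
    expect_false("high-confidence" %in% s)
    expect_false("cross-species" %in% s)
  }
  expect_equal(unique(got$support_count[!far]), 6L)
  expect_true(all(got$high_confidence[!far]))
  expect_false(any(got$high_confidence[far]))
})

test_that("proximity classification uses the min gap to the CDS span", {
  cat <- loadScn1aCatalogue()
  gm <- catGeneModel(cat)
  cds <- cdsSpan(gm)

  at250 <- fromExternal("chr2", start(cds) - 251000, start(cds) - 250001)
  got <- classifyProximity(at250, gm)
  expect_equal(got$distance_bp, 250000)
  expect_equal(got$proximity, "near")

  inside <- fromExternal("chr2", start(cds) + 10, start(cds) + 500)
  got2 <- classifyProximity(inside, gm)
  expect_equal(got2$distance_bp, 0)
  expect_equal(got2$proximity, "near")

  grn <- classifyProximity(enhancerSets(cat)$GRN, gm)
  expect_equal(as.integer(table(grn$proximity)[c("near", "far")]), c(7L, 2L))
  expect_true(all(grn$distance_bp[grn$proximity == "far"] > 7e5))

  expect_error(classifyProximity(fromExternal("chr9", 1, 10), gm),
               "distance undefined")
  expect_error(classifyProximity(at250, gm, near = 0), "near > 0")

  # randomized placements against a brute-force min-gap scan;
  # distance is 0 iff the candidate overlaps the CDS span
  set.seed(37)
  cs <- start(cds); ce <- end(cds)
  pos <- sample(seq(cs - 2e6, ce + 2e6, by = 997), 150)
  cands <- fromExternal("chr2", pos, pos + 499)
  d <- classifyProximity(cands, gm)$distance_bp
  want <- vapply(seq_along(pos), function(i) {
    if (pos[i] + 499 < cs) cs - (pos[i] + 499) - 1
    else if (pos[i] > ce) pos[i] - ce - 1
    else 0
  }, numeric(1))
  expect_equal(d, want)
  expect_identical(d == 0,
                   as.logical(intervalsOverlap(cands, rep(cds, length(cands)))))
})

test_that("links require one anchor on the promoter and one on the enhancer", {
  prom <- fromExternal("chr1", c(10000, 30000), c(12000, 32000))
  names(prom) <- c("P1c*", "P1a*")
  enh <- fromExternal("chr1", 90000, 91000)

  loops <- S4Vectors::Pairs(
    fromExternal("chr1", c(10500, 90200, 50000), c(11500, 90800, 51000)),
    fromExternal("chr1", c(90100, 30100, 70000), c(90900, 31000, 71000)),
    cell_type = c("oligodendrocyte", "neuron", "microglia"),
    source = rep("placseq", 3),
    loop_id = c("l1", "l2", "l3"))

  got <- linkInteractions(loops, prom, enh)
  expect_equal(nrow(got), 2)
  # anchor orientation does not matter: l2 has the enhancer in anchor_a
  expect_setequal(got$cell_type, c("oligodendrocyte", "neuron"))
  expect_equal(got$promoter[got$cell_type == "oligodendrocyte"], "P1c*")
  expect_equal(got$n_loops, c(1L, 1L))
  # the microglia loop touches no promoter: no microglia link
  expect_false("microglia" %in% got$cell_type)

  # swapping every loop's anchors leaves the link set unchanged
  swapped <- S4Vectors::Pairs(S4Vectors::second(loops),
                              S4Vectors::first(loops),
                              cell_type = S4Vectors::mcols(loops)$cell_type,
                              source = S4Vectors::mcols(loops)$source,
                              loop_id = S4Vectors::mcols(loops)$loop_id)
  expect_identical(linkInteractions(swapped, prom, enh), got)

  expect_equal(nrow(linkInteractions(emptyLoops(), prom, enh)), 0)
})

test_that("random loops match a brute-force all-pairs anchor test", {
  set.seed(41)
  prom <- fromExternal("chr1", c(1000, 4000, 8000), c(1900, 4900, 8900))
  names(prom) <- paste0("P", 1:3)
  enh <- fromExternal("chr1", c(20000, 25000), c(20800, 25800))
  n <- 120
  a_s <- sample.int(30000, n); b_s <- sample.int(30000, n)
  cells <- sample(c("neuron", "oligodendrocyte", "microglia"), n, replace = TRUE)
  loops <- S4Vectors::Pairs(fromExternal("chr1", a_s, a_s + 500),
                            fromExternal("chr1", b_s, b_s + 500),
                            cell_type = cells, source = rep("x", n),
                            loop_id = sprintf("l%03d", seq_len(n)))
  got <- linkInteractions(loops, prom, enh)

  ovl <- function(s1, e1, s2, e2) max(s1, s2) <= min(e1, e2)
  want <- character(0)
  for (p in seq_along(prom)) for (e in seq_along(enh)) for (l in seq_len(n)) {
    pa <- ovl(a_s[l], a_s[l] + 500, start(prom)[p], end(prom)[p]) &&
      ovl(b_s[l], b_s[l] + 500, start(enh)[e], end(enh)[e])
    pb <- ovl(b_s[l], b_s[l] + 500, start(prom)[p], end(prom)[p]) &&
      ovl(a_s[l], a_s[l] + 500, start(enh)[e], end(enh)[e])
    if (pa || pb)
      want <- c(want, paste(names(prom)[p], e, cells[l], sep = "|"))
  }
  got_keys <- rep(paste(got$promoter,
                        match(got$enh_start, start(enh)),
                        got$cell_type, sep = "|"), got$n_loops)
  expect_setequal(got_keys, want)
  expect_equal(sum(got$n_loops), length(want))
})

test_that("the cell-type table is complete and zero-filled", {
  empty <- linkInteractions(emptyLoops(), GenomicRanges::GRanges(),
                            GenomicRanges::GRanges())
  tab0 <- linkTableByCellType(empty, cell_types = c("neuron", "microglia"),
                              promoters = c("P1a*", "P1b*"))
  expect_true(all(tab0 == 0))
  expect_equal(dim(tab0), c(2, 2))

  one <- data.frame(promoter = "P1a*", enh_chrom = "chr1", enh_start = 1,
                    enh_end = 10, cell_type = "neuron", n_loops = 2,
                    loop_ids = "l1,l2")
  tab1 <- linkTableByCellType(one, cell_types = c("neuron", "microglia"),
                              promoters = c("P1a*", "P1b*"))
  expect_equal(tab1["neuron", "P1a*"], 1L)
  expect_equal(sum(tab1), 1L)
})
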