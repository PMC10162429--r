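test_that("external 1-based inclusive coordinates convert losslessly", {
  p1a <- fromExternal("chr2", 166148180, 166151550, "-")
  expect_equal(width(p1a), 3371)
  expect_equal(start(p1a), 166148180)

  single <- fromExternal("chr1", 5, 5, "+")
  expect_equal(width(single), 1)

  expect_error(fromExternal("chr1", 10, 9, "+"), "coordinate error")
  expect_error(fromExternal("chr1", 0, 4), "coordinate error")
  expect_error(fromExternal("chr1", -3, 4), "coordinate error")

  set.seed(42)
  for (i in 1:100) {
    s <- sample.int(1e6, 1); e <- s + sample.int(1000, 1) - 1
    gr <- fromExternal("chrX", s, e)
    ext <- toExternal(gr)
    expect_equal(c(ext$start, ext$end), c(s, e))
    back <- fromExternal(ext$chrom, ext$start, ext$end)
    expect_equal(width(back), e - s + 1)
  }
})

test_that("interval overlap is any-bp, half-open-adjacency-safe, symmetric", {
  a <- fromExternal("chr1", 1, 10)   # [0,10) in half-open terms
  b <- fromExternal("chr1", 11, 20)  # [10,20): adjacent, no shared base
  expect_false(intervalsOverlap(a, b))
  c_ <- fromExternal("chr1", 10, 20) # [9,20): one shared base
  expect_true(intervalsOverlap(a, c_))
  expect_true(intervalsOverlap(c_, a))
  expect_false(intervalsOverlap(a, fromExternal("chr2", 1, 10)))

  set.seed(7)
  for (i in 1:1000) {
    s1 <- sample.int(200, 1); e1 <- s1 + sample.int(30, 1) - 1
    s2 <- sample.int(200, 1); e2 <- s2 + sample.int(30, 1) - 1
    got <- intervalsOverlap(fromExternal("chr1", s1, e1),
                            fromExternal("chr1", s2, e2))
    expect_identical(got, bruteOverlap(s1, e1, s2, e2))
    expect_identical(got, intervalsOverlap(fromExternal("chr1", s2, e2),
                                           fromExternal("chr1", s1, e1)))
  }
})

test_that("merge bridges gaps up to the bound and matches the mask oracle", {
  abutting <- c(fromExternal("chr1", 1, 10), fromExternal("chr1", 11, 20))
  m <- mergeWithGap(abutting, gap = 0)
  expect_equal(length(m), 1)
  expect_equal(c(start(m), end(m)), c(1, 20))

  apart <- c(fromExternal("chr1", 1, 10), fromExternal("chr1", 16, 20))
  expect_equal(length(mergeWithGap(apart, gap = 4)), 2)  # gap of 5 > 4
  expect_equal(length(mergeWithGap(apart, gap = 5)), 1)

  expect_equal(length(mergeWithGap(GenomicRanges::GRanges(), 0)), 0)

  set.seed(11)
  for (i in 1:100) {
    n <- sample.int(8, 1)
    s <- sample.int(150, n, replace = TRUE)
    e <- s + sample.int(20, n, replace = TRUE) - 1
    gap <- sample(0:6, 1)
    gr <- fromExternal("chr1", s, e)
    got <- mergeWithGap(gr, gap)
    want <- bruteMerge(s, e, gap)
    expect_equal(cbind(start = start(got), end = end(got)), want,
                 ignore_attr = TRUE)
    # idempotent and order-invariant
    expect_identical(ranges(mergeWithGap(got, gap)), ranges(got))
    shuf <- gr[sample(length(gr))]
    expect_identical(ranges(mergeWithGap(shuf, gap)), ranges(got))
  }
})

test_that("encompassment requires exact abutment on both sides", {
  a <- fromExternal("chr1", 121, 150)
  both <- c(fromExternal("chr1", 1, 120), fromExternal("chr1", 151, 200))
  expect_true(encompassedBy(a, both))
  expect_false(encompassedBy(a, both[1]))
  expect_false(encompassedBy(a, GenomicRanges::GRanges()))
  gapped <- c(fromExternal("chr1", 1, 119), fromExternal("chr1", 151, 200))
  expect_false(encompassedBy(a, gapped))

  set.seed(13)
  for (i in 1:100) {
    s <- sample(50:100, 1); e <- s + sample.int(40, 1)
    a <- fromExternal("chr1", s, e)
    left_end <- s - 1 + sample(c(0, -1, 1), 1)
    right_start <- e + 1 + sample(c(0, -1, 1), 1)
    f <- c(fromExternal("chr1", 1, max(1, left_end)),
           fromExternal("chr1", right_start, right_start + 30))
    want <- (left_end == s - 1) && (right_start == e + 1)
    expect_identical(encompassedBy(a, f), want)
    if (want) {
      merged <- mergeWithGap(c(a, f), gap = 0)
      expect_equal(length(merged), 1)  # flanks fuse with a
    }
  }
})

test_that("BED, bedGraph and BEDPE round-trip through disk", {
  tmp <- withr::local_tempdir()
  bed <- file.path(tmp, "x.bed")
  writeLines("chr2\t166148179\t166151550\tP1a*", bed)
  gr <- readBed(bed)
  expect_equal(c(start(gr), end(gr)), c(166148180, 166151550))
  expect_equal(gr$name, "P1a*")

  empty <- file.path(tmp, "empty.bed")
  writeLines(character(0), empty)
  expect_equal(length(readBed(empty)), 0)

  set.seed(17)
  s <- sample.int(1e5, 100); e <- s + sample.int(500, 100)
  recs <- fromExternal("chr3", s, e)
  recs$name <- sprintf("r%03d", 1:100)
  rt <- file.path(tmp, "rt.bed")
  writeBed(recs, rt)
  back <- readBed(rt)
  expect_identical(ranges(back), ranges(recs))
  expect_identical(back$name, recs$name)

  bg <- file.path(tmp, "x.bedgraph")
  sc <- round(stats::rnorm(50), 4)
  scored <- fromExternal("chr1", seq(1, by = 10, length.out = 50),
                         seq(10, by = 10, length.out = 50))
  scored$score <- sc
  writeBedGraph(scored, bg)
  back <- readBedGraph(bg)
  expect_equal(back$score, sc)
  expect_identical(ranges(back), ranges(scored))

  bad <- file.path(tmp, "bad.bed")
  writeLines(c("track name=x", "chr1\t1\t10\ta", "chr1\t5"), bad)
  expect_error(readBed(bad), "line 3")
})

test_that("BEDPE loops round-trip and trans pairs are rejected", {
  tmp <- withr::local_tempdir()
  pe <- file.path(tmp, "loops.bedpe")
  writeLines(c("chr1\t100\t200\tchr1\t5000\t5100\tneuron\tplacseq",
               "chr1\t300\t400\tchr1\t9000\t9100\toligodendrocyte\tplacseq"),
             pe)
  loops <- readBedpe(pe)
  expect_equal(length(loops), 2)
  expect_equal(S4Vectors::mcols(loops)$cell_type,
               c("neuron", "oligodendrocyte"))
  expect_equal(start(S4Vectors::first(loops))[1], 101)

  rt <- file.path(tmp, "rt.bedpe")
  writeBedpe(loops, rt)
  back <- readBedpe(rt)
  expect_identical(ranges(S4Vectors::first(back)),
                   ranges(S4Vectors::first(loops)))
  expect_identical(S4Vectors::mcols(back)$cell_type,
                   S4Vectors::mcols(loops)$cell_type)

  trans <- file.path(tmp, "trans.bedpe")
  writeLines("chr1\t100\t200\tchr2\t5000\t5100\tneuron\tx", trans)
  expect_error(readBedpe(trans), "trans-chromosomal")
  expect_equal(length(readBedpe(trans, allow_trans = TRUE)), 1)
})
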