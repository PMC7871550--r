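test_that("block inference applies the consecutive-SNV rule literally", {
  sl <- c(chr1 = 1000)
  vm <- VariantMap("chr1", c(100, 200, 300, 400, 500),
                   rep("A", 5), rep("G", 5), sl)
  calls <- simulateSegregantCalls(uniformMosaic("BY", sl), vm)
  blocks <- inferBlocks(calls, vm, minRun = 5)
  # one BY block [100, 500] flanked by unassigned [1,99] and [501,1000]
  expect_equal(length(blocks), 3L)
  expect_equal(as.character(S4Vectors::mcols(blocks)$origin),
               c("unassigned", "BY", "unassigned"))
  expect_equal(BiocGenerics::start(blocks), c(1, 100, 501))
  expect_equal(BiocGenerics::end(blocks), c(99, 500, 1000))
  expect_equal(S4Vectors::mcols(blocks)$nSupportingSNVs[2], 5L)
  # four consecutive calls stay below the run threshold
  vm4 <- VariantMap("chr1", c(100, 200, 300, 400), rep("A", 4),
                    rep("G", 4), sl)
  calls4 <- simulateSegregantCalls(uniformMosaic("AWRI", sl), vm4)
  b4 <- inferBlocks(calls4, vm4, minRun = 5)
  expect_equal(as.character(S4Vectors::mcols(b4)$origin), "unassigned")
  expect_equal(BiocGenerics::width(b4), 1000)
})

test_that("block inference matches a run-scan oracle and tiles the genome", {
  set.seed(61)
  sl <- c(chr1 = 50000)
  for (rep in 1:25) {
    n <- sample(30:80, 1)
    pos <- sort(sample.int(50000, n))
    vm <- VariantMap("chr1", pos, rep("A", n), rep("G", n), sl)
    call <- sample(c("BY", "AWRI"), n, replace = TRUE,
                   prob = c(0.7, 0.3))
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                 call = factor(call,
                                               levels = c("BY", "AWRI")),
                                 seqinfo = GenomeInfoDb::Seqinfo("chr1",
                                                                 50000))
    calls <- new("SegregantCalls", gr)
    blocks <- inferBlocks(calls, vm, minRun = 4)
    # tiling invariant: no gaps, no overlaps, full coverage
    expect_equal(BiocGenerics::start(blocks)[1], 1)
    expect_equal(BiocGenerics::end(blocks)[length(blocks)], 50000)
    expect_true(all(BiocGenerics::start(blocks)[-1] ==
                      BiocGenerics::end(blocks)[-length(blocks)] + 1))
    assigned <- blocks[S4Vectors::mcols(blocks)$origin != "unassigned"]
    orc <- oracleRunBlocks(pos, call, 4)
    if (is.null(orc)) {
      expect_length(assigned, 0L)
    } else {
      expect_equal(BiocGenerics::start(assigned), orc$start)
      expect_equal(BiocGenerics::end(assigned), orc$end)
      expect_equal(as.character(S4Vectors::mcols(assigned)$origin),
                   orc$origin)
      expect_equal(S4Vectors::mcols(assigned)$nSupportingSNVs, orc$n)
    }
  }
})

test_that("block inference is a fixed point under call regeneration", {
  vm <- tinyMap(500, seed = 62)
  pool <- simulateSegregants(tinyGmap(), 5, seed = 63)
  regen <- function(blocks) {
    assigned <- blocks[S4Vectors::mcols(blocks)$origin != "unassigned"]
    hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(vm),
                                        assigned)
    gr <- GenomicRanges::granges(vm)[S4Vectors::queryHits(hits)]
    S4Vectors::mcols(gr)$call <-
      factor(as.character(S4Vectors::mcols(assigned)$origin)[
        S4Vectors::subjectHits(hits)], levels = c("BY", "AWRI"))
    new("SegregantCalls", gr)
  }
  sameBlocks <- function(a, b) {
    expect_equal(BiocGenerics::start(a), BiocGenerics::start(b))
    expect_equal(BiocGenerics::end(a), BiocGenerics::end(b))
    expect_equal(as.character(S4Vectors::mcols(a)$origin),
                 as.character(S4Vectors::mcols(b)$origin))
  }
  for (i in 1:5) {
    # error-free calls: regeneration reproduces the blocks directly
    clean <- simulateSegregantCalls(mosaic(pool, i), vm)
    b1 <- inferBlocks(clean, vm)
    sameBlocks(inferBlocks(regen(b1), vm), b1)
    # with miscalls, one regeneration reaches the fixed point
    noisy <- simulateSegregantCalls(mosaic(pool, i), vm,
                                    miscallRate = 0.02, seed = 64 + i)
    b2 <- inferBlocks(regen(inferBlocks(noisy, vm)), vm)
    sameBlocks(inferBlocks(regen(b2), vm), b2)
  }
})

test_that("error-free inference recovers the generating mosaic", {
  vm <- tinyMap(900, seed = 66)  # ~3 SNVs per kbp: runs are long
  pool <- simulateSegregants(tinyGmap(), 8, seed = 67)
  for (i in 1:8) {
    m <- mosaic(pool, i)
    blocks <- inferBlocks(simulateSegregantCalls(m, vm), vm)
    assigned <- blocks[S4Vectors::mcols(blocks)$origin != "unassigned"]
    mid <- floor((BiocGenerics::start(assigned) +
                    BiocGenerics::end(assigned)) / 2)
    truth <- originAt(m, as.character(GenomeInfoDb::seqnames(assigned)),
                      mid)
    expect_identical(as.character(S4Vectors::mcols(assigned)$origin),
                     truth)
  }
})

test_that("donor fractions equal a base-counting oracle", {
  m <- tinyMosaic()
  expect_equal(donorFraction(m, "AWRI"), 100 * 220000 / 320000)
  expect_equal(donorFraction(m, "BY"), 100 * 100000 / 320000)
  expect_equal(donorFraction(uniformMosaic("AWRI", tinyLengths()), "AWRI"),
               100)
  expect_equal(donorFraction(uniformMosaic("BY", tinyLengths()), "AWRI"), 0)
  # GRanges block path with unassigned intervals and both denominators
  sl <- c(chr1 = 1000)
  blocks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 101, 501), c(100, 500, 1000)),
    origin = factor(c("unassigned", "AWRI", "BY"),
                    levels = c("BY", "AWRI", "unassigned")),
    seqinfo = GenomeInfoDb::Seqinfo("chr1", 1000))
  expect_equal(donorFraction(blocks, "AWRI"), 40)
  expect_equal(donorFraction(blocks, "AWRI", denominator = "assigned"),
               100 * 400 / 900)
  # excluding a duplicated segment removes it from both sides
  dup <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 500))
  expect_equal(donorFraction(blocks, "AWRI", exclude = dup),
               100 * 300 / 900)
  noneAssigned <- blocks[1]
  expect_error(donorFraction(noneAssigned, "AWRI",
                             denominator = "assigned"), "no assigned")
})

test_that("the drift expectation halves per generation", {
  expect_equal(expectedDonorFraction(1), 50)
  expect_equal(expectedDonorFraction(7), 0.78125)
  expect_equal(round(expectedDonorFraction(7), 1), 0.8)
  g <- 1:10
  expect_equal(expectedDonorFraction(g + 1), expectedDonorFraction(g) / 2)
  expect_error(expectedDonorFraction(0), ">= 1")
})

test_that("backcrossing retains marker regions and selected QTLs", {
  gm <- tinyGmap()
  marker <- data.frame(chrom = "chrA", pos = 30000)
  # markers forced to the donor (BY) origin in an AWRI-recurrent lineage
  bc <- runBackcross(gm, recurrent = "AWRI", generations = 4, nPerGen = 8,
                     model = TraitModel(noiseSD = 1), markerLoci = marker,
                     markerOrigin = "BY", seed = 68)
  for (m in lineageMosaics(bc))
    expect_identical(originAt(m, "chrA", 30000), "BY")
  expect_equal(lineageSummary(bc)$generation, 2:4)
  # a strong donor-beneficial QTL is retained under top-FI selection
  qtl <- TraitModel(baseline = 100,
                    loci = data.frame(chrom = "chrB", pos = 60000,
                                      effectBY = 0, effectAWRI = 30),
                    noiseSD = 3)
  retained <- vapply(1:15, function(s) {
    set.seed(100 + s)
    # the founder is the best-FI F1 segregant, as in a real lineage
    f1 <- simulateSegregants(gm, 30)
    founder <- mosaic(f1, selectTop(traitValues(f1, qtl), 1))
    bc <- runBackcross(gm, founder = founder, recurrent = "BY",
                       generations = 5, nPerGen = 12, model = qtl,
                       seed = 200 + s)
    originAt(lineageMosaics(bc)[["F5"]], "chrB", 60000) == "AWRI"
  }, logical(1))
  expect_gte(mean(retained), 0.9)
  expect_error(runBackcross(gm, generations = 1), ">= 2")
})

test_that("backcross lineages can report inferred blocks per generation", {
  vm <- tinyMap(700, seed = 69)
  bc <- runBackcross(tinyGmap(), generations = 3, nPerGen = 5,
                     model = TraitModel(noiseSD = 1), map = vm, seed = 70)
  expect_named(lineageBlocks(bc), c("F2", "F3"))
  b <- lineageBlocks(bc)[["F3"]]
  expect_true(all(S4Vectors::mcols(b)$origin %in%
                    c("BY", "AWRI", "unassigned")))
  # inferred donor fraction tracks the true mosaic's donor fraction
  trueDon <- lineageSummary(bc)$donorFractionPct[2]
  infDon <- donorFraction(b, "AWRI")
  expect_lt(abs(trueDon - infDon), 5)
})

test_that("depth-based duplication calls recover a planted segment", {
  set.seed(71)
  ws <- 1000
  nw <- 500
  start0 <- (seq_len(nw) - 1L) * ws
  # windowed depth = reads in window / window length (per-base coverage)
  depth <- rpois(nw, 100 * ws) / ws
  inDup <- start0 >= 150000 & start0 < 350000
  depth[inDup] <- rpois(sum(inDup), 200 * ws) / ws
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start0 + 1, start0 + ws),
                               depth = depth)
  flat <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(start0 + 1, start0 + ws),
                                 depth = rpois(nw, 100 * ws) / ws)
  expect_length(detectDuplication(flat), 0L)
  calls <- detectDuplication(gr, foldThreshold = 1.5, minLen = 50000)
  expect_length(calls, 1L)
  planted <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150001, 350000))
  ov <- GenomicRanges::intersect(calls, planted)
  expect_gte(sum(BiocGenerics::width(ov)) / 200000, 0.9)
  expect_gt(S4Vectors::mcols(calls)$meanFold, 1.5)
  expect_length(detectDuplication(gr, foldThreshold = Inf), 0L)
  zero <- gr
  S4Vectors::mcols(zero)$depth <- 0
  expect_error(detectDuplication(zero), "zero")
})
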