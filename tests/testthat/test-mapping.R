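test_that("allele ratios apply the pseudocount rule site by site", {
  pc <- PoolCounts("chrA", c(100, 200, 300),
                   nBY = c(10, 20, 0), nAWRI = c(10, 0, 0),
                   seqlengths = tinyLengths())
  ar0 <- suppressMessages(alleleRatio(pc, pseudocount = 0))
  expect_length(ar0, 2L)  # zero-depth site dropped
  expect_equal(S4Vectors::mcols(ar0)$ratioAWRIBY[1], 1)
  expect_equal(S4Vectors::mcols(ar0)$freqAWRI[1], 0.5)
  ar <- suppressMessages(alleleRatio(pc, pseudocount = 0.5))
  expect_equal(S4Vectors::mcols(ar)$ratioAWRIBY[2], 0.5 / 20.5)
  # vectorized output equals a per-site loop on random counts
  set.seed(41)
  nb <- rpois(1000, 30); na <- rpois(1000, 25)
  pc2 <- PoolCounts("chrA", sort(sample.int(2e5, 1000)), nb, na,
                    seqlengths = tinyLengths())
  ar2 <- suppressMessages(alleleRatio(pc2, 0.5))
  keep <- nb + na > 0
  expect_equal(S4Vectors::mcols(ar2)$ratioAWRIBY,
               ((na + 0.5) / (nb + 0.5))[keep])
  expect_equal(S4Vectors::mcols(ar2)$freqAWRI, (na / (na + nb))[keep])
  expect_error(alleleRatio(pc[0]), "empty")
})

test_that("window medians agree with a brute-force oracle and leave gaps", {
  # constructed: one window with {1, 2, 9} has median 2
  pc <- PoolCounts("chrA", c(1000, 2000, 3000, 45000),
                   nBY = c(10, 10, 2, 5), nAWRI = c(10, 20, 18, 5),
                   seqlengths = tinyLengths())
  ar <- alleleRatio(pc, pseudocount = 0)
  w <- windowMedian(ar, 10000)
  expect_equal(S4Vectors::mcols(w)$medianRatio[1], 2)
  expect_equal(S4Vectors::mcols(w)$nSNVs, c(3L, 1L))
  # windows 2-4 of chrA carry no SNV: a gap, not zero entries
  expect_equal(BiocGenerics::start(w), c(1, 40001))
  # random instance vs oracle
  set.seed(42)
  vm <- tinyMap(800, seed = 43)
  pool <- simulateSegregants(tinyGmap(), 150, seed = 44)
  ar2 <- alleleRatio(poolSequencing(pool, vm, 80, seed = 45))
  w2 <- windowMedian(ar2, 10000)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(ar2)),
                   pos = BiocGenerics::start(ar2),
                   ratio = S4Vectors::mcols(ar2)$ratioAWRIBY,
                   freq = S4Vectors::mcols(ar2)$freqAWRI)
  orc <- oracleWindowMedian(df, 10000, tinyLengths())
  expect_equal(length(w2), nrow(orc))
  expect_equal(S4Vectors::mcols(w2)$medianRatio, orc$medianRatio)
  expect_equal(S4Vectors::mcols(w2)$medianFreq, orc$medianFreq)
  expect_equal(BiocGenerics::start(w2), orc$start)
  # last window of chrA (200 kb) is full width; chrB (120 kb) exact tiling
  expect_true(all(BiocGenerics::end(w2) <= tinyLengths()[
    as.character(GenomeInfoDb::seqnames(w2))]))
  # unsorted input is rejected, not silently sorted
  shuffled <- ar2[c(2, 1, 3:length(ar2))]
  expect_error(windowMedian(shuffled, 10000), "sorted")
})

test_that("delta tracks subtract average from selected where both exist", {
  vm <- tinyMap(600, seed = 46)
  pool <- simulateSegregants(tinyGmap(), 200, seed = 47)
  w1 <- windowMedian(alleleRatio(poolSequencing(pool, vm, 90, seed = 48)))
  expect_equal(S4Vectors::mcols(poolDelta(w1, w1))$delta,
               rep(0, length(w1)))
  w2 <- windowMedian(alleleRatio(poolSequencing(pool, vm, 90, seed = 49)))
  d <- poolDelta(w1, w2)
  key <- paste0(GenomeInfoDb::seqnames(d), ":", BiocGenerics::start(d))
  k1 <- paste0(GenomeInfoDb::seqnames(w1), ":", BiocGenerics::start(w1))
  k2 <- paste0(GenomeInfoDb::seqnames(w2), ":", BiocGenerics::start(w2))
  expect_setequal(key, intersect(k1, k2))
  expect_equal(S4Vectors::mcols(d)$delta,
               S4Vectors::mcols(w1)$medianFreq[match(key, k1)] -
                 S4Vectors::mcols(w2)$medianFreq[match(key, k2)])
  wbad <- windowMedian(alleleRatio(poolSequencing(pool, vm, 90, seed = 50)),
                       windowSize = 5000)
  expect_error(poolDelta(w1, wbad), "window sizes")
})

test_that("the null threshold shrinks with depth and is reproducible", {
  sl <- c(chr1 = 150000)
  vm <- buildParentalMap(300, sl, seed = 51)
  gm <- uniformGeneticMap(0.345, sl)
  thr <- vapply(c(50, 200, 800), function(d) {
    nullThreshold(vm, gm, poolSizes = c(500, 500), meanDepths = c(d, d),
                  nSims = 20, seed = 52)
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_equal(nullThreshold(vm, gm, c(500, 500), c(50, 50), nSims = 20,
                             seed = 52), thr[1])
  expect_error(nullThreshold(vm, gm, c(10, 10), c(50, 50), nSims = 5),
               ">= 20")
})

test_that("peak calling equals an exhaustive run-scan oracle", {
  mkDelta <- function(delta, chrom, startWin, ws = 10000,
                      sl = c(chrZ = 1e6, chrY = 1e6)) {
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(startWin * ws + 1, (startWin + 1) * ws),
      delta = delta,
      seqinfo = GenomeInfoDb::Seqinfo(names(sl), unname(sl)))
    gr <- BiocGenerics::sort(gr)
    S4Vectors::metadata(gr)$windowSize <- ws
    gr
  }
  flat <- mkDelta(rep(0, 10), "chrZ", 0:9)
  expect_length(callPeaks(flat, 0.2), 0L)
  one <- mkDelta(c(0, 0.3, 0.31, 0.3, 0), "chrZ", 0:4)
  pk <- callPeaks(one, 0.2, minWindows = 2)
  expect_length(pk, 1L)
  expect_equal(BiocGenerics::start(pk), 10001)
  expect_equal(BiocGenerics::end(pk), 40000)
  expect_equal(S4Vectors::mcols(pk)$enrichedParent, "AWRI")
  expect_equal(S4Vectors::mcols(pk)$apexDelta, 0.31)
  # sign flips split runs; below-minWindows runs are dropped
  set.seed(53)
  for (rep in 1:30) {
    n <- 40
    wins <- sort(sample(0:60, n))
    chrom <- sample(c("chrZ", "chrY"), n, replace = TRUE)
    d <- round(rnorm(n, 0, 0.25), 2)
    d[d == 0] <- 0.01
    gr <- mkDelta(d, chrom, wins)
    got <- callPeaks(gr, 0.2, minWindows = 2)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     delta = S4Vectors::mcols(gr)$delta)
    orc <- oraclePeaks(df, 0.2, 2, 10000)
    if (is.null(orc)) {
      expect_length(got, 0L)
    } else {
      expect_equal(length(got), nrow(orc))
      expect_equal(BiocGenerics::start(got), orc$start)
      expect_equal(BiocGenerics::end(got), orc$end)
      expect_equal(S4Vectors::mcols(got)$nWindows, orc$nWindows)
      expect_equal(ifelse(S4Vectors::mcols(got)$enrichedParent == "AWRI",
                          1, -1), orc$sign)
    }
  }
})

test_that("allele enrichment counts genotyped strains at a locus", {
  vm <- tinyMap(100, seed = 54)
  m <- tinyMosaic()
  chrom <- as.character(GenomeInfoDb::seqnames(vm))
  pos <- BiocGenerics::start(vm)
  target <- which(chrom == "chrB")[1]  # AWRI in tinyMosaic
  callsA <- lapply(1:7, function(i)
    simulateSegregantCalls(m, vm, id = paste0("s", i)))
  mBY <- uniformMosaic("BY", tinyLengths())
  callsB <- lapply(1:3, function(i)
    simulateSegregantCalls(mBY, vm, id = paste0("t", i)))
  rep <- alleleEnrichment(c(callsA, callsB), chrom[target], pos[target])
  expect_equal(rep$nAWRI, 7)
  expect_equal(rep$nBY, 3)
  expect_equal(rep$pctAWRI, 70)
  expect_equal(rep$pctBY + rep$pctAWRI, 100)
  expect_error(alleleEnrichment(callsA, "chrA", 999999), "uncalled")
})

test_that("marker hitchhiking distorts both pools but cancels in the delta", {
  sl <- c(chrM = 300000)
  vm <- buildParentalMap(600, sl, seed = 55)
  gm <- uniformGeneticMap(0.345, sl)
  marker <- data.frame(chrom = "chrM", pos = 150000)
  mkPool <- function(seed) {
    p <- simulateSegregants(gm, 3000, seed = seed)
    suppressMarkerMessages(applyMarkerSelection(p, marker, "BY"))
  }
  pa <- mkPool(56)
  ps <- mkPool(57)
  fa <- poolAlleleFreq(pa, vm)
  near <- abs(BiocGenerics::start(vm) - 150000) < 5000
  expect_lt(max(fa[near]), 0.05)  # strong BY distortion at the marker
  wa <- windowMedian(alleleRatio(poolSequencing(pa, vm, 738, seed = 58)))
  ws <- windowMedian(alleleRatio(poolSequencing(ps, vm, 1407, seed = 59)))
  d <- poolDelta(ws, wa)
  # absent trait selection the distortion subtracts out
  expect_lt(max(abs(S4Vectors::mcols(d)$delta)), 0.08)
})
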