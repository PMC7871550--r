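test_that("an all-BY pool sequenced without error yields no AWRI reads", {
  vm <- tinyMap(200)
  pc <- poolSequencing(list(uniformMosaic("BY", tinyLengths())), vm,
                       meanDepth = 50, errorRate = 0, seed = 1)
  expect_true(all(S4Vectors::mcols(pc)$nAWRI == 0L))
  expect_identical(poolLabel(pc), "custom")
})

test_that("sequencing depth concentrates at its Poisson target", {
  vm <- tinyMap(500)
  pool <- simulateSegregants(tinyGmap(), 100, seed = 2)
  pc <- poolSequencing(pool, vm, meanDepth = 120, seed = 3,
                       poolLabel = "average")
  depth <- S4Vectors::mcols(pc)$nBY + S4Vectors::mcols(pc)$nAWRI
  expect_lt(abs(mean(depth) - 120), 3 * sqrt(120 / 500))
  expect_equal(meanTargetDepth(pc), 120)
})

test_that("deep error-free sequencing recovers exact pool frequencies", {
  vm <- tinyMap(300)
  # pool of one BY and one AWRI genome: true f = 0.5 everywhere
  pool <- list(uniformMosaic("BY", tinyLengths()),
               uniformMosaic("AWRI", tinyLengths()))
  pc <- poolSequencing(pool, vm, meanDepth = 1e5, errorRate = 0, seed = 4)
  f <- S4Vectors::mcols(pc)$nAWRI /
    (S4Vectors::mcols(pc)$nBY + S4Vectors::mcols(pc)$nAWRI)
  expect_true(all(abs(f - 0.5) < 0.005))
  # a random pool at depth 1e5 matches its true frequencies to 0.5 %
  pool2 <- simulateSegregants(tinyGmap(), 40, seed = 5)
  truef <- poolAlleleFreq(pool2, vm)
  pc2 <- poolSequencing(pool2, vm, meanDepth = 1e5, errorRate = 0, seed = 6)
  f2 <- S4Vectors::mcols(pc2)$nAWRI /
    (S4Vectors::mcols(pc2)$nBY + S4Vectors::mcols(pc2)$nAWRI)
  expect_true(all(abs(f2 - truef) < 0.005))
})

test_that("sequencing error pulls frequencies toward 1/2", {
  vm <- tinyMap(400)
  pc <- poolSequencing(list(uniformMosaic("BY", tinyLengths())), vm,
                       meanDepth = 2000, errorRate = 0.01, seed = 7)
  f <- S4Vectors::mcols(pc)$nAWRI /
    (S4Vectors::mcols(pc)$nBY + S4Vectors::mcols(pc)$nAWRI)
  expect_lt(abs(mean(f) - 0.01), 3 * sqrt(0.01 * 0.99 / (2000 * 400)))
})

test_that("pool sequencing rejects invalid arguments", {
  vm <- tinyMap(50)
  expect_error(poolSequencing(list(), vm, 100), "empty pool")
  pool <- list(uniformMosaic("BY", tinyLengths()))
  expect_error(poolSequencing(pool, vm, 0), "meanDepth")
  expect_error(poolSequencing(pool, vm, 10, errorRate = 0.5), "errorRate")
})

test_that("pool frequencies match a per-genome counting oracle", {
  vm <- tinyMap(120)
  pool <- simulateSegregants(tinyGmap(2), 60, seed = 8)
  f <- poolAlleleFreq(pool, vm)
  chrom <- as.character(GenomeInfoDb::seqnames(vm))
  pos <- BiocGenerics::start(vm)
  direct <- vapply(seq_along(pos), function(j) {
    mean(vapply(seq_len(60), function(i)
      originAt(mosaic(pool, i), chrom[j], pos[j]) == "AWRI", logical(1)))
  }, numeric(1))
  expect_equal(f, direct)
})

test_that("segregant calls reflect the mosaic, its errors and its gaps", {
  vm <- tinyMap(500)
  m <- tinyMosaic()
  truth <- originAt(m, as.character(GenomeInfoDb::seqnames(vm)),
                    BiocGenerics::start(vm))
  exact <- simulateSegregantCalls(m, vm, 0, 0, seed = 1, id = "s1")
  expect_length(exact, 500L)
  expect_identical(as.character(S4Vectors::mcols(exact)$call), truth)
  # miscalls land in the binomial band around rate * sites
  noisy <- simulateSegregantCalls(m, vm, miscallRate = 0.05, seed = 2)
  flips <- sum(as.character(S4Vectors::mcols(noisy)$call) != truth)
  expect_lt(abs(flips - 25), 3 * sqrt(500 * 0.05 * 0.95))
  # full missingness empties the call set
  empty <- simulateSegregantCalls(m, vm, missingRate = 1, seed = 3)
  expect_length(empty, 0L)
})
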