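test_that("the NL proxy is stain gain per cell density", {
  expect_equal(nlProxy(0.5, 100, 600), 1000)
  expect_equal(nlProxy(2, 300, 300), 0)
  expect_error(nlProxy(0, 1, 2), "od600")
  # vectorized evaluation equals a per-well loop
  set.seed(21)
  od <- runif(50, 0.2, 1)
  pre <- runif(50, 0, 100)
  post <- pre + rnorm(50, 500, 100)
  expect_equal(nlProxy(od, pre, post),
               vapply(1:50, function(i) (post[i] - pre[i]) / od[i],
                      numeric(1)))
})

test_that("plate normalization scales to the on-plate reference mean", {
  rec <- data.frame(
    plate = rep(c("P1", "P2"), each = 3),
    well = c("A1", "A2", "A3", "A1", "A2", "A3"),
    strain = c("Y7092", "Y7092", "s1", "Y7092", "Y7092", "s2"),
    od600 = 1,
    fi_pre = 0,
    fi_post = c(90, 110, 150, 180, 220, 150))
  out <- plateNormalize(rec)
  # reference wells average to 1 on each plate
  expect_equal(mean(out$normalized[out$strain == "Y7092" &
                                     out$plate == "P1"]), 1)
  # identical raw value 150 normalizes to 1.5 vs 0.75 across plates
  expect_equal(out$normalized[out$strain == "s1"], 1.5)
  expect_equal(out$normalized[out$strain == "s2"], 0.75)
  # well order does not matter
  perm <- rec[sample(nrow(rec)), ]
  out2 <- plateNormalize(perm)
  expect_equal(out2$normalized[match(paste(out$plate, out$well),
                                     paste(out2$plate, out2$well))],
               out$normalized)
  # a plate without reference wells is a named error
  rec$strain[rec$plate == "P2"] <- "sX"
  expect_error(plateNormalize(rec), "P2")
  expect_error(plateNormalize(rec[, -4]), "missing column")
})

test_that("binning is equal-width on log2 with a linear class mapping", {
  set.seed(22)
  vals <- 2^runif(500, -1, 1)
  h <- binDistribution(vals, nBins = 100, byParentValue = 1,
                       awriParentValue = 1.5)
  expect_equal(sum(h@counts), 500L)
  expect_length(h@breaks, 101L)
  w <- diff(h@breaks)
  expect_lt(diff(range(w)), 1e-12)
  # exact linearity of the class<->log2 mapping
  cls <- c(10, 40, 90)
  lv <- classLog2(cls, c(1, 101), range(h@breaks))
  expect_equal((lv[2] - lv[1]) / (cls[2] - cls[1]),
               (lv[3] - lv[2]) / (cls[3] - cls[2]))
  # anchors recorded and recoverable
  expect_equal(unname(h@anchors["classBY"]), classOf(h, 1))
  # a value on an interior right edge belongs to the right bin
  h2 <- binDistribution(c(1, 2, 4), nBins = 2)
  expect_identical(classOf(h2, 2), 2L)
  expect_identical(classOf(h2, 4), 2L)  # top edge stays in the last bin
  expect_error(binDistribution(rep(2, 5)), "degenerate")
  expect_error(binDistribution(c(1, -1, 2)), "positive")
})

test_that("transgressive fractions partition the sample exactly", {
  tf <- transgressiveFractions(c(1, 2, 3, 4), 1.5, 3.5)
  expect_equal(unname(tf), c(25, 50, 25))
  expect_equal(sum(tf), 100)
  none <- transgressiveFractions(c(2, 2.5, 3), 1.5, 3.5)
  expect_equal(unname(none[c(1, 3)]), c(0, 0))
  expect_warning(tfs <- transgressiveFractions(1:4, 3.5, 1.5), "swap")
  expect_equal(unname(tfs), c(25, 50, 25))
  expect_error(transgressiveFractions(numeric(0), 1, 2), "empty")
})

test_that("lipid totals follow the reporting convention", {
  expect_equal(lipidTotal(28.1, 12.5), 40.6)
  expect_equal(lipidTotal(28.1, 12.5, ca = TRUE), 41)
  expect_equal(lipidTotal(0, 0), 0)
})

test_that("the two-sample t-test matches the closed form and conventions", {
  set.seed(23)
  a <- rnorm(8, 10, 2)
  b <- rnorm(12, 11, 2)
  expect_equal(twoTailedTTest(a, b), oracleStudentT(a, b))
  expect_equal(twoTailedTTest(a, a), 1)
  expect_equal(twoTailedTTest(c(1, 1, 1), c(1, 1)), 1)
  expect_equal(twoTailedTTest(c(1, 1, 1), c(2, 2)), 0)
  # p-value decreases monotonically as the shift grows
  ps <- vapply(c(0.5, 2, 5, 20), function(d) twoTailedTTest(a, b + d),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # Welch flag reproduces the unequal-variance test
  expect_equal(twoTailedTTest(a, b, welch = TRUE),
               t.test(a, b)$p.value)
  expect_error(twoTailedTTest(1, b), "at least 2")
})

test_that("histogram shape is invariant to per-plate rescaling", {
  set.seed(24)
  fi <- 2^rnorm(150, 0.4, 0.3) * 114
  plates <- simulatePlateData(fi, byParentFI = 114, awriParentFI = 180.13,
                              plateGainSD = 0, seed = 25)
  norm1 <- plateNormalize(plates)
  scaled <- plates
  scale <- ifelse(scaled$plate == "P01", 3.7, 1)  # one plate re-gained
  scaled$fi_pre <- scaled$fi_pre * scale
  scaled$fi_post <- scaled$fi_post * scale
  norm2 <- plateNormalize(scaled)
  expect_equal(norm2$normalized, norm1$normalized)
  sam1 <- norm1$normalized[!(norm1$strain %in% c("Y7092", "AWRI1631"))]
  h1 <- binDistribution(sam1, 100)
  h2 <- binDistribution(norm2$normalized[!(norm2$strain %in%
                                             c("Y7092", "AWRI1631"))], 100)
  expect_identical(h1@counts, h2@counts)
})
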