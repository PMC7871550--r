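# Microplate Nile Red phenotyping: raw plate-reader OD/fluorescence tables
# are turned into a per-well neutral-lipid proxy, scaled to on-plate
# reference-strain replicates, and summarised as a 100-class log2 frequency
# distribution with parental anchor classes.

#' Neutral-lipid proxy from plate-reader readings
#'
#' `(fiPost - fiPre) / od600`: the gain in Nile Red fluorescence on
#' staining, normalized to the well's cell density.  Negative values
#' (post-stain reading below pre-stain) are possible and retained; they are
#' excluded later from log2 binning.
#'
#' @param od600 cell density (absorbance, must be > 0).
#' @param fiPre,fiPost fluorescence before / after staining.
#' @return numeric vector of FI/OD values.
#' @examples
#' nlProxy(0.5, 100, 600)  # 1000
#' @export
nlProxy <- function(od600, fiPre, fiPost) {
  if (any(!is.finite(od600)) || any(od600 <= 0))
    stop("invalid measurement: od600 must be > 0")
  (fiPost - fiPre) / od600
}

#' Normalize a plate dataset to its on-plate reference strain
#'
#' Adds `nl_proxy` and `normalized` columns.  `normalized` is each well's
#' `nl_proxy` divided by the mean `nl_proxy` of the reference-strain
#' replicates on the *same* plate, making plates comparable (the study uses
#' four Y7092 replicates per plate).
#'
#' @param records data.frame with columns `plate`, `well`, `strain`,
#'   `od600`, `fi_pre`, `fi_post`.
#' @param referenceStrain strain id of the on-plate reference.
#' @return the input with `nl_proxy` and `normalized` columns added.
#' @export
plateNormalize <- function(records, referenceStrain = "Y7092") {
  need <- c("plate", "well", "strain", "od600", "fi_pre", "fi_post")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records$nl_proxy <- nlProxy(records$od600, records$fi_pre,
                              records$fi_post)
  nneg <- sum(records$nl_proxy < 0)
  if (nneg > 0)
    message(nneg, " well(s) with negative nl_proxy retained (flagged)")
  refmean <- tapply(records$nl_proxy[records$strain == referenceStrain],
                    records$plate[records$strain == referenceStrain], mean)
  plates <- unique(records$plate)
  noref <- setdiff(as.character(plates), names(refmean))
  if (length(noref))
    stop("no reference-strain ('", referenceStrain, "') wells on plate(s): ",
         paste(noref, collapse = ", "))
  records$normalized <- records$nl_proxy /
    unname(refmean[as.character(records$plate)])
  records
}

#' 100-class log2 frequency distribution of normalized FI
#'
#' Bins `log2(values)` into `nBins` equally sized intervals spanning
#' `[min, max]` of the data (or an explicit `limits`, for a common range
#' across panels).  A value on an interior right edge falls in the bin to
#' its right; the final bin is closed on both sides.
#'
#' @param values positive normalized FI values.
#' @param nBins number of classes (default 100).
#' @param limits optional length-2 log2 range to bin over (values outside
#'   it are an error); default the data range.
#' @param byParentValue,awriParentValue optional parental normalized FI
#'   values; when given, their classes are recorded as anchors.
#' @return an [NLHistogram-class].
#' @export
binDistribution <- function(values, nBins = 100, limits = NULL,
                            byParentValue = NULL, awriParentValue = NULL) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("invalid measurement: all values must be positive for log2 binning (",
         sum(values <= 0 | !is.finite(values)), " offending value(s))")
  if (length(values) < 2L) stop("need at least 2 values")
  lv <- log2(values)
  if (is.null(limits)) limits <- range(lv)
  if (diff(limits) <= 0)
    stop("degenerate range: all values equal, cannot form equal-width bins")
  if (any(lv < limits[1L] | lv > limits[2L]))
    stop("values outside the binning limits")
  breaks <- seq(limits[1L], limits[2L], length.out = nBins + 1L)
  idx <- .classIndex(lv, limits, nBins)
  counts <- tabulate(idx, nbins = nBins)
  anchors <- numeric()
  if (!is.null(byParentValue))
    anchors <- c(anchors, classBY = .classIndex(log2(byParentValue),
                                                limits, nBins))
  if (!is.null(awriParentValue))
    anchors <- c(anchors, classAWRI = .classIndex(log2(awriParentValue),
                                                  limits, nBins))
  new("NLHistogram", breaks = breaks, counts = as.integer(counts),
      anchors = anchors)
}

# 1-based class of a log2 value; right edges belong to the right bin
# except the final bin
.classIndex <- function(lv, limits, nBins) {
  w <- diff(limits) / nBins
  as.integer(pmin(pmax(floor((lv - limits[1L]) / w) + 1L, 1L), nBins))
}

#' Class of a value in an existing histogram
#'
#' @param hist an [NLHistogram-class].
#' @param value positive normalized FI value(s).
#' @return integer class indices (1-based).
#' @export
classOf <- function(hist, value) {
  .classIndex(log2(value), range(hist@breaks), length(hist@counts))
}

#' Linear class-to-log2 mapping from two anchor classes
#'
#' The class index and the log2 FI scale are affinely related; given two
#' anchor pairs (e.g. the class of the BY parent at log2 = 0 and of the
#' AWRI parent at log2 = 0.66) any class converts to its log2 value by
#' linear interpolation.
#'
#' @param class class index (vectorized).
#' @param anchorClass length-2 vector of anchor class indices.
#' @param anchorLog2 length-2 vector of the anchors' log2 values.
#' @return log2 values along `class`.
#' @examples
#' classLog2(c(54, 66), c(44, 62), c(0, 0.66))  # ~0.37, ~0.81
#' @export
classLog2 <- function(class, anchorClass, anchorLog2) {
  stopifnot(length(anchorClass) == 2L, length(anchorLog2) == 2L,
            diff(anchorClass) != 0)
  slope <- diff(anchorLog2) / diff(anchorClass)
  anchorLog2[1L] + (class - anchorClass[1L]) * slope
}

#' Transgressive-segregation fractions
#'
#' Percentages of segregants strictly below the low-FI parent and strictly
#' above the high-FI parent -- progeny outside the parental range indicate
#' antagonistic alleles in both parental backgrounds.
#'
#' @param values segregant phenotype values.
#' @param byParentValue,awriParentValue parental values; if the BY value is
#'   not the lower one, the roles are swapped with a warning.
#' @return named numeric: `pctBelowLow`, `pctBetween`, `pctAboveHigh`
#'   (summing to 100).
#' @export
transgressiveFractions <- function(values, byParentValue, awriParentValue) {
  if (!length(values)) stop("empty sample set")
  if (byParentValue >= awriParentValue) {
    warning("BY parent value is not the lower one; swapping parent roles")
    tmp <- byParentValue
    byParentValue <- awriParentValue
    awriParentValue <- tmp
  }
  below <- 100 * mean(values < byParentValue)
  above <- 100 * mean(values > awriParentValue)
  c(pctBelowLow = below, pctBetween = 100 - below - above,
    pctAboveHigh = above)
}

#' Total neutral lipids from TAG and SE means
#'
#' @param tagMean,seMean triacylglycerol and steryl-ester means
#'   (mg per g cell dry weight).
#' @param ca round to the nearest integer, matching the "ca." reporting
#'   convention for totals.
#' @return total NL in mg/g CDW.
#' @examples
#' lipidTotal(28.1, 12.5)            # 40.6
#' lipidTotal(28.1, 12.5, ca = TRUE) # 41
#' @export
lipidTotal <- function(tagMean, seMean, ca = FALSE) {
  tot <- tagMean + seMean
  if (ca) round(tot) else tot
}

#' Two-tailed two-sample t-test p-value
#'
#' Student's equal-variance t-test by default (Welch by flag).  The
#' degenerate case of two zero-variance samples is resolved by convention:
#' p = 1 for equal means, p = 0 otherwise.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param welch use the Welch unequal-variance variant.
#' @return two-sided p-value.
#' @export
twoTailedTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (var(a) == 0 && var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  t.test(a, b, var.equal = !welch)$p.value
}

#' Simulate microplate reader data for a set of segregants
#'
#' Lays out segregant FI values onto 96-well plates with reference-strain
#' replicates (four wells each of the BY-background reference and the AWRI
#' parent per plate, as in the study design), applies a per-plate
#' multiplicative gain, and generates OD and pre-/post-stain fluorescence
#' readings such that [plateNormalize()] recovers the value relative to
#' the reference strain.
#'
#' @param fi true per-segregant FI values (arbitrary units).
#' @param ids segregant ids (default `seg1..segN`).
#' @param byParentFI,awriParentFI true FI of the two reference strains.
#' @param wellsPerPlate wells per plate (default 96).
#' @param refReplicates reference replicates per strain per plate.
#' @param plateGainSD SD of the lognormal per-plate gain.
#' @param odMean,odSD distribution of well OD600.
#' @param fiPreMean,fiPreSD distribution of pre-stain fluorescence.
#' @param readNoiseSD additive noise on the post-stain reading.
#' @param seed optional integer seed.
#' @return data.frame with columns `plate`, `well`, `strain`, `od600`,
#'   `fi_pre`, `fi_post`.
#' @export
simulatePlateData <- function(fi, ids = NULL, byParentFI = 108,
                              awriParentFI = 170.6, wellsPerPlate = 96,
                              refReplicates = 4, plateGainSD = 0.15,
                              odMean = 0.5, odSD = 0.05,
                              fiPreMean = 50, fiPreSD = 5,
                              readNoiseSD = 0, seed = NULL) {
  .setSeed(seed)
  n <- length(fi)
  if (is.null(ids)) ids <- paste0("seg", seq_len(n))
  perPlate <- wellsPerPlate - 2L * refReplicates
  if (perPlate < 1L) stop("no sample wells left on the plate")
  nPlates <- ceiling(n / perPlate)
  rows <- list()
  k <- 0L
  for (p in seq_len(nPlates)) {
    take <- seq.int(k + 1L, min(k + perPlate, n))
    k <- k + length(take)
    strain <- c(rep("Y7092", refReplicates),
                rep("AWRI1631", refReplicates), ids[take])
    true <- c(rep(byParentFI, refReplicates),
              rep(awriParentFI, refReplicates), fi[take])
    gain <- exp(rnorm(1, 0, plateGainSD))
    od <- pmax(rnorm(length(true), odMean, odSD), 0.05)
    pre <- pmax(rnorm(length(true), fiPreMean, fiPreSD), 0)
    post <- pre + true * gain * od +
      if (readNoiseSD > 0) rnorm(length(true), 0, readNoiseSD) else 0
    rows[[p]] <- data.frame(
      plate = sprintf("P%02d", p),
      well = paste0(rep(LETTERS[1:8], length.out = length(true)),
                    rep(seq_len(ceiling(length(true) / 8)), each = 8)[
                      seq_along(true)]),
      strain = strain, od600 = od, fi_pre = pre, fi_post = post)
  }
  do.call(rbind, rows)
}
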