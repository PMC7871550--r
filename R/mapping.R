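# X-QTL mapping: per-SNV parental allele ratios from two pooled-sequencing
# count tables, 10 kbp windowed medians, the selected-minus-average
# difference track, and candidate QTL peak calling against a simulated
# selection-free null.

#' Per-SNV parental allele ratios of a sequenced pool
#'
#' For each covered SNV: `ratioAWRIBY = (nAWRI + c) / (nBY + c)` with
#' pseudocount `c` (default 0.5, keeping ratios finite at zero counts),
#' `freqAWRI = nAWRI / depth`, and `depth = nBY + nAWRI`.  The canonical
#' orientation is AWRI:BY; the reciprocal (BY:AWRI) is available from
#' `1 / ratioAWRIBY` for report parity with the opposite phrasing.
#' Zero-depth sites are always dropped; with `pseudocount = 0`,
#' zero-denominator sites are dropped too (both with a message).
#'
#' @param pool a [PoolCounts-class].
#' @param pseudocount non-negative pseudocount `c`.
#' @return a `GRanges` with columns `ratioAWRIBY`, `freqAWRI`, `depth`.
#' @examples
#' pc <- PoolCounts("chrA", c(100, 200), nBY = c(10, 20),
#'                  nAWRI = c(10, 0), seqlengths = c(chrA = 1e4))
#' alleleRatio(pc)
#' @export
alleleRatio <- function(pool, pseudocount = 0.5) {
  if (!length(pool)) stop("empty pool")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  nb <- mcols(pool)$nBY
  na <- mcols(pool)$nAWRI
  depth <- nb + na
  keep <- depth > 0L
  if (pseudocount == 0) keep <- keep & nb > 0L
  nd <- sum(!keep)
  if (nd > 0)
    message(nd, " SNV(s) dropped (zero depth",
            if (pseudocount == 0) " or zero BY-allele denominator", ")")
  gr <- granges(pool)[keep]
  mcols(gr)$ratioAWRIBY <- (na[keep] + pseudocount) /
    (nb[keep] + pseudocount)
  mcols(gr)$freqAWRI <- na[keep] / depth[keep]
  mcols(gr)$depth <- depth[keep]
  metadata(gr)$pseudocount <- pseudocount
  metadata(gr)$poolLabel <- metadata(pool)$poolLabel
  gr
}

#' Windowed medians of per-SNV allele ratios
#'
#' Tiles each chromosome with non-overlapping windows of `windowSize` bp
#' (0-based starts at multiples of the window size; the last window of a
#' chromosome may be shorter and is flagged).  Per window, the median
#' ratio and median AWRI frequency over the SNVs whose position falls in
#' it.  Windows containing no SNV are omitted, producing the gaps seen in
#' regions derived exclusively from the reference parent.
#'
#' @param ratios a sorted `GRanges` from [alleleRatio()] (unsorted input is
#'   an error, not silently reordered).
#' @param windowSize window size in bp (default 10,000).
#' @return a `GRanges` with columns `nSNVs`, `medianRatio`, `medianFreq`,
#'   `short`; `metadata()$windowSize` records the tiling.
#' @export
windowMedian <- function(ratios, windowSize = 10000) {
  if (windowSize <= 0) stop("'windowSize' must be > 0")
  if (!isSorted(ratios))
    stop("'ratios' must be sorted by (chromosome, position)")
  if (anyNA(seqlengths(ratios)))
    stop("'ratios' must carry seqlengths")
  dt <- data.table(chrom = as.character(seqnames(ratios)),
                   pos = start(ratios),
                   ratio = mcols(ratios)$ratioAWRIBY,
                   freq = mcols(ratios)$freqAWRI)
  dt[, win := (pos - 1L) %/% as.integer(windowSize)]
  agg <- dt[, list(nSNVs = .N, medianRatio = median(ratio),
                   medianFreq = median(freq)), by = c("chrom", "win")]
  sl <- seqlengths(ratios)
  start <- agg$win * windowSize + 1
  end <- pmin((agg$win + 1) * windowSize, sl[agg$chrom])
  gr <- GRanges(agg$chrom, IRanges(start, unname(end)),
                nSNVs = agg$nSNVs, medianRatio = agg$medianRatio,
                medianFreq = agg$medianFreq,
                short = unname(end) - start + 1 < windowSize,
                seqinfo = seqinfo(ratios))
  gr <- sort(gr)
  metadata(gr)$windowSize <- windowSize
  metadata(gr)$poolLabel <- metadata(ratios)$poolLabel
  gr
}

#' Selected-minus-average difference track
#'
#' Per window present in *both* tracks, the difference between the
#' selected and the average pool.  On the default frequency scale,
#' `delta = medianFreq(selected) - medianFreq(average)`: positive values
#' mean the window is enriched for AWRI-derived sequence in the
#' high-phenotype pool, negative values for BY-derived sequence.  A
#' ratio-scale delta (difference of median AWRI:BY ratios) is available
#' for figure parity.
#'
#' @param selected,average window tracks from [windowMedian()], computed
#'   with the same `windowSize`.
#' @param scale `"freq"` (default) or `"ratio"`.
#' @return a `GRanges` with columns `delta`, `nSNVsSelected`,
#'   `nSNVsAverage`.
#' @export
poolDelta <- function(selected, average, scale = c("freq", "ratio")) {
  scale <- match.arg(scale)
  wsS <- metadata(selected)$windowSize
  wsA <- metadata(average)$windowSize
  if (is.null(wsS) || is.null(wsA) || wsS != wsA)
    stop("window sizes of the two tracks differ (or are missing)")
  keyS <- paste0(seqnames(selected), ":", start(selected))
  keyA <- paste0(seqnames(average), ":", start(average))
  common <- intersect(keyS, keyA)
  s <- selected[match(common, keyS)]
  a <- average[match(common, keyA)]
  col <- if (scale == "freq") "medianFreq" else "medianRatio"
  gr <- granges(s)
  mcols(gr)$delta <- mcols(s)[[col]] - mcols(a)[[col]]
  mcols(gr)$nSNVsSelected <- mcols(s)$nSNVs
  mcols(gr)$nSNVsAverage <- mcols(a)$nSNVs
  gr <- sort(gr)
  metadata(gr)$windowSize <- wsS
  metadata(gr)$scale <- scale
  gr
}

#' Simulated selection-free null threshold for peak calling
#'
#' Simulates `nSims` pairs of selection-free pools (fresh segregants, no
#' phenotypic selection) at the stated pool sizes and sequencing depths,
#' runs the identical ratio/window/delta pipeline, and returns the given
#' quantile of the genome-wide `|delta|` distribution.  Used as the peak
#' calling threshold, since selection leaves this null untouched.
#'
#' @param map a [VariantMap-class].
#' @param gmap a [GeneticMap-class].
#' @param poolSizes length-2 (average, selected) pool sizes in segregants.
#' @param meanDepths length-2 (average, selected) mean depths, e.g.
#'   `c(738, 1407)`.
#' @param nSims number of simulated pool pairs (>= 20).
#' @param quantile null quantile returned (default 0.99).
#' @param windowSize,pseudocount passed to the pipeline.
#' @param errorRate sequencing error rate.
#' @param seed optional integer seed.
#' @return numeric threshold on the `|delta|` (frequency) scale.
#' @export
nullThreshold <- function(map, gmap, poolSizes, meanDepths = c(738, 1407),
                          nSims = 20, quantile = 0.99, windowSize = 10000,
                          pseudocount = 0.5, errorRate = 0, seed = NULL) {
  if (nSims < 20) stop("'nSims' must be >= 20")
  poolSizes <- rep_len(poolSizes, 2L)
  meanDepths <- rep_len(meanDepths, 2L)
  .setSeed(seed)
  absdelta <- vector("list", nSims)
  for (s in seq_len(nSims)) {
    wa <- windowMedian(alleleRatio(
      poolSequencing(simulateSegregants(gmap, poolSizes[1L]), map,
                     meanDepths[1L], errorRate = errorRate,
                     poolLabel = "average"),
      pseudocount = pseudocount), windowSize = windowSize)
    ws <- windowMedian(alleleRatio(
      poolSequencing(simulateSegregants(gmap, poolSizes[2L]), map,
                     meanDepths[2L], errorRate = errorRate,
                     poolLabel = "selected"),
      pseudocount = pseudocount), windowSize = windowSize)
    absdelta[[s]] <- abs(mcols(poolDelta(ws, wa))$delta)
  }
  unname(quantile(unlist(absdelta), probs = quantile))
}

#' Call candidate QTL peaks from a difference track
#'
#' Maximal runs of at least `minWindows` genomically adjacent windows with
#' `|delta| >= threshold` and constant sign become peaks.  The apex is the
#' run's window of maximal `|delta|`; the enriched parent is AWRI for
#' positive delta and BY for negative.
#'
#' @param delta a difference track from [poolDelta()].
#' @param threshold positive calling threshold (e.g. from
#'   [nullThreshold()]).
#' @param minWindows minimum run length in windows (default 2).
#' @return a `GRanges` of peaks with columns `apexPos`, `apexDelta`,
#'   `enrichedParent`, `nWindows` (empty when nothing passes).
#' @export
callPeaks <- function(delta, threshold, minWindows = 2) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  ws <- metadata(delta)$windowSize
  d <- mcols(delta)$delta
  chrom <- as.character(seqnames(delta))
  st <- start(delta)
  n <- length(d)
  emptyPeaks <- function() {
    gr <- GRanges(seqinfo = seqinfo(delta))
    mcols(gr) <- DataFrame(apexPos = integer(), apexDelta = numeric(),
                           enrichedParent = character(),
                           nWindows = integer())
    gr
  }
  if (!n) return(emptyPeaks())
  sig <- abs(d) >= threshold
  sgn <- sign(d)
  # a run breaks on chromosome change, non-adjacency, losing significance,
  # or a sign flip
  adjacent <- if (n > 1L) {
    chrom[-1L] == chrom[-n] &
      (if (is.null(ws)) TRUE else st[-1L] == st[-n] + ws)
  } else logical(0)
  newRun <- c(TRUE, !adjacent | sgn[-1L] != sgn[-n])
  runId <- cumsum(newRun | !sig)
  runId[!sig] <- NA_integer_
  if (all(is.na(runId))) return(emptyPeaks())
  idx <- which(!is.na(runId))
  runs <- split(idx, runId[idx])
  runs <- runs[lengths(runs) >= minWindows]
  if (!length(runs)) return(emptyPeaks())
  peaks <- lapply(runs, function(ii) {
    apex <- ii[which.max(abs(d[ii]))]
    data.frame(chrom = chrom[ii[1L]], start = st[ii[1L]],
               end = end(delta)[ii[length(ii)]],
               apexPos = as.integer((start(delta)[apex] +
                                       end(delta)[apex]) / 2),
               apexDelta = d[apex],
               enrichedParent = if (d[apex] > 0) "AWRI" else "BY",
               nWindows = length(ii))
  })
  pk <- do.call(rbind, peaks)
  gr <- GRanges(pk$chrom, IRanges(pk$start, pk$end),
                apexPos = pk$apexPos, apexDelta = pk$apexDelta,
                enrichedParent = pk$enrichedParent, nWindows = pk$nWindows,
                seqinfo = seqinfo(delta))
  sort(gr)
}

#' Parental-allele enrichment among genotyped segregants at one locus
#'
#' Counts BY vs AWRI calls at a single variant site over a set of
#' genotyped segregants (e.g. the top-FI subset), reporting percentages
#' over the strains with a non-missing call.
#'
#' @param calls list of [SegregantCalls-class].
#' @param chrom,pos the locus (must be called in at least one strain).
#' @return data.frame with `nStrains`, `nBY`, `nAWRI`, `pctBY`, `pctAWRI`.
#' @export
alleleEnrichment <- function(calls, chrom, pos) {
  got <- vapply(calls, function(sc) {
    hit <- which(as.character(seqnames(sc)) == chrom & start(sc) == pos)
    if (length(hit)) as.character(mcols(sc)$call[hit[1L]])
    else NA_character_
  }, character(1))
  called <- got[!is.na(got)]
  if (!length(called))
    stop("locus ", chrom, ":", pos, " is uncalled in all strains")
  nBY <- sum(called == "BY")
  nAWRI <- sum(called == "AWRI")
  data.frame(chrom = chrom, pos = pos, nStrains = length(got),
             nBY = nBY, nAWRI = nAWRI,
             pctBY = 100 * nBY / length(called),
             pctAWRI = 100 * nAWRI / length(called))
}
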