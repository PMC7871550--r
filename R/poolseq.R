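#' True AWRI allele frequency of a pool at every SNV
#'
#' Fraction of pool genomes carrying the AWRI origin at each site of the
#' variant map.  Computed by breakpoint event accumulation (a difference
#' array over SNV indices), so cost scales with the number of crossovers,
#' not pool size x SNV count.
#'
#' @param pool a [SegregantPool-class].
#' @param map a [VariantMap-class] on the same genome.
#' @return numeric vector along `map` with values in `[0, 1]`.
#' @export
poolAlleleFreq <- function(pool, map) {
  stopifnot(is(pool, "SegregantPool"), is(map, "VariantMap"))
  chs <- as.character(unique(seqnames(map)))
  if (!all(chs %in% names(pool@seqlengths)))
    stop("variant map chromosomes missing from the pool genome")
  n <- length(pool)
  snv <- .snvByChrom(map)
  out <- numeric(length(map))
  offset <- 0L
  for (ch in names(snv)) {
    pos <- snv[[ch]]
    S <- length(pos)
    if (!S) next
    delta <- numeric(S + 1L)
    delta[1L] <- sum(pool@startAWRI[, ch])
    b <- pool@breaks[[ch]]
    if (length(b)) {
      k <- pool@nbreaks[[ch]]
      j <- sequence(k)                       # within-segregant toggle index
      s <- rep.int(pool@startAWRI[, ch], k)  # leftmost-segment origin
      sign <- ifelse(s, -1, 1) * (-1)^(j - 1L)
      i0 <- findInterval(b, pos) + 1L        # first SNV with pos > b
      keep <- i0 <= S + 1L
      if (any(keep)) {
        acc <- rowsum(sign[keep], i0[keep])
        delta[as.integer(rownames(acc))] <-
          delta[as.integer(rownames(acc))] + acc[, 1L]
      }
    }
    out[offset + seq_len(S)] <- cumsum(delta)[seq_len(S)] / n
    offset <- offset + S
  }
  out
}

#' @rdname poolSequencing
#' @export
setMethod("poolSequencing", "SegregantPool",
  function(x, map, meanDepth, errorRate = 0, seed = NULL,
           poolLabel = "custom") {
    if (length(x) < 1L) stop("empty pool")
    if (meanDepth <= 0) stop("'meanDepth' must be > 0")
    if (errorRate < 0 || errorRate >= 0.5)
      stop("'errorRate' must be in [0, 0.5)")
    f <- poolAlleleFreq(x, map)
    .setSeed(seed)
    S <- length(map)
    depth <- rpois(S, meanDepth)
    p <- f * (1 - errorRate) + (1 - f) * errorRate
    nA <- rbinom(S, depth, p)
    gr <- granges(map)
    mcols(gr)$nBY <- depth - nA
    mcols(gr)$nAWRI <- nA
    metadata(gr)$poolLabel <- match.arg(poolLabel,
                                        c("average", "selected", "custom"))
    metadata(gr)$meanTargetDepth <- meanDepth
    metadata(gr)$errorRate <- errorRate
    metadata(gr)$poolSize <- length(x)
    new("PoolCounts", gr)
  })

#' @rdname poolSequencing
#' @export
setMethod("poolSequencing", "list",
  function(x, map, meanDepth, errorRate = 0, seed = NULL,
           poolLabel = "custom") {
    if (!length(x)) stop("empty pool")
    poolSequencing(.listToPool(x), map, meanDepth, errorRate = errorRate,
                   seed = seed, poolLabel = poolLabel)
  })

# internal: pack a list of Mosaic genomes into a SegregantPool
.listToPool <- function(ms) {
  stopifnot(all(vapply(ms, is, logical(1), "Mosaic")))
  sl <- ms[[1L]]@seqlengths
  chs <- names(sl)
  breaks <- lapply(chs, function(ch)
    unlist(lapply(ms, function(m) m@breaks[[ch]]), use.names = FALSE))
  names(breaks) <- chs
  nbreaks <- lapply(chs, function(ch)
    vapply(ms, function(m) length(m@breaks[[ch]]), integer(1)))
  names(nbreaks) <- chs
  sa <- do.call(rbind, lapply(ms, function(m) m@startAWRI[chs]))
  colnames(sa) <- chs
  new("SegregantPool", breaks = breaks, nbreaks = nbreaks,
      startAWRI = sa, seqlengths = sl)
}

#' @rdname poolLabel
#' @export
setMethod("poolLabel", "PoolCounts", function(x) metadata(x)$poolLabel)

#' @rdname poolLabel
#' @export
setMethod("meanTargetDepth", "PoolCounts",
          function(x) metadata(x)$meanTargetDepth)

#' Construct a PoolCounts object from count vectors
#'
#' @param chrom,pos site coordinates (must be a subset of the variant map
#'   when used downstream).
#' @param nBY,nAWRI non-negative integer read counts per parental allele.
#' @param seqlengths named chromosome lengths.
#' @param poolLabel `"average"`, `"selected"` or `"custom"`.
#' @param meanTargetDepth target mean depth (optional bookkeeping).
#' @return a [PoolCounts-class].
#' @export
PoolCounts <- function(chrom, pos, nBY, nAWRI, seqlengths,
                       poolLabel = "custom", meanTargetDepth = NA_real_) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                seqinfo = Seqinfo(names(seqlengths),
                                  unname(as.integer(seqlengths))))
  mcols(gr)$nBY <- as.integer(nBY)
  mcols(gr)$nAWRI <- as.integer(nAWRI)
  gr <- sort(gr)
  metadata(gr)$poolLabel <- match.arg(poolLabel,
                                      c("average", "selected", "custom"))
  metadata(gr)$meanTargetDepth <- meanTargetDepth
  new("PoolCounts", gr)
}

#' Simulate haploid variant calls for one segregant
#'
#' Per SNV of the map the call equals the true parental origin of the
#' mosaic, flipped with probability `miscallRate` and dropped (missing)
#' with probability `missingRate`.
#'
#' @param mosaic a [Mosaic-class].
#' @param map a [VariantMap-class].
#' @param miscallRate,missingRate probabilities in `[0, 1)` (`missingRate`
#'   may be 1, giving an empty call set).
#' @param seed optional integer seed.
#' @param id segregant identifier stored in `metadata()`.
#' @return a [SegregantCalls-class].
#' @export
simulateSegregantCalls <- function(mosaic, map, miscallRate = 0,
                                   missingRate = 0, seed = NULL,
                                   id = "segregant") {
  stopifnot(is(mosaic, "Mosaic"), is(map, "VariantMap"))
  if (miscallRate < 0 || miscallRate >= 1) stop("'miscallRate' in [0, 1)")
  if (missingRate < 0 || missingRate > 1) stop("'missingRate' in [0, 1]")
  .setSeed(seed)
  truth <- originAt(mosaic, as.character(seqnames(map)), start(map))
  S <- length(map)
  flip <- if (miscallRate > 0) runif(S) < miscallRate else rep(FALSE, S)
  call <- ifelse(flip, ifelse(truth == "BY", "AWRI", "BY"), truth)
  drop <- if (missingRate > 0) runif(S) < missingRate else rep(FALSE, S)
  gr <- granges(map)[!drop]
  mcols(gr)$call <- factor(call[!drop], levels = .ORIGINS)
  metadata(gr)$id <- id
  new("SegregantCalls", gr)
}
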