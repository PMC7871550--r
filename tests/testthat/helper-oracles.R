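# Independent brute-force oracles.  These deliberately use naive loops and
# data-frame logic so they share no code path with the package internals
# they check.

# windowed medians by explicit per-window subsetting
oracleWindowMedian <- function(df, windowSize, seqlens) {
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    nwin <- ceiling(seqlens[[ch]] / windowSize)
    for (w in seq_len(nwin) - 1L) {
      lo <- w * windowSize + 1
      hi <- min((w + 1) * windowSize, seqlens[[ch]])
      inwin <- sub[sub$pos >= lo & sub$pos <= hi, ]
      if (!nrow(inwin)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = lo, end = hi, nSNVs = nrow(inwin),
        medianRatio = median(inwin$ratio), medianFreq = median(inwin$freq))
    }
  }
  do.call(rbind, out)
}

# assigned blocks by explicit run scanning over ordered calls
oracleRunBlocks <- function(pos, call, minRun) {
  out <- list()
  i <- 1L
  n <- length(call)
  while (i <= n) {
    j <- i
    while (j < n && call[j + 1L] == call[i]) j <- j + 1L
    if (j - i + 1L >= minRun)
      out[[length(out) + 1L]] <- data.frame(start = pos[i], end = pos[j],
                                            origin = call[i],
                                            n = j - i + 1L)
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# peak runs by explicit scanning of a window-ordered delta table
oraclePeaks <- function(df, threshold, minWindows, windowSize) {
  out <- list()
  i <- 1L
  n <- nrow(df)
  while (i <= n) {
    if (abs(df$delta[i]) < threshold) { i <- i + 1L; next }
    j <- i
    while (j < n &&
           df$chrom[j + 1L] == df$chrom[j] &&
           df$start[j + 1L] == df$start[j] + windowSize &&
           abs(df$delta[j + 1L]) >= threshold &&
           sign(df$delta[j + 1L]) == sign(df$delta[i])) j <- j + 1L
    if (j - i + 1L >= minWindows)
      out[[length(out) + 1L]] <- data.frame(
        chrom = df$chrom[i], start = df$start[i], end = df$end[j],
        nWindows = j - i + 1L, sign = sign(df$delta[i]))
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# equal-variance two-sample t-test p-value from the closed form
oracleStudentT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}
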