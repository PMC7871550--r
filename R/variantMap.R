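#' Generate a synthetic inter-parent SNV map
#'
#' Emulates the catalogue of segregating sites between the two parental
#' strains (about 68,000 SNVs between the laboratory strain and the wine
#' strain over the 12.07 Mb nuclear genome, i.e. one marker every ~178 bp).
#' Site counts are allocated to chromosomes multinomially in proportion to
#' length; positions are drawn uniformly without replacement within each
#' chromosome and sorted; parental alleles are distinct nucleotides.
#'
#' @param nSNVs total number of segregating sites (>= 1).
#' @param seqlengths named chromosome lengths in bp; defaults to
#'   [yeastChromLengths()].
#' @param seed optional integer seed; the same seed reproduces the same map.
#' @return a [VariantMap-class].
#' @examples
#' vm <- buildParentalMap(500, c(chrA = 1e5, chrB = 5e4), seed = 1)
#' length(vm)
#' @export
buildParentalMap <- function(nSNVs = 68000, seqlengths = yeastChromLengths(),
                             seed = NULL) {
  nSNVs <- as.integer(nSNVs)
  if (is.na(nSNVs) || nSNVs < 1L)
    stop("'nSNVs' must be a positive integer")
  seqlengths <- setNames(as.numeric(seqlengths), names(seqlengths))
  if (nSNVs > sum(seqlengths))
    stop("'nSNVs' exceeds the number of available positions in the genome")
  .setSeed(seed)

  k <- as.vector(rmultinom(1L, nSNVs, seqlengths / sum(seqlengths)))
  names(k) <- names(seqlengths)
  # a chromosome cannot hold more sites than bases; push any excess onto
  # the chromosome with the most remaining room (vanishingly rare in use)
  while (any(over <- k > seqlengths)) {
    i <- which(over)[1L]
    excess <- k[i] - seqlengths[i]
    k[i] <- seqlengths[i]
    room <- seqlengths - k
    k[which.max(room)] <- k[which.max(room)] + excess
  }

  chrom <- rep(names(k), k)
  pos <- unlist(lapply(names(k), function(ch) {
    if (k[[ch]] == 0L) return(integer())
    sort(sample.int(seqlengths[[ch]], k[[ch]]))
  }), use.names = FALSE)

  bases <- c("A", "C", "G", "T")
  by <- sample(bases, nSNVs, replace = TRUE)
  shift <- sample.int(3L, nSNVs, replace = TRUE)
  awri <- bases[((match(by, bases) - 1L + shift) %% 4L) + 1L]

  VariantMap(chrom, pos, by, awri, seqlengths)
}

# internal: SNV positions split by chromosome, in seqlevels order
.snvByChrom <- function(map) {
  split(start(map), factor(as.character(seqnames(map)), levels = seqlevels(map)))
}
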