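#' Uniform genetic map
#'
#' One rate segment per chromosome.  The default 0.345 cM/kbp (about
#' 2.9 kbp per cM) reproduces the 26.2 kbp ~ 9 cM physical-genetic
#' correspondence of the yeast cross and gives the 12.07 Mb genome a total
#' genetic length of roughly 4,165 cM.
#'
#' @param rate recombination rate in cM per kbp (> 0); recycled over
#'   chromosomes, so a named per-chromosome vector is also accepted.
#' @param seqlengths named chromosome lengths (bp).
#' @return a [GeneticMap-class].
#' @examples
#' gm <- uniformGeneticMap()
#' sum(geneticLength(gm))  # total cM
#' @export
uniformGeneticMap <- function(rate = 0.345, seqlengths = yeastChromLengths()) {
  if (any(rate <= 0)) stop("'rate' must be > 0")
  chs <- names(seqlengths)
  r <- if (!is.null(names(rate))) {
    if (!all(chs %in% names(rate))) stop("named 'rate' must cover all chromosomes")
    unname(rate[chs])
  } else rep_len(rate, length(chs))
  gr <- GRanges(chs, IRanges(1L, unname(as.integer(seqlengths))),
                rate = r,
                seqinfo = Seqinfo(chs, unname(as.integer(seqlengths))))
  new("GeneticMap", gr)
}

#' Construct a (piecewise) genetic map from a GRanges
#'
#' @param gr a `GRanges` with a `rate` column (cM/kbp) whose ranges tile
#'   each chromosome exactly; `seqlengths` must be set.
#' @return a [GeneticMap-class].
#' @export
GeneticMap <- function(gr) new("GeneticMap", sort(gr))

#' Genetic length per chromosome
#'
#' @param gmap a [GeneticMap-class].
#' @return named numeric vector, cM per chromosome.
#' @export
geneticLength <- function(gmap) {
  cm <- width(gmap) / 1000 * mcols(gmap)$rate
  vapply(split(cm, as.character(seqnames(gmap)))[seqlevels(gmap)],
         sum, numeric(1))
}

#' Genetic distance between two positions on a chromosome
#'
#' @param gmap a [GeneticMap-class].
#' @param chrom chromosome name.
#' @param pos1,pos2 1-based bp positions.
#' @return distance in cM.
#' @examples
#' gm <- uniformGeneticMap()
#' geneticDistance(gm, "chrV", 32000, 58200)  # ~9 cM at 26.2 kbp
#' @export
geneticDistance <- function(gmap, chrom, pos1, pos2) {
  tab <- .gmapTable(gmap)[[chrom]]
  if (is.null(tab)) stop("chromosome '", chrom, "' is not on the genetic map")
  g <- stats::approx(tab$bp, tab$cm, c(pos1, pos2), rule = 2)$y
  abs(g[2L] - g[1L])
}

#' Haldane's map function
#'
#' Converts a genetic distance `d` (cM) into a recombination fraction
#' under a no-interference crossover model: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d genetic distance in cM.
#' @return recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(9)  # ~0.082
#' @export
haldane <- function(d) (1 - exp(-2 * d / 100)) / 2

# internal: per-chromosome lookup tables bp <-> cumulative cM.
# bp breakpoints start at 0 so crossovers drawn uniformly on the genetic
# scale can be mapped back to physical coordinates by linear interpolation.
.gmapTable <- function(gmap) {
  out <- lapply(seqlevels(gmap), function(ch) {
    seg <- sort(gmap[seqnames(gmap) == ch])
    bp <- c(0, end(seg))
    cm <- c(0, cumsum(width(seg) / 1000 * mcols(seg)$rate))
    list(bp = bp, cm = cm, totalCM = cm[length(cm)])
  })
  names(out) <- seqlevels(gmap)
  out
}
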