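#' Default S288C-like nuclear genome
#'
#' The 16 nuclear chromosome lengths of the S. cerevisiae S288C reference
#' assembly (no mitochondrial genome), totalling 12,071,326 bp.  Used as the
#' default genome for the synthetic cross; any named length vector can be
#' substituted.
#'
#' @return named integer vector of chromosome lengths in bp.
#' @examples
#' sum(yeastChromLengths())
#' @export
yeastChromLengths <- function() {
  c(chrI    = 230218L,  chrII   = 813184L,  chrIII  = 316620L,
    chrIV   = 1531933L, chrV    = 576874L,  chrVI   = 270161L,
    chrVII  = 1090940L, chrVIII = 562643L,  chrIX   = 439888L,
    chrX    = 745751L,  chrXI   = 666816L,  chrXII  = 1078177L,
    chrXIII = 924431L,  chrXIV  = 784333L,  chrXV   = 1091291L,
    chrXVI  = 948066L)
}

#' Default haploid selection-marker loci
#'
#' Loci standing in for the CAN1 (chrV) and LYP1 (chrXIV) counterselection
#' markers of a MATa haploid-selection cross.  Both deletions derive from
#' the laboratory (BY) parent, so selected segregants must carry the BY
#' origin there; linked alleles hitchhike (e.g. RML2, 26.2 kbp from CAN1).
#'
#' @return data.frame with columns `chrom`, `pos`, `name`.
#' @export
defaultMarkerLoci <- function() {
  data.frame(chrom = c("chrV", "chrXIV"),
             pos = c(32000L, 717500L),
             name = c("CAN1", "LYP1"))
}

# internal: normalize seed handling -- every stochastic entry point takes
# an optional integer seed and seeds the session RNG when given.
.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
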