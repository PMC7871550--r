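#' Construct a polygenic trait model
#'
#' @param baseline fluorescence-intensity baseline (the value of a genome
#'   whose effect-locus origins all contribute 0).
#' @param loci data.frame with columns `chrom`, `pos`, `effectBY`,
#'   `effectAWRI`: the additive effect contributed when the genome carries
#'   the corresponding parental origin at that locus.
#' @param epistasis data.frame with columns `chrom1`, `pos1`, `origin1`,
#'   `chrom2`, `pos2`, `origin2`, `effect`: `effect` is added when both
#'   origin conditions hold.
#' @param noiseSD Gaussian noise SD in FI units (biological plus
#'   measurement noise folded together).
#' @return a [TraitModel-class].
#' @export
TraitModel <- function(baseline = 0,
                       loci = data.frame(chrom = character(), pos = integer(),
                                         effectBY = numeric(),
                                         effectAWRI = numeric()),
                       epistasis = data.frame(chrom1 = character(),
                                              pos1 = integer(),
                                              origin1 = character(),
                                              chrom2 = character(),
                                              pos2 = integer(),
                                              origin2 = character(),
                                              effect = numeric()),
                       noiseSD = 0) {
  new("TraitModel", baseline = baseline, loci = loci,
      epistasis = epistasis, noiseSD = noiseSD)
}

#' Default neutral-lipid trait model for the synthetic cross
#'
#' Five additive loci plus one diminishing-returns interaction, placed at
#' the approximate positions of the lipid-storage QTLs of the cross
#' (PIG1-like on chrXII, PHO23-like and AQR1-like on chrXIV, SWH1-like on
#' chrI, RML2-like on chrV near the CAN1 marker).  Four loci are
#' AWRI-beneficial; the RML2-like locus is BY-beneficial, giving
#' antagonistic alleles in both parents and hence transgressive
#' segregation in both directions.
#'
#' Calibration: the all-BY genome scores 114 FI and the all-AWRI genome
#' `114 * 2^0.66 ~ 180.1`, i.e. the parental FI ratio is 2^0.66 ~ 1.58 on
#' the log2 scale used for the 100-class histograms.  The interaction term
#' requires both BY origins (the BY-beneficial allele pair), which puts
#' the F1 mean slightly below the parental midpoint: with `noiseSD = 33`
#' roughly a fifth of segregants falls below the BY parent and slightly
#' fewer rise above the AWRI parent, the asymmetry characteristic of this
#' cross.
#'
#' @return a [TraitModel-class].
#' @export
defaultTraitModel <- function() {
  loci <- data.frame(
    chrom = c("chrXII", "chrXIV", "chrI", "chrV", "chrXIV"),
    pos = c(480000L, 300000L, 130000L, 58200L, 160000L),
    effectBY = c(0, 0, 0, 8, 0),
    effectAWRI = c(36, 26, 12, 0, 6.13),
    row.names = c("PIG1like", "PHO23like", "SWH1like", "RML2like",
                  "AQR1like"))
  epi <- data.frame(
    chrom1 = "chrV", pos1 = 58200L, origin1 = "BY",
    chrom2 = "chrXIV", pos2 = 300000L, origin2 = "BY",
    effect = 6)
  TraitModel(baseline = 100, loci = loci, epistasis = epi, noiseSD = 33)
}

#' Noise-free parental trait expectations
#'
#' Trait values of the two uniform parental genomes under the model with
#' the Gaussian noise switched off -- the reference values plates are
#' normalized against.
#'
#' @param model a [TraitModel-class].
#' @param seqlengths named chromosome lengths.
#' @return named numeric `c(BY = ..., AWRI = ...)`.
#' @examples
#' pv <- parentValues(defaultTraitModel(), yeastChromLengths())
#' log2(pv[["AWRI"]] / pv[["BY"]])  # ~0.66
#' @export
parentValues <- function(model, seqlengths) {
  m0 <- model
  m0@noiseSD <- 0
  c(BY = traitValues(uniformMosaic("BY", seqlengths), m0),
    AWRI = traitValues(uniformMosaic("AWRI", seqlengths), m0))
}

.checkModelLoci <- function(model, seqlengths) {
  loc <- rbind(
    data.frame(chrom = model@loci$chrom, pos = model@loci$pos),
    data.frame(chrom = model@epistasis$chrom1, pos = model@epistasis$pos1),
    data.frame(chrom = model@epistasis$chrom2, pos = model@epistasis$pos2))
  if (!nrow(loc)) return(invisible(NULL))
  bad <- !(loc$chrom %in% names(seqlengths)) |
    loc$pos < 1 | loc$pos > seqlengths[loc$chrom]
  if (any(bad, na.rm = TRUE) || anyNA(bad))
    stop("trait-model locus off the mapped genome: ",
         paste(unique(paste0(loc$chrom[bad], ":", loc$pos[bad])),
               collapse = ", "))
  invisible(NULL)
}

# internal: n x nloci matrix of logical AWRI origin
.originMatrix <- function(x, chrom, pos) {
  if (is(x, "SegregantPool")) {
    vapply(seq_along(pos),
           function(i) originAt(x, chrom[i], pos[i]) == "AWRI",
           logical(length(x)))
  } else { # Mosaic
    matrix(originAt(x, chrom, pos) == "AWRI", nrow = 1L)
  }
}

.traitCore <- function(x, model, n) {
  val <- rep(model@baseline, n)
  if (nrow(model@loci)) {
    aw <- .originMatrix(x, model@loci$chrom, model@loci$pos)
    if (is.null(dim(aw))) aw <- matrix(aw, nrow = n)
    val <- val + as.vector(
      aw %*% model@loci$effectAWRI + (!aw) %*% model@loci$effectBY)
  }
  if (nrow(model@epistasis)) {
    for (i in seq_len(nrow(model@epistasis))) {
      e <- model@epistasis[i, ]
      m1 <- .originMatrix(x, e$chrom1, e$pos1)[, 1L] == (e$origin1 == "AWRI")
      m2 <- .originMatrix(x, e$chrom2, e$pos2)[, 1L] == (e$origin2 == "AWRI")
      val <- val + ifelse(m1 & m2, e$effect, 0)
    }
  }
  if (model@noiseSD > 0) val <- val + rnorm(n, 0, model@noiseSD)
  val
}

#' @rdname traitValues
#' @export
setMethod("traitValues", "SegregantPool", function(x, model, seed = NULL) {
  .checkModelLoci(model, x@seqlengths)
  .setSeed(seed)
  .traitCore(x, model, length(x))
})

#' @rdname traitValues
#' @export
setMethod("traitValues", "Mosaic", function(x, model, seed = NULL) {
  .checkModelLoci(model, x@seqlengths)
  .setSeed(seed)
  .traitCore(x, model, 1L)
})

#' @rdname traitValues
#' @export
setMethod("traitValues", "list", function(x, model, seed = NULL) {
  .setSeed(seed)
  vapply(x, function(m) traitValues(m, model), numeric(1))
})
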