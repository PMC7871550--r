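#' @import methods
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- isSorted DataFrame
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqnames seqlevels
#' @importFrom BiocGenerics start end width strand
#' @importFrom data.table data.table as.data.table fread fwrite setorder :=
#' @importFrom stats rpois rbinom rnorm runif median quantile setNames
#'   rmultinom t.test pt var sd
#' @importFrom utils packageVersion head tail str
#' @importFrom graphics abline
NULL

.ORIGINS <- c("BY", "AWRI")

#' SNV catalogue distinguishing the two parental strains
#'
#' A `VariantMap` is a [GenomicRanges::GRanges] of width-1 sites with
#' metadata columns `alleleBY` and `alleleAWRI` (the nucleotide carried by
#' each parent at that site) and fully declared `seqlengths`.  It is the
#' marker backbone of the whole pipeline: pool sequencing, per-segregant
#' calls and haplotype-block inference are all defined on its sites.
#'
#' Validity requires sites sorted and unique per chromosome, positions within
#' the chromosome, and `alleleBY != alleleAWRI` everywhere.
#'
#' @seealso [buildParentalMap()], [readVariantMap()]
#' @exportClass VariantMap
setClass("VariantMap", contains = "GRanges")

setValidity("VariantMap", function(object) {
  msg <- character()
  if (length(object)) {
    if (!all(c("alleleBY", "alleleAWRI") %in% names(mcols(object))))
      return("metadata columns 'alleleBY' and 'alleleAWRI' are required")
    if (any(width(object) != 1L))
      msg <- c(msg, "all sites must have width 1")
    if (anyNA(seqlengths(object)))
      msg <- c(msg, "every chromosome must have a declared seqlength")
    if (!isSorted(object))
      msg <- c(msg, "sites must be sorted by (chromosome, position)")
    key <- paste0(seqnames(object), ":", start(object))
    if (anyDuplicated(key))
      msg <- c(msg, "positions must be unique within a chromosome")
    sl <- seqlengths(object)[as.character(seqnames(object))]
    if (any(start(object) < 1L | start(object) > sl))
      msg <- c(msg, "positions must lie in [1, chrom_length]")
    a1 <- as.character(mcols(object)$alleleBY)
    a2 <- as.character(mcols(object)$alleleAWRI)
    if (any(a1 == a2))
      msg <- c(msg, "alleleBY must differ from alleleAWRI at every site")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantMap from vectors
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based site positions.
#' @param alleleBY,alleleAWRI parental nucleotides at each site.
#' @param seqlengths named vector of chromosome lengths (bp); must cover
#'   every chromosome referenced in `chrom`.
#' @return A [VariantMap-class] object.
#' @export
VariantMap <- function(chrom, pos, alleleBY, alleleAWRI, seqlengths) {
  if (is.null(names(seqlengths)))
    stop("'seqlengths' must be a named vector of chromosome lengths")
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                seqinfo = Seqinfo(names(seqlengths),
                                  unname(as.integer(seqlengths))))
  mcols(gr)$alleleBY <- as.character(alleleBY)
  mcols(gr)$alleleAWRI <- as.character(alleleAWRI)
  new("VariantMap", gr)
}

#' Genetic map: recombination rate along each chromosome
#'
#' A `GeneticMap` is a `GRanges` whose ranges tile each chromosome exactly
#' and whose `rate` column gives the local recombination rate in cM/kbp.
#' A single range per chromosome gives a uniform map; several ranges give a
#' piecewise map.
#'
#' @seealso [uniformGeneticMap()], [geneticLength()], [haldane()]
#' @exportClass GeneticMap
setClass("GeneticMap", contains = "GRanges")

setValidity("GeneticMap", function(object) {
  msg <- character()
  if (!("rate" %in% names(mcols(object))))
    return("metadata column 'rate' (cM/kbp) is required")
  if (any(mcols(object)$rate <= 0))
    msg <- c(msg, "all rates must be > 0")
  if (anyNA(seqlengths(object)))
    msg <- c(msg, "every chromosome must have a declared seqlength")
  for (ch in seqlevels(object)) {
    seg <- object[seqnames(object) == ch]
    if (!length(seg)) { msg <- c(msg, paste0("no rate segment for ", ch)); next }
    seg <- sort(seg)
    if (start(seg)[1L] != 1L ||
        end(seg)[length(seg)] != seqlengths(object)[[ch]] ||
        (length(seg) > 1L &&
         any(start(seg)[-1L] != end(seg)[-length(seg)] + 1L)))
      msg <- c(msg, paste0("rate segments must tile ", ch, " exactly"))
  }
  if (length(msg)) msg else TRUE
})

#' A segregant genome as a mosaic of parental segments
#'
#' A `Mosaic` stores, per chromosome, the crossover breakpoints (continuous
#' bp coordinates, strictly increasing) and the parental origin of the
#' leftmost segment.  The origin at a 1-based position `x` is the leftmost
#' origin toggled once per breakpoint `b < x`.  Use [mosaicSegments()] for a
#' `GRanges` view and [originAt()] for point queries.
#'
#' @exportClass Mosaic
setClass("Mosaic", representation(
  breaks = "list",       # per chromosome, numeric breakpoints in (0, len)
  startAWRI = "logical", # per chromosome, is the leftmost segment AWRI?
  seqlengths = "numeric"
))

setValidity("Mosaic", function(object) {
  msg <- character()
  chs <- names(object@seqlengths)
  if (!identical(names(object@breaks), chs) ||
      !identical(names(object@startAWRI), chs))
    return("breaks/startAWRI must be named consistently with seqlengths")
  for (ch in chs) {
    b <- object@breaks[[ch]]
    if (is.unsorted(b, strictly = TRUE))
      msg <- c(msg, paste0("breakpoints on ", ch, " must be strictly increasing"))
    if (length(b) && (b[1L] <= 0 || b[length(b)] >= object@seqlengths[[ch]]))
      msg <- c(msg, paste0("breakpoints on ", ch, " must lie inside (0, length)"))
  }
  if (length(msg)) msg else TRUE
})

#' A bulk haploid segregant population
#'
#' Compact columnar store for `n` segregant genomes: per chromosome, the
#' concatenated crossover breakpoints of all segregants (`breaks`), the
#' per-segregant breakpoint counts (`nbreaks`) and an `n x nchrom` logical
#' matrix saying whether each segregant's leftmost segment is AWRI-derived.
#' Pool-level operations (allele frequencies, trait values, marker
#' selection, pooled sequencing) work directly on this representation.
#'
#' @seealso [simulateSegregants()], [mosaic()], [poolAlleleFreq()]
#' @exportClass SegregantPool
setClass("SegregantPool", representation(
  breaks = "list",     # per chromosome: concatenated numeric breakpoints
  nbreaks = "list",    # per chromosome: integer vector, one count/segregant
  startAWRI = "matrix",
  seqlengths = "numeric"
))

setValidity("SegregantPool", function(object) {
  chs <- names(object@seqlengths)
  n <- nrow(object@startAWRI)
  if (!identical(names(object@breaks), chs) ||
      !identical(names(object@nbreaks), chs) ||
      !identical(colnames(object@startAWRI), chs))
    return("slot names must be consistent with seqlengths")
  for (ch in chs) {
    if (length(object@nbreaks[[ch]]) != n)
      return("nbreaks length must equal the number of segregants")
    if (length(object@breaks[[ch]]) != sum(object@nbreaks[[ch]]))
      return("breaks length must equal sum(nbreaks)")
  }
  TRUE
})

#' Configurable polygenic trait model on the Nile Red FI scale
#'
#' Trait value of a mosaic genome = `baseline` + per-locus additive effect
#' chosen by the parental origin at that locus + epistatic effects whose two
#' origin conditions both hold + `Normal(0, noiseSD)`.  FACS/plate-reader
#' measurement noise is folded into `noiseSD`.
#'
#' @exportClass TraitModel
setClass("TraitModel", representation(
  baseline = "numeric",
  loci = "data.frame",      # chrom, pos, effectBY, effectAWRI
  epistasis = "data.frame", # chrom1, pos1, origin1, chrom2, pos2, origin2, effect
  noiseSD = "numeric"
))

setValidity("TraitModel", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "effectBY", "effectAWRI")
  if (nrow(object@loci) && !all(need %in% names(object@loci)))
    msg <- c(msg, "loci needs columns chrom, pos, effectBY, effectAWRI")
  neede <- c("chrom1", "pos1", "origin1", "chrom2", "pos2", "origin2", "effect")
  if (nrow(object@epistasis) && !all(neede %in% names(object@epistasis)))
    msg <- c(msg, "epistasis needs columns chrom1, pos1, origin1, chrom2, pos2, origin2, effect")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  ok <- c(object@epistasis$origin1, object@epistasis$origin2)
  if (length(ok) && !all(ok %in% .ORIGINS))
    msg <- c(msg, "epistasis origins must be 'BY' or 'AWRI'")
  if (length(msg)) msg else TRUE
})

#' Per-SNV parental allele read counts for a sequenced pool
#'
#' A `PoolCounts` is a `GRanges` of VariantMap sites with integer metadata
#' columns `nBY` and `nAWRI` (reads supporting each parental allele).  The
#' pool label and target depth live in `metadata()`; see [poolLabel()] and
#' [meanTargetDepth()].
#'
#' @exportClass PoolCounts
setClass("PoolCounts", contains = "GRanges")

setValidity("PoolCounts", function(object) {
  msg <- character()
  if (!all(c("nBY", "nAWRI") %in% names(mcols(object))))
    return("metadata columns 'nBY' and 'nAWRI' are required")
  nb <- mcols(object)$nBY; na <- mcols(object)$nAWRI
  if (any(nb < 0) || any(na < 0) ||
      any(nb != round(nb)) || any(na != round(na)))
    msg <- c(msg, "counts must be non-negative integers")
  lab <- metadata(object)$poolLabel
  if (!is.null(lab) && !lab %in% c("average", "selected", "custom"))
    msg <- c(msg, "poolLabel must be 'average', 'selected' or 'custom'")
  if (length(msg)) msg else TRUE
})

#' Per-segregant parental SNV calls
#'
#' A `GRanges` subset of VariantMap sites with a `call` factor column with
#' levels `BY`/`AWRI`.  Missing sites are simply absent.  The segregant id
#' is kept in `metadata()$id`.
#'
#' @exportClass SegregantCalls
setClass("SegregantCalls", contains = "GRanges")

setValidity("SegregantCalls", function(object) {
  if (!("call" %in% names(mcols(object))))
    return("metadata column 'call' is required")
  cl <- mcols(object)$call
  if (!is.factor(cl) || !identical(levels(cl), .ORIGINS))
    return("'call' must be a factor with levels BY, AWRI")
  if (length(object) && !isSorted(object))
    return("calls must be sorted by (chromosome, position)")
  TRUE
})

#' 100-bin log2 frequency distribution of normalized Nile Red FI
#'
#' Equal-width bins on the log2(normalized FI) scale.  `breaks` has
#' `nBins + 1` strictly increasing edges; `counts` one count per bin;
#' `anchors` optionally records the class (bin index) of the BY and AWRI
#' parental values.  Binning is half-open `[left, right)` except the last
#' bin, which also includes its right edge.
#'
#' @seealso [binDistribution()], [classOf()], [classLog2()]
#' @exportClass NLHistogram
setClass("NLHistogram", representation(
  breaks = "numeric",
  counts = "integer",
  anchors = "numeric"
))

setValidity("NLHistogram", function(object) {
  msg <- character()
  if (is.unsorted(object@breaks, strictly = TRUE))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (length(object@counts) != length(object@breaks) - 1L)
    msg <- c(msg, "need one count per bin")
  w <- diff(object@breaks)
  if (length(w) > 1L && diff(range(w)) > 1e-8 * mean(w))
    msg <- c(msg, "bins must be equal width")
  if (length(msg)) msg else TRUE
})

#' One backcross lineage: per-generation selections and genomes
#'
#' `summary` has one row per generation (generation, id, trait,
#' donorFractionPct, nCandidates); `mosaics` holds the selected segregant's
#' genome per generation; `blocks` (optionally) the haplotype blocks
#' inferred from simulated SNV calls of each selected segregant.
#'
#' @seealso [runBackcross()]
#' @exportClass BackcrossLineage
setClass("BackcrossLineage", representation(
  summary = "data.frame",
  mosaics = "list",
  blocks = "list",
  recurrent = "character",
  donor = "character"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "Mosaic", function(object) {
  nseg <- sum(lengths(object@breaks)) + length(object@seqlengths)
  cat("Mosaic genome: ", length(object@seqlengths), " chromosomes, ",
      nseg, " segments\n", sep = "")
  don <- vapply(.ORIGINS, function(o) .mosaicOriginBp(object, o), numeric(1))
  pct <- round(100 * don / sum(object@seqlengths), 2)
  cat("  BY: ", pct[["BY"]], "%  AWRI: ", pct[["AWRI"]], "%\n", sep = "")
})

setMethod("show", "SegregantPool", function(object) {
  cat("SegregantPool: ", nrow(object@startAWRI), " segregants, ",
      length(object@seqlengths), " chromosomes (",
      format(sum(object@seqlengths), big.mark = ","), " bp)\n", sep = "")
})

setMethod("show", "TraitModel", function(object) {
  cat("TraitModel: baseline ", object@baseline, ", ",
      nrow(object@loci), " effect loci, ",
      nrow(object@epistasis), " epistasis terms, noiseSD ",
      object@noiseSD, "\n", sep = "")
})

setMethod("show", "NLHistogram", function(object) {
  cat("NLHistogram: ", length(object@counts), " classes on log2 [",
      round(min(object@breaks), 3), ", ", round(max(object@breaks), 3),
      "], n = ", sum(object@counts), "\n", sep = "")
  if (length(object@anchors))
    cat("  anchors: ", paste(names(object@anchors), object@anchors,
                             sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "BackcrossLineage", function(object) {
  cat("BackcrossLineage: recurrent ", object@recurrent, ", donor ",
      object@donor, ", generations F",
      min(object@summary$generation), "-F",
      max(object@summary$generation), "\n", sep = "")
  print(object@summary)
})
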