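#' Parental origin at genomic positions
#'
#' @param x a [Mosaic-class] or [SegregantPool-class].
#' @param chrom chromosome name (scalar for `SegregantPool`; for `Mosaic`
#'   a vector paired with `pos`).
#' @param pos 1-based position(s).
#' @return For a `Mosaic`, a character vector (`"BY"`/`"AWRI"`) along
#'   `pos`; for a `SegregantPool`, a character vector along segregants at
#'   the single queried locus.
#' @export
setGeneric("originAt", function(x, chrom, pos) standardGeneric("originAt"))

#' Trait values under a polygenic model
#'
#' @param x a [Mosaic-class], list of mosaics, or [SegregantPool-class].
#' @param model a [TraitModel-class].
#' @param seed optional integer seed for the Gaussian noise draw.
#' @return numeric vector of fluorescence-intensity values.
#' @export
setGeneric("traitValues", function(x, model, seed = NULL)
  standardGeneric("traitValues"))

#' Retain segregants matching required origins at selection-marker loci
#'
#' Models haploid selection-marker systems (e.g. can1-delta counterselection
#' on canavanine): only segregants whose genome carries `requiredOrigin` at
#' every marker locus survive.
#'
#' @param x a [SegregantPool-class] or a list of [Mosaic-class] objects.
#' @param markerLoci data.frame with columns `chrom`, `pos`.
#' @param requiredOrigin `"BY"` or `"AWRI"` (recycled over loci).
#' @return object of the same kind containing only the survivors (possibly
#'   empty; a message reports the surviving fraction).
#' @export
setGeneric("applyMarkerSelection", function(x, markerLoci, requiredOrigin)
  standardGeneric("applyMarkerSelection"))

#' Simulate pooled whole-genome sequencing of segregants
#'
#' Per SNV of the variant map, the true AWRI frequency `f` is the fraction
#' of pool genomes with AWRI origin at the site; sequencing draws
#' `depth ~ Poisson(meanDepth)` and
#' `nAWRI ~ Binomial(depth, f(1-e) + (1-f)e)` with error rate `e`,
#' `nBY = depth - nAWRI`.
#'
#' @param x a [SegregantPool-class] or non-empty list of [Mosaic-class].
#' @param map a [VariantMap-class].
#' @param meanDepth mean sequencing depth (> 0), e.g. 738 for an unselected
#'   pool or 1407 for a FACS-selected pool.
#' @param errorRate per-read allele miscall probability in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @param poolLabel `"average"`, `"selected"` or `"custom"`.
#' @return a [PoolCounts-class].
#' @export
setGeneric("poolSequencing",
  function(x, map, meanDepth, errorRate = 0, seed = NULL,
           poolLabel = "custom") standardGeneric("poolSequencing"))

#' Percentage of the genome derived from the donor parent
#'
#' @param x a [Mosaic-class] or a `GRanges` of haplotype blocks (with an
#'   `origin` column, as returned by [inferBlocks()]) that tiles the genome.
#' @param donor `"BY"` or `"AWRI"`.
#' @param denominator `"genome"` (total genome length; default, so the
#'   `(1/2)^g` backcross expectation is well defined) or `"assigned"`
#'   (origin-assigned bases only).
#' @param exclude optional `GRanges` of regions (e.g. a duplicated segment)
#'   removed from both numerator and denominator.
#' @return percentage in `[0, 100]`.
#' @export
setGeneric("donorFraction",
  function(x, donor, denominator = c("genome", "assigned"), exclude = NULL)
    standardGeneric("donorFraction"))

#' @rdname PoolCounts-class
#' @param x a `PoolCounts`.
#' @export
setGeneric("poolLabel", function(x) standardGeneric("poolLabel"))

#' @rdname PoolCounts-class
#' @export
setGeneric("meanTargetDepth", function(x) standardGeneric("meanTargetDepth"))

#' Extract one segregant genome from a pool
#'
#' @param x a [SegregantPool-class].
#' @param i segregant index.
#' @return a [Mosaic-class].
#' @export
setGeneric("mosaic", function(x, i) standardGeneric("mosaic"))
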