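#' @rdname applyMarkerSelection
#' @export
setMethod("applyMarkerSelection", "SegregantPool",
  function(x, markerLoci, requiredOrigin) {
    req <- .checkMarkers(markerLoci, requiredOrigin, x@seqlengths)
    keep <- rep(TRUE, length(x))
    for (i in seq_len(nrow(markerLoci)))
      keep <- keep & originAt(x, markerLoci$chrom[i],
                              markerLoci$pos[i]) == req[i]
    message("marker selection: ", sum(keep), "/", length(x),
            " segregants survive")
    x[keep]
  })

#' @rdname applyMarkerSelection
#' @export
setMethod("applyMarkerSelection", "list",
  function(x, markerLoci, requiredOrigin) {
    if (!length(x)) return(x)
    req <- .checkMarkers(markerLoci, requiredOrigin, x[[1L]]@seqlengths)
    keep <- vapply(x, function(m) {
      all(originAt(m, markerLoci$chrom, markerLoci$pos) == req)
    }, logical(1))
    message("marker selection: ", sum(keep), "/", length(x),
            " segregants survive")
    x[keep]
  })

.checkMarkers <- function(markerLoci, requiredOrigin, seqlengths) {
  stopifnot(is.data.frame(markerLoci),
            all(c("chrom", "pos") %in% names(markerLoci)))
  bad <- !(markerLoci$chrom %in% names(seqlengths))
  if (any(bad))
    stop("marker locus on unmapped chromosome: ",
         paste(unique(markerLoci$chrom[bad]), collapse = ", "))
  req <- rep_len(requiredOrigin, nrow(markerLoci))
  if (!all(req %in% .ORIGINS)) stop("requiredOrigin must be 'BY' or 'AWRI'")
  req
}

#' Number of cells/segregants collected by a FACS gate
#'
#' @param n population size.
#' @param gateFraction fraction collected, in `(0, 1]`.
#' @return `ceiling(gateFraction * n)`.
#' @examples
#' facsGateSize(1.5e8, 0.02)  # 3e6 cells in a ~2 % gate
#' @export
facsGateSize <- function(n, gateFraction) {
  if (gateFraction <= 0 || gateFraction > 1)
    stop("'gateFraction' must be in (0, 1]")
  ceiling(gateFraction * n)
}

#' FACS gate: indices of the brightest fraction of a population
#'
#' Returns the indices of the `ceiling(gateFraction * n)` highest
#' fluorescence values; ties are broken in favour of the lower index.
#'
#' @param values numeric fluorescence intensities.
#' @param gateFraction fraction of the population collected (default the
#'   ~2 % high-fluorescence gate of the X-QTL sort).
#' @return integer indices, sorted increasing.
#' @export
facsSort <- function(values, gateFraction = 0.02) {
  if (!length(values)) stop("'values' must be non-empty")
  k <- facsGateSize(length(values), gateFraction)
  sort(selectTop(values, k))
}

#' Indices of the k largest values
#'
#' Stable top-k selection: ties are resolved in favour of the lower index.
#'
#' @param values numeric vector.
#' @param k number of indices to return, `1 <= k <= length(values)`.
#' @return integer indices in decreasing order of value.
#' @export
selectTop <- function(values, k) {
  n <- length(values)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    stop("'k' must be between 1 and length(values)")
  ord <- order(values, decreasing = TRUE)  # stable: ties keep input order
  ord[seq_len(k)]
}
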