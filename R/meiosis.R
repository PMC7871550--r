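# Meiosis model: per chromosome the crossover count on a gamete is
# Poisson(genetic length in Morgans), breakpoints fall uniformly on the
# genetic scale (no interference, no obligate chiasma) and are mapped to bp
# through the genetic map; the parental origin of the leftmost segment is a
# fair coin.  Under this model the recombination fraction between two loci
# follows Haldane's map function of their cM distance.

# internal: sorted crossover breakpoints (bp) for n independent gametes on
# one chromosome.  Returns concatenated positions + per-gamete counts.
.sampleCrossovers <- function(n, tab) {
  k <- rpois(n, tab$totalCM / 100)
  tot <- sum(k)
  if (tot == 0L) return(list(pos = numeric(), k = k))
  g <- runif(tot, 0, tab$totalCM)
  bp <- stats::approx(tab$cm, tab$bp, g)$y
  grp <- rep.int(seq_len(n), k)
  ord <- order(grp, bp)
  list(pos = bp[ord], k = k)
}

#' Simulate haploid F1 segregants of the two-parent cross
#'
#' Each segregant is an independent gamete of the F1 hybrid diploid: its
#' genome is a mosaic of the two parental genomes determined by simulated
#' meiotic crossovers under the genetic map.
#'
#' @param gmap a [GeneticMap-class].
#' @param n number of segregants.
#' @param seed optional integer seed.
#' @return a [SegregantPool-class] of `n` genomes.
#' @examples
#' pool <- simulateSegregants(uniformGeneticMap(), 100, seed = 1)
#' pool
#' @export
simulateSegregants <- function(gmap, n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  .setSeed(seed)
  tabs <- .gmapTable(gmap)
  chs <- names(tabs)
  breaks <- vector("list", length(chs)); names(breaks) <- chs
  nbreaks <- vector("list", length(chs)); names(nbreaks) <- chs
  for (ch in chs) {
    cx <- .sampleCrossovers(n, tabs[[ch]])
    breaks[[ch]] <- cx$pos
    nbreaks[[ch]] <- cx$k
  }
  sa <- matrix(runif(n * length(chs)) < 0.5, nrow = n,
               dimnames = list(NULL, chs))
  sl <- seqlengths(gmap)[chs]
  new("SegregantPool", breaks = breaks, nbreaks = nbreaks,
      startAWRI = sa, seqlengths = setNames(as.numeric(sl), chs))
}

#' Simulate a single meiotic product
#'
#' @inheritParams simulateSegregants
#' @return a [Mosaic-class].
#' @export
simulateMeiosis <- function(gmap, seed = NULL) {
  mosaic(simulateSegregants(gmap, 1L, seed = seed), 1L)
}

#' @rdname mosaic
#' @export
setMethod("mosaic", "SegregantPool", function(x, i) {
  i <- as.integer(i)
  n <- nrow(x@startAWRI)
  if (is.na(i) || i < 1L || i > n) stop("segregant index out of range")
  chs <- names(x@seqlengths)
  br <- lapply(chs, function(ch) {
    k <- x@nbreaks[[ch]]
    off <- cumsum(c(0L, k))
    x@breaks[[ch]][seq_len(k[i]) + off[i]]
  })
  names(br) <- chs
  new("Mosaic", breaks = br,
      startAWRI = setNames(x@startAWRI[i, , drop = TRUE], chs),
      seqlengths = x@seqlengths)
})

#' Number of segregants in a pool
#' @param x a [SegregantPool-class].
#' @export
setMethod("length", "SegregantPool", function(x) nrow(x@startAWRI))

#' Subset a segregant pool
#' @param x a [SegregantPool-class].
#' @param i integer or logical index of segregants to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SegregantPool", function(x, i, j, ..., drop = FALSE) {
  n <- length(x)
  idx <- seq_len(n)[i]
  if (anyNA(idx)) stop("subscript out of bounds")
  chs <- names(x@seqlengths)
  breaks <- x@breaks; nbreaks <- x@nbreaks
  for (ch in chs) {
    k <- nbreaks[[ch]]
    off <- cumsum(c(0L, k))
    take <- unlist(lapply(idx, function(ii) seq_len(k[ii]) + off[ii]),
                   use.names = FALSE)
    breaks[[ch]] <- x@breaks[[ch]][take]
    nbreaks[[ch]] <- k[idx]
  }
  new("SegregantPool", breaks = breaks, nbreaks = nbreaks,
      startAWRI = x@startAWRI[idx, , drop = FALSE],
      seqlengths = x@seqlengths)
})

# internal: concatenate pools on the same genome
.poolRbind <- function(a, b) {
  chs <- names(a@seqlengths)
  breaks <- lapply(chs, function(ch) c(a@breaks[[ch]], b@breaks[[ch]]))
  names(breaks) <- chs
  nbreaks <- lapply(chs, function(ch) c(a@nbreaks[[ch]], b@nbreaks[[ch]]))
  names(nbreaks) <- chs
  new("SegregantPool", breaks = breaks, nbreaks = nbreaks,
      startAWRI = rbind(a@startAWRI, b@startAWRI),
      seqlengths = a@seqlengths)
}

#' Simulate F1 segregants that survive haploid marker selection
#'
#' Keeps simulating meioses until `n` segregants carrying `requiredOrigin`
#' at every marker locus have been collected -- the population a plated,
#' marker-selected segregant panel represents.
#'
#' @inheritParams simulateSegregants
#' @param markerLoci data.frame with columns `chrom`, `pos` (`NULL` for no
#'   selection).
#' @param requiredOrigin `"BY"` or `"AWRI"`.
#' @param maxTries bound on the number of simulation batches.
#' @return a [SegregantPool-class] of exactly `n` survivors.
#' @export
simulateSelectedSegregants <- function(gmap, n, markerLoci = NULL,
                                       requiredOrigin = "BY", seed = NULL,
                                       maxTries = 50) {
  .setSeed(seed)
  if (is.null(markerLoci) || !nrow(markerLoci))
    return(simulateSegregants(gmap, n))
  got <- NULL
  p <- 0.5^nrow(markerLoci)  # unlinked-marker expectation as a first guess
  for (i in seq_len(maxTries)) {
    need <- n - if (is.null(got)) 0L else length(got)
    if (need <= 0L) break
    batch <- simulateSegregants(gmap, ceiling(need / p * 1.2) + 20L)
    keep <- suppressMessages(
      applyMarkerSelection(batch, markerLoci, requiredOrigin))
    p <- max(length(keep) / length(batch), 1e-3)
    got <- if (is.null(got)) keep else .poolRbind(got, keep)
    if (i == maxTries && length(got) < n)
      stop("could not collect ", n, " marker-surviving segregants in ",
           maxTries, " batches")
  }
  got[seq_len(n)]
}

## ---- origin queries -----------------------------------------------------

# origin toggles at each breakpoint b for positions x > b, so the number of
# toggles before 1-based position x is #{b < x} (left-open findInterval)
.parityAWRI <- function(startAWRI, nToggles) xor(startAWRI, nToggles %% 2L == 1L)

#' @rdname originAt
#' @export
setMethod("originAt", "Mosaic", function(x, chrom, pos) {
  chrom <- as.character(chrom)
  stopifnot(length(chrom) == length(pos) || length(chrom) == 1L)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  bad <- !(chrom %in% names(x@seqlengths))
  if (any(bad)) stop("chromosome(s) not in mosaic: ",
                     paste(unique(chrom[bad]), collapse = ", "))
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    nt <- findInterval(pos[sel], x@breaks[[ch]], left.open = TRUE)
    out[sel] <- .ORIGINS[.parityAWRI(x@startAWRI[[ch]], nt) + 1L]
  }
  out
})

#' @rdname originAt
#' @export
setMethod("originAt", "SegregantPool", function(x, chrom, pos) {
  chrom <- as.character(chrom)
  stopifnot(length(chrom) == 1L, length(pos) == 1L)
  if (!chrom %in% names(x@seqlengths))
    stop("chromosome '", chrom, "' not in pool")
  n <- length(x)
  k <- x@nbreaks[[chrom]]
  b <- x@breaks[[chrom]]
  lt <- b < pos
  nt <- integer(n)
  if (any(lt)) {
    grp <- rep.int(seq_len(n), k)
    nt <- tabulate(grp[lt], nbins = n)
  }
  .ORIGINS[.parityAWRI(x@startAWRI[, chrom], nt) + 1L]
})

## ---- Mosaic views -------------------------------------------------------

#' Parental-origin segments of a mosaic genome
#'
#' Collapses the breakpoint representation into a `GRanges` tiling of the
#' genome with an `origin` factor column; adjacent segments always have
#' different origins.  Breakpoints falling within the same base pair cancel
#' in pairs (even multiplicity leaves origin unchanged).
#'
#' @param x a [Mosaic-class].
#' @return a sorted `GRanges` with column `origin`.
#' @export
mosaicSegments <- function(x) {
  stopifnot(is(x, "Mosaic"))
  chs <- names(x@seqlengths)
  parts <- lapply(chs, function(ch) {
    len <- x@seqlengths[[ch]]
    # integer boundary = last base of the left segment; keep odd multiplicity
    bnd <- floor(x@breaks[[ch]])
    bnd <- bnd[bnd >= 1 & bnd < len]
    if (length(bnd)) {
      tb <- table(bnd)
      bnd <- as.numeric(names(tb))[tb %% 2L == 1L]
    }
    starts <- c(1, bnd + 1)
    ends <- c(bnd, len)
    org <- rep_len(c(x@startAWRI[[ch]], !x@startAWRI[[ch]]),
                   length(starts))
    data.frame(chrom = ch, start = starts, end = ends,
               origin = .ORIGINS[org + 1L])
  })
  df <- do.call(rbind, parts)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                origin = factor(df$origin, levels = .ORIGINS),
                seqinfo = Seqinfo(chs, unname(as.integer(x@seqlengths))))
  sort(gr)
}

setAs("Mosaic", "GRanges", function(from) mosaicSegments(from))

#' Build a Mosaic from explicit segments
#'
#' Convenience constructor mostly used in tests and examples: segments must
#' tile each chromosome.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed), `origin` (`"BY"`/`"AWRI"`).
#' @param seqlengths named chromosome lengths.
#' @return a [Mosaic-class].
#' @export
Mosaic <- function(segments, seqlengths) {
  chs <- names(seqlengths)
  breaks <- vector("list", length(chs)); names(breaks) <- chs
  startAWRI <- setNames(logical(length(chs)), chs)
  for (ch in chs) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (!nrow(seg) || seg$start[1L] != 1 ||
        seg$end[nrow(seg)] != seqlengths[[ch]] ||
        (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)] + 1)))
      stop("segments must tile chromosome ", ch)
    org <- seg$origin == "AWRI"
    keep <- c(TRUE, diff(org) != 0)   # merge same-origin neighbours
    seg <- seg[keep, , drop = FALSE]
    breaks[[ch]] <- as.numeric(seg$end[-nrow(seg)])
    startAWRI[[ch]] <- seg$origin[1L] == "AWRI"
  }
  new("Mosaic", breaks = breaks, startAWRI = startAWRI,
      seqlengths = setNames(as.numeric(seqlengths), chs))
}

#' A genome inherited entirely from one parent
#'
#' @param origin `"BY"` or `"AWRI"`.
#' @param seqlengths named chromosome lengths.
#' @return a [Mosaic-class] with a single segment per chromosome.
#' @export
uniformMosaic <- function(origin, seqlengths) {
  origin <- match.arg(origin, .ORIGINS)
  chs <- names(seqlengths)
  new("Mosaic",
      breaks = setNames(rep(list(numeric()), length(chs)), chs),
      startAWRI = setNames(rep(origin == "AWRI", length(chs)), chs),
      seqlengths = setNames(as.numeric(seqlengths), chs))
}

# internal: bp inherited from one origin
.mosaicOriginBp <- function(x, origin) {
  isA <- origin == "AWRI"
  tot <- 0
  for (ch in names(x@seqlengths)) {
    b <- c(0, x@breaks[[ch]], x@seqlengths[[ch]])
    w <- diff(b)
    org <- rep_len(c(x@startAWRI[[ch]], !x@startAWRI[[ch]]), length(w))
    tot <- tot + sum(w[org == isA])
  }
  tot
}

## ---- backcross gamete ---------------------------------------------------

# internal: one gamete of (mosaic m) x (uniform recurrent parent).
# New crossovers switch the active homolog; the gamete's origin at any
# point is m's origin while on homolog 1 and the recurrent origin on
# homolog 2.  Merged boundaries are compressed to actual origin changes.
.backcrossGamete <- function(m, recurrentAWRI, tabs) {
  chs <- names(m@seqlengths)
  breaks <- vector("list", length(chs)); names(breaks) <- chs
  startAWRI <- setNames(logical(length(chs)), chs)
  for (ch in chs) {
    cx <- .sampleCrossovers(1L, tabs[[ch]])$pos
    h1first <- runif(1) < 0.5
    mb <- m@breaks[[ch]]
    B <- sort(c(cx, mb))
    pts <- c(0, B)  # representative left end of each interval
    onH1 <- xor(h1first, findInterval(pts, cx) %% 2L == 1L)
    mA <- .parityAWRI(m@startAWRI[[ch]], findInterval(pts, mb))
    org <- ifelse(onH1, mA, recurrentAWRI)
    chg <- which(diff(as.integer(org)) != 0L)
    breaks[[ch]] <- B[chg]
    startAWRI[[ch]] <- org[1L]
  }
  new("Mosaic", breaks = breaks, startAWRI = startAWRI,
      seqlengths = m@seqlengths)
}
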