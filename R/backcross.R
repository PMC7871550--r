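# Backcross-introgression analysis: a 7-generation backcross driver with
# per-generation top-FI selection, haplotype-block inference from runs of
# at least five consecutive same-parent SNV calls, donor-genome
# quantification against the (1/2)^g drift expectation, and
# duplicated-segment flagging from windowed sequencing depth.

#' Drive a multi-generation backcross with per-generation selection
#'
#' Starting from an F1 founder segregant, each round crosses the currently
#' selected segregant to the recurrent parent, simulates `nPerGen`
#' marker-surviving offspring, phenotypes them under the trait model and
#' carries the highest-FI segregant into the next round.  Generation `g`
#' (F_g) is reached after `g - 1` backcross rounds, so under pure drift
#' the donor-genome fraction at F_g has expectation `100 * (1/2)^g` %
#' when the founder is a random F1 segregant (see
#' [expectedDonorFraction()]).
#'
#' @param gmap a [GeneticMap-class].
#' @param founder an F1 [Mosaic-class]; `NULL` simulates a fresh random F1
#'   segregant.
#' @param recurrent `"BY"` or `"AWRI"`: the lineage's recurrent parent
#'   (the donor is the other parent).
#' @param generations final generation index (F_generations, >= 2;
#'   default 7).
#' @param nPerGen marker-surviving segregants phenotyped per round
#'   (the study screens ~190).
#' @param model a [TraitModel-class] (zero-effect model = pure drift).
#' @param markerLoci optional data.frame (`chrom`, `pos`) of haploid
#'   selection-marker loci; offspring are discarded unless they carry
#'   `markerOrigin` at every one.
#' @param markerOrigin required origin at the marker loci.
#' @param map optional [VariantMap-class]; when given, SNV calls are
#'   simulated for each selected segregant and haplotype blocks inferred
#'   with [inferBlocks()].
#' @param miscallRate,missingRate call error rates used when `map` is
#'   given.
#' @param minRun minimum consecutive-SNV run for block assignment.
#' @param seed optional integer seed.
#' @param maxTries bound on rejection-sampling batches per round before
#'   giving up when marker survivors are too rare.
#' @return a [BackcrossLineage-class].
#' @export
runBackcross <- function(gmap, founder = NULL,
                         recurrent = c("BY", "AWRI"), generations = 7,
                         nPerGen = 190, model = TraitModel(),
                         markerLoci = NULL, markerOrigin = "BY",
                         map = NULL, miscallRate = 0, missingRate = 0,
                         minRun = 5, seed = NULL, maxTries = 50) {
  recurrent <- match.arg(recurrent)
  donor <- setdiff(.ORIGINS, recurrent)
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 2L)
    stop("'generations' must be >= 2 (F2 is the first backcross generation)")
  .setSeed(seed)
  tabs <- .gmapTable(gmap)
  if (is.null(founder)) {
    # the founder must itself have survived the haploid marker selection,
    # otherwise no offspring can ever satisfy it
    for (tries in seq_len(maxTries)) {
      founder <- simulateMeiosis(gmap)
      if (is.null(markerLoci) ||
          all(originAt(founder, markerLoci$chrom, markerLoci$pos) ==
                rep_len(markerOrigin, nrow(markerLoci)))) break
      if (tries == maxTries)
        stop("no marker-compatible founder found after ", maxTries,
             " attempts")
    }
  } else if (!is.null(markerLoci) &&
             !all(originAt(founder, markerLoci$chrom, markerLoci$pos) ==
                    rep_len(markerOrigin, nrow(markerLoci)))) {
    stop("the founder does not carry the required origin at every ",
         "marker locus")
  }
  sel <- founder
  recAWRI <- recurrent == "AWRI"
  rows <- list()
  mosaics <- list()
  blocks <- list()
  for (g in 2:generations) {
    cands <- vector("list", nPerGen)
    got <- 0L
    tries <- 0L
    while (got < nPerGen) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("generation F", g, ": no marker-surviving segregants after ",
             maxTries, " batches")
      m <- .backcrossGamete(sel, recAWRI, tabs)
      if (!is.null(markerLoci) &&
          !all(originAt(m, markerLoci$chrom, markerLoci$pos) ==
                 rep_len(markerOrigin, nrow(markerLoci)))) next
      got <- got + 1L
      tries <- 0L
      cands[[got]] <- m
    }
    fi <- vapply(cands, function(m) .traitCore(m, model, 1L), numeric(1))
    best <- selectTop(fi, 1L)
    sel <- cands[[best]]
    gen <- paste0("F", g)
    mosaics[[gen]] <- sel
    rows[[gen]] <- data.frame(
      generation = g, id = paste0(gen, "_", best), trait = fi[best],
      donorFractionPct = donorFraction(sel, donor),
      nCandidates = nPerGen)
    if (!is.null(map)) {
      calls <- simulateSegregantCalls(sel, map, miscallRate = miscallRate,
                                      missingRate = missingRate,
                                      id = rows[[gen]]$id)
      blocks[[gen]] <- inferBlocks(calls, map, minRun = minRun)
    }
  }
  new("BackcrossLineage", summary = do.call(rbind, c(rows,
                                                     make.row.names = FALSE)),
      mosaics = mosaics, blocks = blocks, recurrent = recurrent,
      donor = donor)
}

#' Accessors for a backcross lineage
#'
#' @param x a [BackcrossLineage-class].
#' @return `lineageSummary`: the per-generation data.frame;
#'   `lineageMosaics`: named list of selected [Mosaic-class] genomes;
#'   `lineageBlocks`: named list of inferred block `GRanges` (empty when
#'   no variant map was supplied).
#' @export
lineageSummary <- function(x) x@summary

#' @rdname lineageSummary
#' @export
lineageMosaics <- function(x) x@mosaics

#' @rdname lineageSummary
#' @export
lineageBlocks <- function(x) x@blocks

#' Expected donor-genome percentage under selection-free backcrossing
#'
#' `100 * (1/2)^g` for generation F_g: the donor contribution halves at
#' every meiosis, starting from the 50 % expectation of a random F1
#' segregant, so F7 expects 0.78125 % (printed as 0.8 % at one decimal).
#'
#' @param g generation index (>= 1).
#' @return percentage.
#' @examples
#' expectedDonorFraction(1)  # 50
#' expectedDonorFraction(7)  # 0.78125
#' @export
expectedDonorFraction <- function(g) {
  if (any(g < 1)) stop("'g' must be >= 1")
  100 * 0.5^g
}

#' Infer parental-origin haplotype blocks from SNV calls
#'
#' Applies the consecutive-SNV rule: a maximal run of at least `minRun`
#' consecutive same-parent calls becomes an assigned block extending
#' between the furthest two SNVs of the run (1-based closed
#' `[first, last]`, i.e. 0-based half-open `[first - 1, last)`).  Shorter
#' runs and the intervals between assigned blocks are labelled
#' `unassigned`; the result tiles every chromosome of the map exactly.
#'
#' @param calls a [SegregantCalls-class] whose sites are a subset of the
#'   map (anything else is an error).
#' @param map a [VariantMap-class].
#' @param minRun minimum run length (default 5).
#' @return a sorted `GRanges` tiling the genome with columns `origin`
#'   (`BY`/`AWRI`/`unassigned`) and `nSupportingSNVs`.
#' @export
inferBlocks <- function(calls, map, minRun = 5) {
  stopifnot(is(calls, "SegregantCalls"), is(map, "VariantMap"))
  minRun <- as.integer(minRun)
  if (is.na(minRun) || minRun < 1L) stop("'minRun' must be >= 1")
  keyC <- paste0(seqnames(calls), ":", start(calls))
  keyM <- paste0(seqnames(map), ":", start(map))
  if (!all(keyC %in% keyM))
    stop("calls at positions absent from the variant map")
  sl <- seqlengths(map)
  rows <- list()
  for (ch in seqlevels(map)) {
    onch <- as.character(seqnames(calls)) == ch
    pos <- start(calls)[onch]
    cl <- as.character(mcols(calls)$call[onch])
    assigned <- NULL
    if (length(pos)) {
      r <- rle(cl)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- r$lengths >= minRun
      if (any(ok))
        assigned <- data.frame(start = pos[starts[ok]],
                               end = pos[ends[ok]],
                               origin = r$values[ok],
                               n = r$lengths[ok])
    }
    # fill everything between/around assigned blocks as unassigned
    cur <- 1
    chRows <- list()
    if (!is.null(assigned)) {
      for (i in seq_len(nrow(assigned))) {
        if (assigned$start[i] > cur)
          chRows[[length(chRows) + 1L]] <-
            data.frame(start = cur, end = assigned$start[i] - 1,
                       origin = "unassigned", n = 0L)
        chRows[[length(chRows) + 1L]] <- assigned[i, ]
        cur <- assigned$end[i] + 1
      }
    }
    if (cur <= sl[[ch]])
      chRows[[length(chRows) + 1L]] <-
        data.frame(start = cur, end = sl[[ch]], origin = "unassigned",
                   n = 0L)
    df <- do.call(rbind, chRows)
    df$chrom <- ch
    rows[[ch]] <- df
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                origin = factor(df$origin,
                                levels = c(.ORIGINS, "unassigned")),
                nSupportingSNVs = df$n,
                seqinfo = seqinfo(map))
  metadata(gr)$minRun <- minRun
  metadata(gr)$id <- metadata(calls)$id
  sort(gr)
}

## ---- donor fraction -----------------------------------------------------

#' @rdname donorFraction
#' @export
setMethod("donorFraction", "Mosaic",
  function(x, donor, denominator = c("genome", "assigned"),
           exclude = NULL) {
    donor <- match.arg(donor, .ORIGINS)
    denominator <- match.arg(denominator)
    if (is.null(exclude)) {
      # exact: a mosaic has no unassigned bases, both denominators agree
      return(100 * .mosaicOriginBp(x, donor) / sum(x@seqlengths))
    }
    donorFraction(mosaicSegments(x), donor, denominator, exclude)
  })

#' @rdname donorFraction
#' @export
setMethod("donorFraction", "GRanges",
  function(x, donor, denominator = c("genome", "assigned"),
           exclude = NULL) {
    donor <- match.arg(donor, .ORIGINS)
    denominator <- match.arg(denominator)
    if (!("origin" %in% names(mcols(x))))
      stop("'x' needs an 'origin' column")
    if (anyNA(seqlengths(x))) stop("'x' must carry seqlengths")
    genomeGR <- GRanges(seqlevels(x), IRanges(1L, seqlengths(x)),
                        seqinfo = seqinfo(x))
    keepGR <- if (is.null(exclude)) genomeGR else
      GenomicRanges::setdiff(genomeGR, exclude)
    donorBp <- sum(width(GenomicRanges::intersect(
      x[mcols(x)$origin == donor], keepGR)))
    denomBp <- if (denominator == "genome") sum(width(keepGR)) else {
      assignedGR <- x[mcols(x)$origin != "unassigned"]
      if (!length(assignedGR))
        stop("no assigned blocks: donor fraction undefined for ",
             "denominator = 'assigned'")
      sum(width(GenomicRanges::intersect(assignedGR, keepGR)))
    }
    100 * donorBp / denomBp
  })

## ---- depth-based duplication detection ----------------------------------

#' Flag duplicated segments from windowed sequencing depth
#'
#' Normalizes each window's depth by the genome-wide median window depth
#' and reports maximal runs of adjacent windows with fold change at least
#' `foldThreshold` whose total length reaches `minLen` -- the signature of
#' a duplicated chromosome part (e.g. a translocation-borne extra copy)
#' in an otherwise haploid genome.
#'
#' @param depth a `GRanges` of depth windows with a `depth` column, or a
#'   data.frame with `chrom`, `start` (0-based), `end`, `depth` as read by
#'   [readDepthTrack()].
#' @param foldThreshold minimum fold change (default 1.5).
#' @param minLen minimum total run length in bp (default 50,000).
#' @return a `GRanges` of duplication calls with column `meanFold`.
#' @export
detectDuplication <- function(depth, foldThreshold = 1.5, minLen = 50000) {
  if (is.data.frame(depth)) {
    depth <- GRanges(depth$chrom, IRanges(depth$start + 1L, depth$end),
                     depth = depth$depth)
  }
  d <- mcols(depth)$depth
  if (is.null(d) || !length(d)) stop("no depth windows")
  if (all(d == 0)) stop("invalid input: all depths are zero")
  med <- median(d)
  if (med <= 0) stop("median window depth is zero; depths must be > 0 for ",
                     "a majority of windows")
  fold <- d / med
  chrom <- as.character(seqnames(depth))
  n <- length(d)
  ord <- order(factor(chrom, levels = unique(chrom)), start(depth))
  chrom <- chrom[ord]; fold <- fold[ord]
  st <- start(depth)[ord]; en <- end(depth)[ord]
  hot <- is.finite(foldThreshold) & fold >= foldThreshold
  newRun <- c(TRUE, chrom[-1L] != chrom[-n] | st[-1L] != en[-n] + 1L)
  runId <- cumsum(newRun | !hot)
  runId[!hot] <- NA_integer_
  idx <- which(!is.na(runId))
  if (!length(idx)) return(GRanges(seqinfo = seqinfo(depth)))
  runs <- split(idx, runId[idx])
  calls <- lapply(runs, function(ii) {
    len <- en[ii[length(ii)]] - st[ii[1L]] + 1L
    if (len < minLen) return(NULL)
    data.frame(chrom = chrom[ii[1L]], start = st[ii[1L]],
               end = en[ii[length(ii)]], meanFold = mean(fold[ii]))
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) return(GRanges(seqinfo = seqinfo(depth)))
  sort(GRanges(calls$chrom, IRanges(calls$start, calls$end),
               meanFold = calls$meanFold, seqinfo = seqinfo(depth)))
}
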