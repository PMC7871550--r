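# On-disk formats.  Variant maps interchange as minimal VCF (POS 1-based,
# REF = BY allele, ALT = AWRI allele) or an equivalent TSV dialect; window
# and delta tracks as bedGraph-like TSV and blocks/peaks as BED (both
# 0-based half-open); pool counts as TSV (the AD-field analogue of a VCF).
# Readers validate and reject rather than silently reorder unsorted input.

#' Write / read a variant map
#'
#' `writeVariantMap()` emits minimal VCF (`.vcf`) or a TSV dialect with
#' `##contig=` header comments (anything else); `readVariantMap()`
#' auto-detects the dialect.  Write-then-read reproduces the map exactly,
#' including chromosome order.
#'
#' @param map a [VariantMap-class].
#' @param path file path; `.vcf` selects the VCF dialect.
#' @return `readVariantMap()` returns a [VariantMap-class];
#'   `writeVariantMap()` returns `path` invisibly.
#' @export
writeVariantMap <- function(map, path) {
  sl <- seqlengths(map)
  if (grepl("\\.vcf$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=xqtlmap-", packageVersion("xqtlmap")),
                 "##note=REF is the BY4741-parent allele, ALT the AWRI1631-parent allele",
                 sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       as.character(seqnames(map)), start(map),
                       mcols(map)$alleleBY, mcols(map)$alleleAWRI), con)
  } else {
    hdr <- c(sprintf("#contig=%s,length=%d", names(sl), sl),
             "chrom\tpos\tallele_by\tallele_awri")
    body <- sprintf("%s\t%d\t%s\t%s", as.character(seqnames(map)),
                    start(map), mcols(map)$alleleBY, mcols(map)$alleleAWRI)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' @rdname writeVariantMap
#' @export
readVariantMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty input file: ", path)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    meta <- grep("^##contig=", v@meta, value = TRUE)
    id <- sub(".*ID=([^,>]+).*", "\\1", meta)
    len <- as.integer(sub(".*length=([0-9]+).*", "\\1", meta))
    sl <- setNames(len, id)
    vm <- VariantMap(fix[, "CHROM"], as.integer(fix[, "POS"]),
                     fix[, "REF"], fix[, "ALT"], sl)
  } else {
    lines <- readLines(path)
    meta <- grep("^#contig=", lines, value = TRUE)
    if (!length(meta)) stop("TSV variant map lacks #contig= header lines")
    id <- sub("^#contig=([^,]+),.*", "\\1", meta)
    len <- as.integer(sub(".*length=([0-9]+).*", "\\1", meta))
    dt <- fread(path, skip = length(meta), header = TRUE, sep = "\t")
    need <- c("chrom", "pos", "allele_by", "allele_awri")
    miss <- setdiff(need, names(dt))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    vm <- VariantMap(dt$chrom, dt$pos, dt$allele_by, dt$allele_awri,
                     setNames(len, id))
  }
  validObject(vm)  # unsorted/duplicated positions rejected here
  vm
}

#' Write / read pooled allele counts
#'
#' TSV with columns `chrom`, `pos`, `n_by`, `n_awri` -- the allele-depth
#' (AD) analogue of a VCF -- plus `#key=value` header comments carrying
#' the pool label, target depth and contig lengths.  Counts round-trip
#' exactly as integers; negative counts are rejected.
#'
#' @param pool a [PoolCounts-class].
#' @param path file path.
#' @return `readPoolCounts()` returns a [PoolCounts-class].
#' @export
writePoolCounts <- function(pool, path) {
  sl <- seqlengths(pool)
  hdr <- c(sprintf("#pool_label=%s", metadata(pool)$poolLabel %||% "custom"),
           sprintf("#mean_target_depth=%s",
                   metadata(pool)$meanTargetDepth %||% NA),
           sprintf("#contig=%s,length=%d", names(sl), sl),
           "chrom\tpos\tn_by\tn_awri")
  body <- sprintf("%s\t%d\t%d\t%d", as.character(seqnames(pool)),
                  start(pool), mcols(pool)$nBY, mcols(pool)$nAWRI)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writePoolCounts
#' @export
readPoolCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 200L)
  if (!length(lines)) stop("empty input file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  contig <- grep("^#contig=", meta, value = TRUE)
  if (!length(contig)) stop("pool counts file lacks #contig= header lines")
  id <- sub("^#contig=([^,]+),.*", "\\1", contig)
  len <- as.integer(sub(".*length=([0-9]+).*", "\\1", contig))
  lab <- sub("^#pool_label=", "", grep("^#pool_label=", meta, value = TRUE))
  tdepth <- suppressWarnings(as.numeric(
    sub("^#mean_target_depth=", "",
        grep("^#mean_target_depth=", meta, value = TRUE))))
  dt <- fread(path, skip = length(meta), header = TRUE, sep = "\t")
  need <- c("chrom", "pos", "n_by", "n_awri")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$n_by < 0) || any(dt$n_awri < 0))
    stop("negative counts in ", path)
  PoolCounts(dt$chrom, dt$pos, dt$n_by, dt$n_awri, setNames(len, id),
             poolLabel = if (length(lab)) lab else "custom",
             meanTargetDepth = if (length(tdepth)) tdepth else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a window or delta track as bedGraph-like TSV
#'
#' Columns `chrom`, `start` (0-based), `end`, `value`, `n_snvs`; a header
#' comment records the window size and which value column was exported.
#'
#' @param track a `GRanges` from [windowMedian()] or [poolDelta()].
#' @param path file path.
#' @param value name of the metadata column to export (default the first
#'   of `delta`, `medianFreq` present).
#' @export
writeTrack <- function(track, path,
                       value = intersect(c("delta", "medianFreq"),
                                         names(mcols(track)))[1L]) {
  if (is.na(value) || !value %in% names(mcols(track)))
    stop("no exportable value column")
  nsn <- mcols(track)$nSNVs %||% mcols(track)$nSNVsSelected %||%
    rep(NA_integer_, length(track))
  hdr <- c(sprintf("#window_size=%s", metadata(track)$windowSize %||% NA),
           sprintf("#value=%s", value),
           "chrom\tstart\tend\tvalue\tn_snvs")
  body <- sprintf("%s\t%d\t%d\t%.10g\t%d", as.character(seqnames(track)),
                  start(track) - 1L, end(track), mcols(track)[[value]], nsn)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write QTL peaks as BED6
#'
#' `name` is the enriched parent, `score` the `|apexDelta|` scaled to
#' 0-1000 (delta of 1 on the frequency scale = 1000).
#'
#' @param peaks a `GRanges` from [callPeaks()].
#' @param path file path.
#' @export
writePeaksBed <- function(peaks, path) {
  body <- sprintf("%s\t%d\t%d\t%s\t%d\t.", as.character(seqnames(peaks)),
                  start(peaks) - 1L, end(peaks),
                  mcols(peaks)$enrichedParent,
                  pmin(as.integer(round(
                    1000 * abs(mcols(peaks)$apexDelta))), 1000L))
  writeLines(body, path)
  invisible(path)
}

#' Write haplotype blocks as BED4
#'
#' @param blocks a `GRanges` from [inferBlocks()] (name column = origin).
#' @param path file path.
#' @export
writeBlocksBed <- function(blocks, path) {
  body <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(blocks)),
                  start(blocks) - 1L, end(blocks),
                  as.character(mcols(blocks)$origin))
  writeLines(body, path)
  invisible(path)
}

#' Write / read per-segregant SNV calls
#'
#' TSV with columns `chrom`, `pos`, `call` plus `#contig=`/`#id=` headers.
#'
#' @param calls a [SegregantCalls-class].
#' @param path file path.
#' @export
writeSegregantCalls <- function(calls, path) {
  sl <- seqlengths(calls)
  hdr <- c(sprintf("#id=%s", metadata(calls)$id %||% "segregant"),
           sprintf("#contig=%s,length=%d", names(sl), sl),
           "chrom\tpos\tcall")
  body <- sprintf("%s\t%d\t%s", as.character(seqnames(calls)),
                  start(calls), as.character(mcols(calls)$call))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeSegregantCalls
#' @export
readSegregantCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 200L)
  if (!length(lines)) stop("empty input file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  contig <- grep("^#contig=", meta, value = TRUE)
  id <- sub("^#id=", "", grep("^#id=", meta, value = TRUE))
  chid <- sub("^#contig=([^,]+),.*", "\\1", contig)
  len <- as.integer(sub(".*length=([0-9]+).*", "\\1", contig))
  dt <- fread(path, skip = length(meta), header = TRUE, sep = "\t")
  miss <- setdiff(c("chrom", "pos", "call"), names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(dt$call %in% .ORIGINS))
    stop("calls must be 'BY' or 'AWRI'")
  gr <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L),
                call = factor(dt$call, levels = .ORIGINS),
                seqinfo = Seqinfo(chid, len))
  metadata(gr)$id <- if (length(id)) id else "segregant"
  new("SegregantCalls", gr)
}

#' Read a windowed sequencing-depth track
#'
#' TSV with columns `chrom`, `start` (0-based), `end`, `depth`.
#'
#' @param path file path.
#' @return a `GRanges` with a `depth` column.
#' @export
readDepthTrack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = TRUE, sep = "\t")
  miss <- setdiff(c("chrom", "start", "end", "depth"), names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end), depth = dt$depth)
}
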