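# End-to-end orchestration: one declarative configuration drives
# simulate -> phenotype -> FACS sort -> pool sequencing -> QTL mapping
# (and optionally a backcross), writing all artifacts plus a manifest
# with seeds, row counts and a config hash.

#' Build a validated run configuration
#'
#' Every numeric protocol parameter of the pipeline in one place, with the
#' study's defaults: 68,000 SNVs on the 16-chromosome 12.07 Mb genome,
#' 0.345 cM/kbp, a ~2 % FACS gate, 10,000 bp windows, pseudocount 0.5,
#' min-run 5, 100 histogram classes, pool depths 738x (average) and 1407x
#' (selected).
#'
#' @param ... overrides of the default fields (unknown keys are an
#'   error).  See `runConfigDefaults()` for the full list.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- runConfigDefaults()
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  .validateConfig(cfg)
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @export
runConfigDefaults <- function() {
  list(
    genome = as.list(yeastChromLengths()),
    n_snvs = 68000,
    gmap_rate = 0.345,
    n_segregants = 10000,
    gate_fraction = 0.02,
    window_size = 10000,
    pseudocount = 0.5,
    min_run = 5,
    n_bins = 100,
    depth_average = 738,
    depth_selected = 1407,
    error_rate = 0.002,
    marker_loci = defaultMarkerLoci()[, c("chrom", "pos")],
    marker_origin = "BY",
    trait_model = "default",
    null_sims = 20,
    null_quantile = 0.99,
    min_windows = 2,
    backcross = FALSE,
    backcross_generations = 7,
    backcross_n_per_gen = 190,
    backcross_recurrent = "BY",
    seed = 1
  )
}

.validateConfig <- function(cfg) {
  required <- names(runConfigDefaults())
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  stopifnot(cfg$n_snvs >= 1, cfg$gmap_rate > 0,
            cfg$gate_fraction > 0, cfg$gate_fraction <= 1,
            cfg$window_size > 0, cfg$pseudocount >= 0, cfg$min_run >= 1,
            cfg$n_bins >= 2, cfg$depth_average > 0, cfg$depth_selected > 0,
            cfg$error_rate >= 0, cfg$error_rate < 0.5,
            cfg$backcross_generations >= 2, cfg$backcross_n_per_gen >= 1)
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [runConfigDefaults()], all optional.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$marker_loci)) y$marker_loci <- as.data.frame(y$marker_loci)
  # a trait model can be spelled out in YAML as baseline/loci/epistasis/
  # noise_sd instead of the string "default"
  if (is.list(y$trait_model)) {
    tm <- y$trait_model
    y$trait_model <- TraitModel(
      baseline = tm$baseline %||% 0,
      loci = if (!is.null(tm$loci)) as.data.frame(tm$loci) else
        formals(TraitModel)$loci |> eval(),
      epistasis = if (!is.null(tm$epistasis)) as.data.frame(tm$epistasis)
        else formals(TraitModel)$epistasis |> eval(),
      noiseSD = tm$noise_sd %||% 0)
  }
  do.call(runConfig, y)
}

#' Stable hash of the semantically meaningful configuration
#'
#' @param cfg a `RunConfig`.
#' @return character hash; changes iff a config field changes.
#' @export
configHash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[order(names(cfg))]
  rlang::hash(cfg)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig (", length(x), " fields), hash ", configHash(x), "\n",
      sep = "")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Run the full X-QTL pipeline
#'
#' Simulates the cross, phenotypes the segregants on virtual microplates,
#' applies the FACS gate, sequences the average and selected pools,
#' computes ratio/window/delta tracks, calls peaks against a simulated
#' null, and (optionally) drives a backcross lineage.  All artifacts are
#' written to `outdir` together with `manifest.json` (seed, config hash,
#' per-stage row counts, package version).  Identical config + seed gives
#' byte-identical text outputs.
#'
#' @param config a `RunConfig` (or path to a YAML file).
#' @param outdir output directory (created; must not exist or be empty).
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the main in-memory results
#'   (`map`, `traits`, `histogram`, `windows`, `delta`, `threshold`,
#'   `peaks`, and `backcross` if enabled) plus `outdir`.
#' @export
runPipeline <- function(config = runConfig(), outdir, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateConfig(config)
  if (missing(outdir)) stop("'outdir' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  seed <- as.integer(config$seed)
  sl <- unlist(config$genome)
  manifest <- list(package = as.character(packageVersion("xqtlmap")),
                   seed = seed, config_hash = configHash(config),
                   config = .configForManifest(config), stages = list())

  # -- simulate the cross --------------------------------------------------
  map <- buildParentalMap(config$n_snvs, sl, seed = seed)
  gmap <- uniformGeneticMap(config$gmap_rate, sl)
  ml <- as.data.frame(config$marker_loci)
  pool <- simulateSelectedSegregants(gmap, config$n_segregants,
                                     markerLoci = if (nrow(ml)) ml,
                                     requiredOrigin = config$marker_origin,
                                     seed = seed + 1L)
  writeVariantMap(map, file.path(outdir, "variant_map.vcf"))
  note("simulate-cross", length(map), " SNVs, ", length(pool),
       " marker-surviving segregants")
  manifest$stages$simulate <- list(n_snvs = length(map),
                                   n_segregants = length(pool))

  # -- phenotype -------------------------------------------------------------
  model <- if (identical(config$trait_model, "default")) defaultTraitModel()
           else config$trait_model
  fi <- traitValues(pool, model, seed = seed + 2L)
  pv <- parentValues(model, sl)
  byFI <- pv[["BY"]]
  awriFI <- pv[["AWRI"]]
  plates <- simulatePlateData(fi, byParentFI = byFI, awriParentFI = awriFI,
                              seed = seed + 3L)
  norm <- plateNormalize(plates, referenceStrain = "Y7092")
  fwrite(norm, file.path(outdir, "plates_normalized.csv"))
  segNorm <- norm$normalized[!(norm$strain %in% c("Y7092", "AWRI1631")) &
                               norm$normalized > 0]
  hist <- binDistribution(segNorm, nBins = config$n_bins,
                          byParentValue = 1,
                          awriParentValue = awriFI / byFI)
  .writeHistogram(hist, file.path(outdir, "fi_histogram.tsv"))
  tf <- transgressiveFractions(fi, byFI, awriFI)
  note("phenotype", length(fi), " segregants; transgressive ",
       round(tf[["pctBelowLow"]], 1), "% / ",
       round(tf[["pctAboveHigh"]], 1), "%")
  manifest$stages$phenotype <- list(n = length(fi),
                                    transgressive = as.list(tf))

  # -- FACS sort + pool sequencing -----------------------------------------
  selIdx <- facsSort(fi, config$gate_fraction)
  pcAvg <- poolSequencing(pool, map, config$depth_average,
                          errorRate = config$error_rate, seed = seed + 4L,
                          poolLabel = "average")
  pcSel <- poolSequencing(pool[selIdx], map, config$depth_selected,
                          errorRate = config$error_rate, seed = seed + 5L,
                          poolLabel = "selected")
  writePoolCounts(pcAvg, file.path(outdir, "pool_average.tsv"))
  writePoolCounts(pcSel, file.path(outdir, "pool_selected.tsv"))
  note("poolseq", length(selIdx), " selected of ", length(pool),
       "; depths ", config$depth_average, "/", config$depth_selected)
  manifest$stages$poolseq <- list(n_selected = length(selIdx))

  # -- QTL mapping -----------------------------------------------------------
  wAvg <- windowMedian(alleleRatio(pcAvg, config$pseudocount),
                       config$window_size)
  wSel <- windowMedian(alleleRatio(pcSel, config$pseudocount),
                       config$window_size)
  delta <- poolDelta(wSel, wAvg)
  thr <- nullThreshold(map, gmap,
                       poolSizes = c(length(pool), length(selIdx)),
                       meanDepths = c(config$depth_average,
                                      config$depth_selected),
                       nSims = config$null_sims,
                       quantile = config$null_quantile,
                       windowSize = config$window_size,
                       pseudocount = config$pseudocount,
                       errorRate = config$error_rate, seed = seed + 6L)
  peaks <- callPeaks(delta, thr, minWindows = config$min_windows)
  writeTrack(wAvg, file.path(outdir, "windows_average.tsv"))
  writeTrack(wSel, file.path(outdir, "windows_selected.tsv"))
  writeTrack(delta, file.path(outdir, "delta.tsv"))
  writePeaksBed(peaks, file.path(outdir, "peaks.bed"))
  note("map-qtl", length(delta), " windows, threshold ",
       signif(thr, 3), ", ", length(peaks), " peaks")
  manifest$stages$map_qtl <- list(n_windows = length(delta),
                                  threshold = thr,
                                  n_peaks = length(peaks))

  # -- optional backcross ----------------------------------------------------
  bc <- NULL
  if (isTRUE(config$backcross)) {
    bc <- runBackcross(gmap, founder = mosaic(pool, selIdx[1L]),
                       recurrent = config$backcross_recurrent,
                       generations = config$backcross_generations,
                       nPerGen = config$backcross_n_per_gen,
                       model = model,
                       markerLoci = if (nrow(ml)) ml else NULL,
                       markerOrigin = config$marker_origin,
                       map = map, minRun = config$min_run,
                       seed = seed + 7L)
    fwrite(lineageSummary(bc), file.path(outdir, "backcross_summary.tsv"),
           sep = "\t")
    for (gen in names(lineageBlocks(bc)))
      writeBlocksBed(lineageBlocks(bc)[[gen]],
                     file.path(outdir, paste0("blocks_", gen, ".bed")))
    note("backcross", "F", config$backcross_generations, " donor ",
         round(tail(lineageSummary(bc)$donorFractionPct, 1), 2), "%")
    manifest$stages$backcross <-
      list(donor_fraction_final = tail(lineageSummary(bc)$donorFractionPct,
                                       1))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(map = map, gmap = gmap, traits = fi, histogram = hist,
                 windows = list(average = wAvg, selected = wSel),
                 delta = delta, threshold = thr, peaks = peaks,
                 backcross = bc, outdir = outdir))
}

# manifest-friendly view of a config: S4 trait models become plain lists
.configForManifest <- function(cfg) {
  cfg <- unclass(cfg)
  if (is(cfg$trait_model, "TraitModel")) {
    tm <- cfg$trait_model
    cfg$trait_model <- list(baseline = tm@baseline, loci = tm@loci,
                            epistasis = tm@epistasis, noiseSD = tm@noiseSD)
  }
  cfg
}

.writeHistogram <- function(hist, path) {
  n <- length(hist@counts)
  hdr <- c(sprintf("#anchors=%s", paste(names(hist@anchors), hist@anchors,
                                        sep = ":", collapse = ",")),
           "class\tlog2_left\tlog2_right\tcount")
  body <- sprintf("%d\t%.6f\t%.6f\t%d", seq_len(n), hist@breaks[-(n + 1L)],
                  hist@breaks[-1L], hist@counts)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Plot a selected-minus-average difference track
#'
#' Simple base-graphics karyogram-style strip: one panel row, windows
#' along the concatenated genome, horizontal lines at +/- the threshold.
#'
#' @param delta a `GRanges` from [poolDelta()].
#' @param threshold optional calling threshold to draw.
#' @param ... passed to [plot()].
#' @export
plotDeltaTrack <- function(delta, threshold = NULL, ...) {
  sl <- seqlengths(delta)
  off <- cumsum(c(0, as.numeric(sl[-length(sl)])))
  names(off) <- names(sl)
  x <- off[as.character(seqnames(delta))] + start(delta)
  plot(x, mcols(delta)$delta, pch = 16, cex = 0.3,
       xlab = "genome position (bp, chromosomes concatenated)",
       ylab = "AWRI-frequency delta (selected - average)", ...)
  graphics::abline(v = cumsum(as.numeric(sl)), col = "grey80")
  graphics::abline(h = 0, col = "grey50")
  if (!is.null(threshold))
    graphics::abline(h = c(-threshold, threshold), col = "red", lty = 2)
  invisible(NULL)
}
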