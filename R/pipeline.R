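# Deterministic per-stage seed derived from the run seed.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Default pipeline run configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it deterministically, so stages can be rerun independently.
#' @param simulate list of [simConfig()] arguments (empty list: simulator
#'   defaults), or `FALSE` to read an existing screen from `inputDir`.
#' @param inputDir directory with screen tables (used when `simulate` is
#'   `NULL`).
#' @param features features to score (`NULL` = all).
#' @param modes scoring modes to run (subset of `"N"`, `"P"`, `"U"`,
#'   `"traditional"`).
#' @param threshold hit-calling Z-score cutoff.
#' @param thresholds threshold grid for bands and power fits.
#' @param nPerm permutations for the null band.
#' @param holdout held-out negative count per slide.
#' @param cellState `TRUE` to compute the Delta-y matrix.
#' @return named list (a run configuration).
#' @export
runConfig <- function(seed = 1L, simulate = list(), inputDir = NULL,
                      features = NULL, modes = "N", threshold = 3,
                      thresholds = seq(0.5, 6, 0.25), nPerm = 1000L,
                      holdout = 10L, cellState = FALSE) {
  list(seed = seed, simulate = simulate, inputDir = inputDir,
       features = features, modes = modes, threshold = threshold,
       thresholds = thresholds, nPerm = nPerm, holdout = holdout,
       cellState = cellState)
}

#' Run the full screen-analysis pipeline
#'
#' Executes simulate (or load) -> diagnostics -> scoring (all requested
#' modes) -> hit calling + permutation band -> triplicate power fit
#' (-> cell-state Delta-y when requested) and writes every result as a
#' delimited text table plus a machine-readable `manifest.json` recording
#' the configuration, the derived per-stage seeds and the package
#' version. Outputs are byte-stable for a fixed configuration and seed
#' (the manifest's timestamp aside).
#'
#' @param config a [runConfig()] list, or the path of a YAML file of the
#'   same structure.
#' @param outDir output directory (created).
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- runConfig()
  for (nm in setdiff(names(defaults), names(config)))
    config[[nm]] <- defaults[[nm]]
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seeds <- list()

  doSim <- !is.null(config$simulate) && !isFALSE(config$simulate)
  if (doSim) {
    seeds$simulate <- .stageSeed(config$seed, "simulate")
    cfgArgs <- config$simulate
    cfgArgs$seed <- seeds$simulate
    screen <- generateScreen(do.call(simConfig, cfgArgs))
    writeScreen(screen, file.path(outDir, "screen"))
  } else {
    if (is.null(config$inputDir))
      stop("configuration error: neither 'simulate' nor 'inputDir' given")
    screen <- readScreen(config$inputDir)
  }
  feats <- config$features
  if (is.null(feats)) feats <- rownames(screen)

  diag <- diagnosticsReport(screen, features = feats,
                            measures = c("mean", "skewness"),
                            grouping = "row")
  .writeTsv(diag, file.path(outDir, "diagnostics.tsv"))

  if ("P" %in% config$modes &&
      !all(c("row", "col") %in% colnames(screenLayout(screen))))
    stop("configuration error: mode P requires row/col positions in layout")

  allScores <- list()
  for (mode in config$modes) {
    sc <- scoreScreen(screen, features = feats, mode = mode,
                      holdout = if (mode %in% c("N", "P", "U"))
                        config$holdout else NULL)
    tab <- scoresTable(sc)
    .writeTsv(tab, file.path(outDir, sprintf("scores_%s.tsv", mode)))
    allScores[[mode]] <- tab
  }

  primary <- allScores[[config$modes[1]]]
  gst <- geneScoreTable(primary)
  hits <- do.call(rbind, lapply(split(gst, gst$feature), callHits,
                                threshold = config$threshold))
  rownames(hits) <- NULL
  .writeTsv(hits, file.path(outDir, "hits.tsv"))

  seeds$permute <- .stageSeed(config$seed, "permute")
  bands <- lapply(split(gst, gst$feature), function(g)
    permutationBand(g, thresholds = config$thresholds,
                    nPerm = config$nPerm, seed = seeds$permute))
  bandTab <- do.call(rbind, lapply(bands, function(b)
    data.frame(feature = b@feature, threshold = b@thresholds,
               band_min = b@minCount, band_max = b@maxCount,
               observed = b@observed)))
  rownames(bandTab) <- NULL
  .writeTsv(bandTab, file.path(outDir, "band.tsv"))

  seeds$power <- .stageSeed(config$seed, "power")
  fitTabs <- list()
  for (f in unique(gst$feature)) {
    bins <- binsFromScores(gst[gst$feature == f, ], config$thresholds)
    fit <- fitPowerModel(bins, seed = seeds$power)
    tab <- fit@table
    tab$feature <- f
    tab$h <- fit@h
    tab$fit_converged <- fit@converged
    fitTabs[[f]] <- tab
  }
  .writeTsv(do.call(rbind, fitTabs), file.path(outDir, "power_fit.tsv"))

  if (isTRUE(config$cellState)) {
    seeds$cellstate <- .stageSeed(config$seed, "cellstate")
    dy <- deltaYMatrix(screen, nPerm = 0L, seed = seeds$cellstate)
    dyTab <- as.data.frame(as.table(dy@delta))
    colnames(dyTab) <- c("classifier", "output", "delta_y")
    .writeTsv(dyTab, file.path(outDir, "cellstate.tsv"))
  }

  cfgOut <- config
  if (doSim && !is.null(cfgOut$simulate$features))
    cfgOut$simulate$features <- lapply(cfgOut$simulate$features, unclass)
  manifest <- list(config = cfgOut, seeds = seeds,
                   package_version =
                     as.character(packageVersion("shapescreen")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
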