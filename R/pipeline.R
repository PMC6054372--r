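#' @include AllClasses.R construct.R pulling.R trace-analysis.R pillar.R frap.R io.R
NULL

.schemaVersion <- 1L

#' Stage outputs with provenance
#'
#' @slot stage stage name
#' @slot outputs named list of output file paths / in-memory results
#' @slot summary named list of human-readable summary values
#' @slot provenance list(config, masterSeed, timestamp, schemaVersion)
#' @export
setClass("ResultBundle",
  representation(stage = "character", outputs = "list", summary = "list",
                 provenance = "list"))

setMethod("show", "ResultBundle", function(object) {
  cat(sprintf("ResultBundle[%s]\n", object@stage))
  for (nm in names(object@summary))
    cat(sprintf("  %s: %s\n", nm,
                paste(format(object@summary[[nm]], digits = 5),
                      collapse = " ")))
})

#' Read a run configuration
#'
#' A single YAML file with per-stage sections plus top-level
#' \code{master_seed} and \code{output_dir}.
#'
#' @param path YAML config path.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

.require_keys <- function(cfg, keys, where) {
  miss <- setdiff(keys, names(cfg))
  if (length(miss))
    stop("config validation error: missing ", where, " key(s): ",
         paste(miss, collapse = ", "))
}

.stageNames <- c("simulate-pulling", "analyze-traces", "simulate-pillars",
                 "track-pillars", "simulate-frap", "fit-frap",
                 "compare-frap", "quantify-ratio")

#' Run one pipeline stage
#'
#' Executes a named stage from a run configuration, writes its outputs and
#' a provenance record into the output directory, and returns a
#' \linkS4class{ResultBundle}. Configuration is validated before any
#' compute; reruns with an identical configuration reproduce deterministic
#' outputs byte for byte.
#'
#' Stages: \code{simulate-pulling} (keys n_traces, clamp), \code{analyze-traces}
#' (key input_dir), \code{simulate-pillars} (keys n_frames, amplitude_px,
#' drift_px, noise_sd), \code{track-pillars} (key stack),
#' \code{simulate-frap} (keys n_curves, floor, plateau, tau, noise_sd),
#' \code{fit-frap} (key input_dir), \code{compare-frap} (keys dir_a,
#' dir_b), \code{quantify-ratio} (key ratios).
#'
#' @param config a config list (see \code{\link{readRunConfig}}) with
#'   \code{master_seed}, \code{output_dir} and a section named after the
#'   stage.
#' @param stage one of the stage names above.
#' @return A \linkS4class{ResultBundle}.
#' @export
runPipeline <- function(config, stage) {
  if (!stage %in% .stageNames)
    stop("unknown stage '", stage, "'; stages are: ",
         paste(.stageNames, collapse = ", "))
  .require_keys(config, c("master_seed", "output_dir"), "top-level")
  sc <- config[[stage]]
  if (is.null(sc)) sc <- list()
  seed <- as.integer(config$master_seed)
  outDir <- file.path(config$output_dir, stage)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  res <- switch(stage,
    "simulate-pulling" = {
      .require_keys(sc, c("n_traces", "clamp"), stage)
      construct <- if (!is.null(sc$construct_file))
        readConstructFile(sc$construct_file)
      else talinR7R8Construct(clamped = isTRUE(sc$clamp))
      protocol <- PullingProtocol(
        forceNoiseSd = if (is.null(sc$noise_sd)) 5 else sc$noise_sd)
      traces <- simulateDataset(construct, protocol, sc$n_traces, seed)
      paths <- vapply(seq_along(traces), function(i) {
        p <- file.path(outDir, sprintf("trace_%03d.csv", i))
        writeTraceFile(traces[[i]], p)
        p
      }, character(1))
      list(outputs = list(traces = paths),
           summary = list(n_traces = length(paths),
                          clamp = isTRUE(sc$clamp)))
    },
    "analyze-traces" = {
      .require_keys(sc, "input_dir", stage)
      files <- list.files(sc$input_dir, pattern = "\\.csv$",
                          full.names = TRUE)
      files <- files[!grepl("\\.events\\.csv$", files)]
      if (!length(files)) stop("no trace files in ", sc$input_dir)
      traces <- lapply(files, readTraceFile)
      results <- analyzeDataset(traces)
      lens <- cohortUnfoldingLengths(results)
      fit <- if (length(lens) >= 3) fitGaussianHistogram(lens, 5) else NULL
      tab <- data.frame(
        file = basename(files),
        accepted = vapply(results, isAccepted, logical(1)),
        unfolding_length_nm = vapply(results, unfoldingLength, numeric(1)))
      p <- file.path(outDir, "trace_results.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      list(outputs = list(results = p),
           summary = list(
             n_accepted = length(lens),
             mean_unfolding_length_nm =
               if (is.null(fit)) NA_real_ else fit@mean))
    },
    "simulate-pillars" = {
      .require_keys(sc, c("n_frames", "amplitude_px", "drift_px",
                          "noise_sd"), stage)
      grid <- PillarGrid()
      mask <- circularCellMask(grid)
      field <- radialContractionField(pillarNodes(grid), mask,
                                      sc$amplitude_px, sc$n_frames)
      movie <- generatePillarMovie(grid, field, drift = rep(sc$drift_px, 2),
                                   noiseSd = sc$noise_sd,
                                   nFrames = sc$n_frames, seed = seed,
                                   cellMask = mask)
      p <- file.path(outDir, "movie.tif")
      writePillarMovie(movie, p)
      list(outputs = list(stack = p, movie = movie),
           summary = list(n_frames = sc$n_frames,
                          n_pillars = nrow(movie@nodes)))
    },
    "track-pillars" = {
      .require_keys(sc, "stack", stage)
      grid <- PillarGrid()
      stack <- readPillarStack(sc$stack)
      nodes <- pillarNodes(grid)
      mask <- circularCellMask(grid)
      tracks <- trackPillarMovie(stack, grid)
      tracks <- correctDrift(tracks, which(!mask))
      map <- displacementsToForces(tracks, grid, mask)
      p <- file.path(outDir, "tracks.csv")
      writeTrackTable(tracks, p, map)
      hm <- file.path(outDir, "peak_forces.png")
      plotForceHeatmap(map, nodes, hm)
      list(outputs = list(tracks = p, heatmap = hm, map = map),
           summary = list(cell_mean_force_nN = cellMeanForce(map)))
    },
    "simulate-frap" = {
      .require_keys(sc, c("n_curves", "floor", "plateau", "tau",
                          "noise_sd"), stage)
      seeds <- deriveSeeds(seed, sc$n_curves)
      paths <- vapply(seq_len(sc$n_curves), function(i) {
        cv <- simulateFrapCurve(sc$floor, sc$plateau, sc$tau, sc$noise_sd,
                                seed = seeds[i])
        p <- file.path(outDir, sprintf("curve_%03d.csv", i))
        writeFrapCurve(cv, p)
        p
      }, character(1))
      list(outputs = list(curves = paths),
           summary = list(n_curves = sc$n_curves))
    },
    "fit-frap" = {
      .require_keys(sc, "input_dir", stage)
      files <- list.files(sc$input_dir, pattern = "^curve_.*\\.csv$",
                          full.names = TRUE)
      if (!length(files)) stop("no FRAP curves in ", sc$input_dir)
      fits <- lapply(files, function(f)
        fitRecovery(readFrapCurve(f, normalized = TRUE)))
      tab <- data.frame(
        file = basename(files),
        floor = vapply(fits, function(x) x@floor, numeric(1)),
        plateau = vapply(fits, function(x) x@plateau, numeric(1)),
        tau_s = vapply(fits, function(x) x@tau, numeric(1)),
        immobile_fraction = vapply(fits, immobileFraction, numeric(1)))
      p <- file.path(outDir, "frap_fits.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      list(outputs = list(fits = p),
           summary = list(mean_immobile_fraction =
                            mean(tab$immobile_fraction)))
    },
    "compare-frap" = {
      .require_keys(sc, c("dir_a", "dir_b"), stage)
      rd <- function(d) lapply(
        list.files(d, pattern = "^curve_.*\\.csv$", full.names = TRUE),
        readFrapCurve, normalized = TRUE)
      ft <- extraSSFTest(rd(sc$dir_a), rd(sc$dir_b))
      list(outputs = list(test = ft),
           summary = list(F = ft@fStatistic, p_value = ft@pValue))
    },
    "quantify-ratio" = {
      .require_keys(sc, "ratios", stage)
      sim <- simulateStainImages(as.numeric(sc$ratios),
                                 noiseSd = if (is.null(sc$noise_sd)) 0
                                           else sc$noise_sd,
                                 seed = seed)
      rt <- intensityRatio(sim$numerator, sim$denominator, sim$masks,
                           backgroundNumerator = 50,
                           backgroundDenominator = 50)
      p <- file.path(outDir, "ratios.csv")
      utils::write.csv(rt, p, row.names = FALSE)
      list(outputs = list(ratios = p),
           summary = list(mean_ratio = mean(rt$ratio, na.rm = TRUE)))
    })

  prov <- list(stage = stage, config = config, master_seed = seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               schema_version = .schemaVersion)
  yaml::write_yaml(prov, file.path(outDir, "provenance.yaml"))
  new("ResultBundle", stage = stage, outputs = res$outputs,
      summary = res$summary,
      provenance = prov)
}
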