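.config_keys <- c("task", "model", "fm", "grid", "nTrials", "duration",
                  "dt", "seed", "scenarios", "name")

#' Read and validate an experiment configuration
#'
#' Configurations are plain-text YAML (or JSON) documents with keys
#' `task` (`"ild"`, `"phase"` or `"population"`), `model` (`"active"` or
#' `"passive"`), `fm`, `grid`, `nTrials`, `duration`, `dt`, `seed`,
#' `name`, and `scenarios` — a list of `{mInh, mode}` entries. Unknown keys
#' are rejected.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated config list of class `lso_config`.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateExperimentConfig(cfg)
}

#' @rdname readExperimentConfig
#' @param cfg A config list (as parsed from YAML/JSON).
#' @export
validateExperimentConfig <- function(cfg) {
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(task = "ild", model = "active", fm = 300, grid = NULL,
                   nTrials = 500, duration = 500, dt = 0.01, seed = 1,
                   name = "experiment")
  scen <- if (is.null(cfg$scenarios))
    list(list(mInh = 8, mode = "uncompensated")) else cfg$scenarios
  cfg$scenarios <- NULL
  cfg <- utils::modifyList(defaults, cfg)
  cfg$scenarios <- scen
  if (!cfg$task %in% c("ild", "phase", "population"))
    stop("config key 'task' must be ild, phase or population")
  if (!cfg$model %in% c("active", "passive"))
    stop("config key 'model' must be active or passive")
  stopifnot(cfg$nTrials >= 2, cfg$duration > 0, cfg$dt > 0)
  cfg$scenarios <- lapply(cfg$scenarios, function(s)
    scenarioSpec(s$mInh, if (is.null(s$mode)) "uncompensated" else s$mode))
  structure(cfg, class = "lso_config")
}

#' Preset experiment configurations
#'
#' Ready-made configurations for the standard simulation campaigns:
#' \describe{
#'   \item{`"default-ild"`, `"default-phase"`}{single healthy-scenario
#'     tuning curves.}
#'   \item{`"uncompensated-sweep"`, `"compensated-sweep"`,
#'     `"overcompensated-sweep"`}{ILD sweeps over
#'     `mInh = 0/1/2/4/6/8/12/16` (compensation modes start at 1).}
#'   \item{`"phase-sweep-150"`, `"phase-sweep-300"`, `"phase-sweep-450"`}{
#'     compensated phase sweeps at the three modulation frequencies.}
#'   \item{`"passive-sweep"`}{uncompensated ILD sweep with the passive IF
#'     model.}
#'   \item{`"population"`}{mirrored-pair population, compensated sweep.}
#' }
#'
#' @param name Preset name.
#' @param scale Multiplier applied to `nTrials` (e.g. `0.1` for a quick
#'   smoke run).
#' @param seed Master seed.
#' @return An `lso_config` object.
#' @export
experimentPreset <- function(name, scale = 1, seed = 1) {
  sweep <- function(mode, ms) lapply(ms, function(m) list(mInh = m, mode = mode))
  uncomp <- sweep("uncompensated", c(0, 1, 2, 4, 6, 8, 12, 16))
  comp <- sweep("compensated", c(1, 2, 4, 6, 8, 12, 16))
  overcomp <- sweep("overcompensated", c(1, 2, 4, 6, 8, 12, 16))
  base <- list(name = name, seed = seed)
  cfg <- switch(name,
    "default-ild" = c(base, list(task = "ild")),
    "default-phase" = c(base, list(task = "phase")),
    "uncompensated-sweep" = c(base, list(task = "ild", scenarios = uncomp)),
    "compensated-sweep" = c(base, list(task = "ild", scenarios = comp)),
    "overcompensated-sweep" = c(base, list(task = "ild", scenarios = overcomp)),
    "phase-sweep-150" = c(base, list(task = "phase", fm = 150, scenarios = comp)),
    "phase-sweep-300" = c(base, list(task = "phase", fm = 300, scenarios = comp)),
    "phase-sweep-450" = c(base, list(task = "phase", fm = 450, scenarios = comp)),
    "passive-sweep" = c(base, list(task = "ild", model = "passive",
                                   scenarios = uncomp)),
    "population" = c(base, list(task = "population", scenarios = comp)),
    stop("unknown preset: ", name))
  cfg$nTrials <- max(2L, as.integer(round(500 * scale)))
  validateExperimentConfig(cfg)
}

#' Run an experiment and write its outputs
#'
#' Executes the configured scenario sweep and writes, per run:
#' `tuning.csv` (per-scenario tuning curves), `discriminability.csv`,
#' `summary.json` (modulation depth, midpoint where defined, averaged
#' absolute discriminability and its normalization to the `mInh = 8` value),
#' and `manifest.json` (config echo, package version, seed, wall time).
#' Identical config and seed give byte-identical CSV contents.
#'
#' @param cfg An `lso_config` (see [readExperimentConfig()],
#'   [experimentPreset()]).
#' @param outDir Output directory (created if missing).
#' @param quiet Suppress per-scenario progress messages.
#' @return Invisibly, the summary list.
#' @export
runExperiment <- function(cfg, outDir, quiet = FALSE) {
  stopifnot(inherits(cfg, "lso_config"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  t0 <- Sys.time()
  avgRange <- if (cfg$task == "ild") c(-45, 15) else NULL
  rows <- list(); drows <- list(); summ <- list()
  popSpec <- populationSpec()

  for (sc in cfg$scenarios) {
    tag <- sprintf("m%02d_%s", sc$mInh, sc$mode)
    if (!quiet)
      message(sprintf("[%s] scenario %s (AInh = %.3g nS)", cfg$name, tag,
                      if (sc$mInh > 0) effectiveInhibitoryAmplitude(sc) else 0))
    if (cfg$task == "population") {
      pop <- runPopulation(popSpec, sc, nTrials = cfg$nTrials,
                           duration = cfg$duration, dt = cfg$dt,
                           seed = cfg$seed, model = cfg$model)
      pd <- populationDiscriminability(pop, popSpec$averageRange)
      drows[[tag]] <- data.frame(scenario = tag, mInh = sc$mInh,
                                 compensation = sc$mode,
                                 midpoint_stimulus = pd$curve$midpoint,
                                 D = pd$curve$meanAbsD)
      summ[[tag]] <- list(mInh = sc$mInh, mode = sc$mode,
                          nPairs = length(pop),
                          populationDiscriminability = pd$scalar)
    } else {
      tc <- runTuning(task = cfg$task, grid = cfg$grid, scenario = sc,
                      model = cfg$model, fm = cfg$fm, nTrials = cfg$nTrials,
                      duration = cfg$duration, dt = cfg$dt, seed = cfg$seed)
      dc <- discriminability(tc)
      rows[[tag]] <- data.frame(scenario = tag, mInh = sc$mInh,
                                compensation = sc$mode,
                                stimulus = tc$stimulus,
                                mean_rate = tc$meanRate,
                                sd_rate = tc$sdRate, fano = tc$fano)
      drows[[tag]] <- data.frame(scenario = tag, mInh = sc$mInh,
                                 compensation = sc$mode,
                                 midpoint_stimulus = dc$midpoint, D = dc$D)
      mid <- if (cfg$task == "ild" && modulationDepth(tc) > 0)
        tryCatch(midpointIld(tc), error = function(e) NA_real_) else NA_real_
      summ[[tag]] <- list(mInh = sc$mInh, mode = sc$mode,
                          modulationDepth = modulationDepth(tc),
                          midpoint = mid,
                          meanAbsD = summarizeDiscriminability(dc, avgRange))
    }
  }

  # normalize discriminability to the mInh = 8 scenario when present
  ref <- Filter(function(s) s$mInh == 8, summ)
  if (length(ref)) {
    key <- if (cfg$task == "population") "populationDiscriminability" else "meanAbsD"
    refval <- ref[[1]][[key]]
    summ <- lapply(summ, function(s) {
      s$normalizedD <- s[[key]] / refval
      s
    })
  }

  if (length(rows))
    utils::write.csv(do.call(rbind, rows),
                     file.path(outDir, "tuning.csv"), row.names = FALSE)
  if (length(drows))
    utils::write.csv(do.call(rbind, drows),
                     file.path(outDir, "discriminability.csv"),
                     row.names = FALSE)
  jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config = lapply(unclass(cfg), function(x)
      if (inherits(x, "lso_scenario")) unclass(x) else x),
    package = "lsosim",
    version = as.character(utils::packageVersion("lsosim")),
    seed = cfg$seed,
    wallTimeSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  manifest$config$scenarios <- lapply(cfg$scenarios, unclass)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}
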