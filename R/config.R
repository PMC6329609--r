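#' @include scoring.R
NULL

#' Fully-defaulted run configuration
#'
#' The configuration schema: `model` (family, n_genes, builder parameter
#' overrides), `morphogen`, `growth`, `protocol` (list of events),
#' `integrator`, `analysis`, `ensemble`, `output`. [loadConfig()] fills
#' omitted fields from these defaults and rejects unknown keys.
#'
#' @return Nested named list.
#' @export
defaultConfig <- function() {
  list(
    model = list(family = "SR2M", n_genes = 5L, params = list()),
    morphogen = list(regime = "static", M_amp = 1, xi = 10,
                     tau_build = NULL, t_decay_start = NULL,
                     tau_decay = NULL, t_germband = NULL, xi_axn = NULL),
    growth = list(n0 = 50L, n_final = 50L, t_start = 0, rate = 0),
    protocol = list(),
    integrator = list(dt = 0.001, dt_out = 0.1, t_end = 60),
    analysis = list(epsilon_g = NULL, epsilon_m = NULL, steady_tol = 1e-6,
                    windows = list()),
    ensemble = list(size = 1L, jitter_sigma = 0.15, noise_sigma = 0.05,
                    seed = NULL),
    output = list(dir = NULL)
  )
}

.checkKeys <- function(cfg, schema, path = "") {
  bad <- character()
  for (nm in names(cfg)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(schema)) {
      bad <- c(bad, full)
    } else if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]])) &&
               is.list(cfg[[nm]]) &&
               !nm %in% c("params", "protocol", "windows")) {
      bad <- c(bad, .checkKeys(cfg[[nm]], schema[[nm]], full))
    }
  }
  bad
}

.mergeConfig <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]]) && !nm %in% c("params", "protocol", "windows")) {
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], cfg[[nm]])
    } else {
      defaults[[nm]] <- cfg[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys with an
#' error naming them, fills every omitted field from [defaultConfig()],
#' and applies consistency checks (a seed is mandatory for ensembles).
#' Loading the file written by [writeConfig()] reproduces the identical
#' effective configuration.
#'
#' @param path path to a YAML or JSON config file, or a named list.
#' @return The effective configuration (class `segwaveConfig`).
#' @export
loadConfig <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  schema <- defaultConfig()
  bad <- .checkKeys(cfg, schema)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  eff <- .mergeConfig(schema, cfg)
  eff$model$n_genes <- as.integer(eff$model$n_genes)
  eff$growth$n0 <- as.integer(eff$growth$n0)
  eff$growth$n_final <- as.integer(eff$growth$n_final)
  eff$ensemble$size <- as.integer(eff$ensemble$size)
  if (eff$ensemble$size > 1 && is.null(eff$ensemble$seed))
    stop("a seed is mandatory when ensemble size > 1")
  if (!eff$model$family %in% c("FF", "FFTG", "SR2M", "SRDM"))
    stop("unknown model family: ", eff$model$family)
  class(eff) <- c("segwaveConfig", "list")
  eff
}

#' Write the effective configuration
#'
#' @param cfg a configuration from [loadConfig()] or [presetConfig()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  dropNull <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, logical(1))]
    lapply(x, dropNull)
  }
  yaml::write_yaml(dropNull(unclass(cfg)), path, precision = 15)
  invisible(path)
}

#' Build simulation objects from a configuration
#'
#' @param cfg an effective configuration.
#' @return List with `network`, `program`, `schedule`, `protocol` (possibly
#'   `NULL`).
#' @export
buildFromConfig <- function(cfg) {
  m <- cfg$model
  params <- if (length(m$params)) m$params else list()
  network <- switch(m$family,
    FF = buildFF(m$n_genes, params),
    FFTG = buildFFTG(m$n_genes, tEndScenario = cfg$integrator$t_end,
                     params = params),
    SR2M = buildSRTwoModule(m$n_genes, params),
    SRDM = buildSRDecayMod(m$n_genes, params))
  mo <- cfg$morphogen
  nn <- function(x) if (is.null(x)) NA_real_ else x
  program <- morphogenProgram(mo$regime, mo$M_amp, mo$xi, nn(mo$tau_build),
                              nn(mo$t_decay_start), nn(mo$tau_decay),
                              nn(mo$t_germband), nn(mo$xi_axn))
  g <- cfg$growth
  schedule <- growthSchedule(g$n0, g$n_final, g$t_start, g$rate)
  protocol <- if (length(cfg$protocol)) protocolFromParams(cfg$protocol)
              else NULL
  list(network = network, program = program, schedule = schedule,
       protocol = protocol)
}

#' Run a scenario end to end
#'
#' Accepts a preset name (see [presetNames()]) or a configuration, runs the
#' simulation (and, when a protocol is present, the matching control run;
#' when `ensemble$size > 1`, the whole ensemble plus region scoring), and
#' optionally writes artifacts: the kymograph TSV with its JSON metadata
#' sidecar, the effective configuration with its hash in a manifest, a
#' reset report and/or score table where applicable. All outputs are
#' deterministic given the seed.
#'
#' @param x preset name or configuration.
#' @param outDir output directory (`NULL`: nothing is written).
#' @param seed overrides the configuration's ensemble seed.
#' @param dt,dtOut optional overrides of the configured integrator grid
#'   (coarser grids speed up exploratory runs).
#' @return Invisibly, a list with the configuration and the computed
#'   objects (`kymograph`, `control`, `resetReport`, `ensemble`, `scores`
#'   as applicable) plus written file paths.
#' @export
runScenario <- function(x, outDir = NULL, seed = NULL,
                        dt = NULL, dtOut = NULL) {
  cfg <- if (is.character(x)) presetConfig(x) else loadConfig(x)
  if (!is.null(seed)) cfg$ensemble$seed <- as.integer(seed)
  if (!is.null(dt)) cfg$integrator$dt <- dt
  if (!is.null(dtOut)) cfg$integrator$dt_out <- dtOut
  obj <- buildFromConfig(cfg)
  it <- cfg$integrator
  res <- list(config = cfg)
  seedVal <- if (is.null(cfg$ensemble$seed)) NA_integer_
             else as.integer(cfg$ensemble$seed)
  if (cfg$ensemble$size > 1) {
    res$ensemble <- simulateEnsemble(obj$network, obj$program, obj$schedule,
                                     it$t_end, protocol = obj$protocol,
                                     size = cfg$ensemble$size,
                                     seed = cfg$ensemble$seed,
                                     jitterSigma = cfg$ensemble$jitter_sigma,
                                     noiseSigma = cfg$ensemble$noise_sigma,
                                     dt = it$dt, dtOut = it$dt_out)
    res$control <- simulateEnsemble(obj$network, obj$program, obj$schedule,
                                    it$t_end, protocol = NULL,
                                    size = cfg$ensemble$size,
                                    seed = cfg$ensemble$seed,
                                    jitterSigma = cfg$ensemble$jitter_sigma,
                                    noiseSigma = cfg$ensemble$noise_sigma,
                                    dt = it$dt, dtOut = it$dt_out)
    if (length(cfg$analysis$windows)) {
      res$scores <- scoreRegions(res$ensemble, obj$protocol,
                                 cfg$analysis$windows,
                                 cfg$analysis$epsilon_g,
                                 cfg$analysis$epsilon_m)
      res$controlScores <- scoreRegions(res$control, obj$protocol,
                                        cfg$analysis$windows,
                                        cfg$analysis$epsilon_g,
                                        cfg$analysis$epsilon_m)
    }
  } else {
    res$kymograph <- simulateTissue(obj$network, obj$program, obj$schedule,
                                    it$t_end, dt = it$dt, dtOut = it$dt_out,
                                    protocol = obj$protocol, seed = seedVal)
    if (!is.null(obj$protocol)) {
      res$control <- simulateTissue(obj$network, obj$program, obj$schedule,
                                    it$t_end, dt = it$dt, dtOut = it$dt_out,
                                    seed = seedVal)
      hasRe <- any(vapply(obj$protocol@events,
                          function(e) e$type == "reinduce", logical(1)))
      if (hasRe)
        res$resetReport <- resetAssay(res$kymograph, res$control,
                                      obj$protocol,
                                      cfg$analysis$epsilon_g,
                                      cfg$analysis$epsilon_m)
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    cfgPath <- file.path(outDir, "effective_config.yaml")
    writeConfig(cfg, cfgPath)
    paths$config <- cfgPath
    if (!is.null(res$kymograph)) {
      paths$kymograph <- file.path(outDir, "kymograph.tsv")
      exportKymograph(res$kymograph, paths$kymograph)
    }
    if (!is.null(res$control) && is(res$control, "Kymograph")) {
      paths$control <- file.path(outDir, "control.tsv")
      exportKymograph(res$control, paths$control)
    }
    if (!is.null(res$resetReport)) {
      paths$resetReport <- file.path(outDir, "reset_report.json")
      rr <- res$resetReport
      jsonlite::write_json(
        list(anterior_erased = rr@anteriorErased,
             sequence_reinduced = rr@sequenceReinduced,
             final_pattern_restored = rr@finalPatternRestored,
             anterior_fate_loss = rr@anteriorFateLoss,
             classification = rr@classification, details = rr@details),
        paths$resetReport, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(res$scores)) {
      paths$scores <- file.path(outDir, "scores.csv")
      exportScores(res$scores, paths$scores)
      paths$controlScores <- file.path(outDir, "control_scores.csv")
      exportScores(res$controlScores, paths$controlScores)
    }
    manifest <- list(package = "segwave",
                     version = as.character(utils::packageVersion("segwave")),
                     config_md5 = unname(tools::md5sum(cfgPath)),
                     seed = seedVal)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    paths$manifest <- file.path(outDir, "manifest.json")
    res$paths <- paths
  }
  invisible(res)
}
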