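#' @include AllClasses.R
NULL

#' Run the simulate -> track -> motion -> kinetics pipeline
#'
#' End-to-end driver: simulates trajectories and a kymograph from a
#' \linkS4class{SimulationConfig}, tracks the kymograph lines, merges
#' blink gaps, segments motion phases and fits diffusion, extracts dwells
#' and fits the binding lifetime, optionally applying the photobleaching
#' correction. Selected stages run in order; a stage failure stops with
#' the stage named, keeping outputs of completed stages. Reports embed the
#' seed, a config hash and the package version, and runs are deterministic
#' given the seed.
#'
#' @param config a \linkS4class{SimulationConfig} (fields are echoed into
#'   the report, including defaults).
#' @param nParticles particles to simulate.
#' @param stages subset of c("simulate", "track", "motion", "kinetics").
#' @param outDir optional directory; when given, tracks/dwells CSVs and the
#'   JSON report are written there.
#' @param trackFromKymograph when TRUE, positions come from kymograph line
#'   tracking; otherwise the simulated tracks are analyzed directly
#'   (faster, localization noise only).
#' @param bleachTrace optional photon trace for
#'   \code{\link{estimateBleachLifetime}}; when supplied the fitted
#'   lifetime is bleach-corrected.
#' @param lifetimeMethod "survival_decay" or "crtd".
#' @return list with elements per executed stage plus \code{meta}.
#' @export
runPipeline <- function(config, nParticles = 50,
                        stages = c("simulate", "track", "motion", "kinetics"),
                        outDir = NULL, trackFromKymograph = FALSE,
                        bleachTrace = NULL,
                        lifetimeMethod = "survival_decay") {
  stages <- match.arg(stages, several.ok = TRUE)
  validObject(config)
  report <- list(meta = list(
    seed = config@rngSeed,
    config_hash = configHash(config),
    package_version = as.character(utils::packageVersion("smtrack")),
    stages = stages))
  window <- config@nFrames * config@frameInterval
  runStage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  sim <- NULL; tracks <- NULL
  if ("simulate" %in% stages) {
    sim <- runStage("simulate", function()
      simulateTrajectories(config, nParticles))
    report$simulate <- list(n_particles = nParticles,
                            n_track_rows = nrow(sim$tracks))
    tracks <- sim$tracks
  }
  if ("track" %in% stages) {
    tracks <- runStage("track", function() {
      if (trackFromKymograph) {
        kymo <- renderKymograph(sim, config)
        tr <- trackLines(kymo, psfSigma = config@psfSigma)
        mergeBlinkGaps(tr, maxGap = 2.0)
      } else {
        mergeBlinkGaps(sim$tracks, maxGap = 2.0)
      }
    })
    report$track <- list(n_tracks = length(unique(tracks$particle_id)))
    if (!is.null(outDir))
      writeTracksCsv(tracks, file.path(outDir, "tracks.csv"))
  }
  if ("motion" %in% stages) {
    phases <- runStage("motion", function()
      analyzeMotion(tracks, config@frameInterval,
                    localizationSigma = config@localizationSigma))
    behavior <- classifyBehavior(tracks, phases, window)
    acc <- phases[phases$accepted, , drop = FALSE]
    report$motion <- list(
      n_phases = nrow(phases), n_accepted = nrow(acc),
      mean_D_um2_s = if (nrow(acc)) mean(acc$D_um2_s) else NA_real_,
      mean_alpha = if (nrow(acc)) mean(acc$alpha) else NA_real_,
      behavior = behavior[, c("motility", "fate", "count")])
    report$phases <- phases
  }
  if ("kinetics" %in% stages) {
    dwells <- runStage("kinetics", function()
      extractDwells(tracks, window))
    if (!is.null(outDir))
      writeDwellsCsv(dwells, file.path(outDir, "dwells.csv"))
    fit <- tryCatch(fitSurvival(dwells, method = lifetimeMethod),
                    error = function(e) NULL)
    if (!is.null(fit) && !is.null(bleachTrace)) {
      bleach <- estimateBleachLifetime(bleachTrace)
      if (!bleach@noBleaching && tau(fit) < tau(bleach))
        fit <- correctPhotobleaching(fit, bleach)
      report$bleach <- list(tau_bleach_s = tau(bleach))
    }
    report$kinetics <- list(
      n_dwells = nrow(dwells), n_censored = sum(dwells$censored),
      tau_s = if (!is.null(fit)) tau(fit) else NA_real_,
      half_life_s = if (!is.null(fit)) halfLife(fit) else NA_real_,
      bleach_corrected = !is.null(fit) && fit@bleachCorrected)
    report$dwells <- dwells
  }
  if (!is.null(outDir)) {
    small <- report[setdiff(names(report), c("phases", "dwells"))]
    jsonlite::write_json(small, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Hash of a simulation configuration
#'
#' MD5 of the JSON serialization of every config field (defaults
#' included), embedded in pipeline reports for provenance.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  fields <- sapply(slotNames(config), function(s) slot(config, s),
                   simplify = FALSE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(fields, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline from a JSON run-configuration file
#'
#' The JSON object may hold \code{seed}, \code{n_particles}, \code{stages},
#' \code{out_dir}, a \code{sim} block of \code{\link{simConfig}} arguments
#' (defaults echoed into the report), and an \code{inputs} block of file
#' paths (e.g. \code{bleach_trace_csv}). Every referenced input must exist
#' before any stage runs.
#'
#' @param path JSON run configuration.
#' @return the \code{\link{runPipeline}} report list.
#' @export
runPipelineFromConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in unlist(cfg$inputs))
    if (!file.exists(f))
      stop(sprintf("input file '%s' referenced by config does not exist", f))
  simArgs <- if (!is.null(cfg$sim)) as.list(cfg$sim) else list()
  if (!is.null(cfg$seed)) simArgs$rngSeed <- cfg$seed
  sc <- do.call(simConfig, simArgs)
  bleach <- NULL
  if (!is.null(cfg$inputs$bleach_trace_csv))
    bleach <- utils::read.csv(cfg$inputs$bleach_trace_csv)
  runPipeline(sc,
    nParticles = if (is.null(cfg$n_particles)) 50 else cfg$n_particles,
    stages = if (is.null(cfg$stages))
      c("simulate", "track", "motion", "kinetics") else cfg$stages,
    outDir = cfg$out_dir, bleachTrace = bleach,
    lifetimeMethod = if (is.null(cfg$lifetime_method)) "survival_decay"
      else cfg$lifetime_method)
}
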