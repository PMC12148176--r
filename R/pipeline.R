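# The end-to-end pipeline: simulate -> features -> labels/stats ->
# classify, with every intermediate written as CSV/JSON under one output
# directory and a manifest tying the run together.

pipeline_paths <- function(out_dir) {
  list(
    profiles = file.path(out_dir, "profiles.csv"),
    gaze = file.path(out_dir, "gaze.csv"),
    trials = file.path(out_dir, "trials.csv"),
    curves = file.path(out_dir, "feature_curves.csv"),
    labels = file.path(out_dir, "detection_labels.csv"),
    separation = file.path(out_dir, "separation_table.csv"),
    reports = file.path(out_dir, "classifier_report.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
}

#' @rdname run_pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  p <- pipeline_paths(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- sample_profiles(
    config$n_participants, config$sim, link_params = config$link_params,
    tremor_band = config$tremor_band, tremor_amp = config$tremor_amp,
    drift_diffusion = config$drift_diffusion,
    detection_slope = config$detection_slope, seed = config$seed
  )
  seeds <- config$seed + seq_along(profiles)
  recs <- mapply(function(pr, s) simulate_recording(pr, config$sim, seed = s),
                 profiles, seeds, SIMPLIFY = FALSE)
  trials <- do.call(rbind, mapply(
    function(pr, s) simulate_trials(pr, config$sim, seed = s + 10000L),
    profiles, seeds, SIMPLIFY = FALSE))
  prof_tab <- do.call(rbind, lapply(profiles, function(pr) {
    data.frame(participant_id = pr$participant_id,
               tremor_freq = pr$tremor_freq, tremor_amp = pr$tremor_amp,
               drift_diffusion = pr$drift_diffusion, cfft = pr$cfft,
               detection_slope = pr$detection_slope)
  }))
  write.csv(prof_tab, p$profiles, row.names = FALSE)
  gaze <- do.call(rbind, lapply(recs, as.data.frame))
  write.csv(gaze, p$gaze, row.names = FALSE, na = "")
  write_trial_table(trials, p$trials)
  invisible(list(profiles = profiles, recordings = recs, trials = trials))
}

read_gaze_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$participant_id), function(dd) {
    rec <- new_gaze_recording(dd$time_ms, as.numeric(dd$x), as.numeric(dd$y),
                              dd$label, dd$participant_id,
                              sampling_interval = diff(dd$time_ms)[1])
    validate_gaze_recording(rec)
    rec
  })
}

#' @rdname run_pipeline
#' @export
pipeline_features <- function(config, out_dir) {
  p <- pipeline_paths(out_dir)
  recs <- read_gaze_cohort(p$gaze)
  curves <- cohort_feature_curves(
    recs, grid_step = config$grid_step, min_segment = config$min_segment,
    emd_min_segment = config$emd_min_segment,
    include_emd = config$include_emd)
  write.csv(curves, p$curves, row.names = FALSE)
  invisible(curves)
}

#' @rdname run_pipeline
#' @export
pipeline_stats <- function(config, out_dir) {
  p <- pipeline_paths(out_dir)
  trials <- read_trial_table(p$trials)
  labels <- label_detection(trials,
                            trials_per_frequency = config$sim$trials_per_frequency)
  write.csv(as.data.frame(labels), p$labels, row.names = FALSE)
  curves <- read.csv(p$curves, stringsAsFactors = FALSE)
  fams <- if (config$include_emd) feature_families() else spectrum_families()
  results <- lapply(config$threshold_freqs, function(th) {
    find_f_star(curves, labels, th, families = fams)
  })
  tab <- summarize_separation(results, families = fams,
                              thresholds = config$threshold_freqs)
  write.csv(tab, p$separation, row.names = FALSE)
  invisible(list(labels = labels, results = results, table = tab))
}

#' @rdname run_pipeline
#' @export
pipeline_classify <- function(config, out_dir) {
  p <- pipeline_paths(out_dir)
  curves <- read.csv(p$curves, stringsAsFactors = FALSE)
  trials <- read_trial_table(p$trials)
  labels <- label_detection(trials,
                            trials_per_frequency = config$sim$trials_per_frequency)
  reports <- list()
  for (th in config$threshold_freqs) {
    res <- find_f_star(curves, labels, th,
                       families = config$classifier_families)
    fm <- assemble_features(res, curves, labels, th,
                            families = config$classifier_families)
    rep <- train_eval(fm, seed = config$seed,
                      subset_search = config$subset_search)
    reports[[paste0("f", th)]] <- rep
  }
  out <- lapply(reports, function(r) {
    r$folds <- lapply(r$folds, function(fd) {
      list(fold = fd$fold, counts = as.list(fd$counts),
           selected_features = fd$selected_features,
           hyperparams = as.list(fd$hyperparams))
    })
    unclass(r)
  })
  jsonlite::write_json(out, p$reports, auto_unbox = TRUE, digits = NA)
  invisible(reports)
}

#' Run the full microtremor-CFFT pipeline
#'
#' Executes simulate, features, stats and classify in order, writing every
#' intermediate table plus a JSON manifest (seed, configuration, package and
#' R versions, stage outputs) under `out_dir`. Re-running with the same
#' configuration and seed reproduces the outputs byte for byte. A stage
#' failure aborts with the stage name; the manifest then lists the stages
#' already completed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  p <- pipeline_paths(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(simulate = pipeline_simulate, features = pipeline_features,
                 stats = pipeline_stats, classify = pipeline_classify)
  done <- character(0)
  for (nm in names(stages)) {
    message(sprintf("[tremorlink] stage '%s' ...", nm))
    ok <- tryCatch({stages[[nm]](config, out_dir); TRUE},
                   error = function(e) {
                     manifest <- pipeline_manifest(config, p, done,
                                                   failed = nm,
                                                   error = conditionMessage(e))
                     jsonlite::write_json(manifest, p$manifest,
                                          auto_unbox = TRUE, digits = NA)
                     stop(sprintf("pipeline stage '%s' failed: %s", nm,
                                  conditionMessage(e)), call. = FALSE)
                   })
    done <- c(done, nm)
  }
  manifest <- pipeline_manifest(config, p, done)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_manifest <- function(config, paths, done, failed = NULL,
                              error = NULL) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  list(
    package = "tremorlink",
    version = as.character(packageVersion("tremorlink")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = cfg,
    stages_completed = done,
    stage_failed = failed,
    error = error,
    outputs = paths[setdiff(names(paths), "manifest")]
  )
}
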