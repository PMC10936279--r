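#' Default pipeline configuration
#'
#' Nested configuration mirroring the constructors' fields:
#' `acquisition` ([acquisition_params()]), `kinematics`
#' ([twitch_kinematics()]), `fatigue` ([fatigue_model()]), `stimulation`
#' ([stimulation_train()]), `study` ([synthetic_study()]), `analysis`
#' (segmentation/feature thresholds) and a global `seed`. Unknown keys are
#' rejected at validation; YAML serialization round-trips losslessly.
#'
#' @param ... Named overrides, e.g. `study = list(n_subjects = 3)`; each
#'   section is merged over its defaults.
#' @return A validated `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(study = list(n_subjects = 2, n_rounds = 1))
#' cfg$study$n_subjects
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    level = "waveform",
    acquisition = formals_defaults(acquisition_params),
    kinematics = formals_defaults(twitch_kinematics),
    fatigue = formals_defaults(fatigue_model),
    stimulation = formals_defaults(stimulation_train),
    study = within(formals_defaults(synthetic_study), rm(seed)),
    analysis = list(onset_k = 3, onset_min_ms = 5, quiet_ms = 20,
                    entropy_cutoff = 0.7, entropy_window = 164,
                    smooth_len = 1.925e-3)
  )
  defaults$fatigue$torque_weights <- as.list(defaults$fatigue$torque_weights)
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "config")
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

formals_defaults <- function(fn) {
  fm <- formals(fn)
  fm <- fm[vapply(fm, function(x) !(is.symbol(x) && !nzchar(as.character(x))),
                  logical(1))]
  lapply(fm, eval, envir = environment(fn))
}

merge_config <- function(defaults, overrides, path) {
  if (!is.list(overrides)) return(overrides)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s) under %s: %s", path,
                  paste(unknown, collapse = ", ")),
          class = "twitchtdi_invalid_argument")
  }
  for (k in names(overrides)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(overrides[[k]])) {
      merge_config(defaults[[k]], overrides[[k]], paste(path, k, sep = "$"))
    } else {
      overrides[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (!cfg$level %in% c("features", "waveform", "rf")) {
    abort("`level` must be one of features, waveform, rf.",
          class = "twitchtdi_invalid_argument")
  }
  # constructors run their own invariant checks (gate ordering etc.)
  do.call(acquisition_params, cfg$acquisition)
  do.call(twitch_kinematics, cfg$kinematics)
  fat <- cfg$fatigue
  fat$torque_weights <- unlist(fat$torque_weights)
  do.call(fatigue_model, fat)
  do.call(stimulation_train, cfg$stimulation)
  do.call(synthetic_study, c(cfg$study, list(seed = cfg$seed)))
  invisible(cfg)
}

#' Read and write pipeline configurations as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` the path invisibly; `read_config()` a validated
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> (velocity) -> features -> statistics under one
#' configuration and seed, writing `features.csv`, `report.json` and
#' `manifest.json` into `out_dir`. Identical configuration and seed give
#' byte-identical feature tables and reports.
#'
#' The statistics stage reproduces the study's analysis plan on the
#' synthetic data: per-subject baseline normalization; paired t-tests
#' (pooled baseline vs first post-fatigue twitch) across measures with
#' Holm-Bonferroni correction; one-way repeated-measures ANOVA over the
#' recovery twitches of round 1; a power-law recovery trend per measure and
#' round (pooled over subjects); and a per-subject stepwise regression of
#' raw torque on the five raw waveform features.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; side effects on disk.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "twitchtdi_pipeline_failure")
    })
  }

  fat <- cfg$fatigue
  fat$torque_weights <- unlist(fat$torque_weights)
  fatigue <- do.call(fatigue_model, fat)
  spec <- do.call(synthetic_study, c(cfg$study, list(seed = cfg$seed)))
  kin <- do.call(twitch_kinematics, cfg$kinematics)
  params <- do.call(acquisition_params, cfg$acquisition)

  study <- stage("simulate",
                 generate_study(spec, fatigue, kin, params,
                                level = cfg$level))
  an <- cfg$analysis
  features <- stage("features", measure_study_features(
    study,
    onset_k = an$onset_k, onset_min_ms = an$onset_min_ms,
    quiet_ms = an$quiet_ms, entropy_cutoff = an$entropy_cutoff,
    entropy_window = an$entropy_window))
  features_path <- file.path(out_dir, "features.csv")
  write_features_csv(features, features_path)

  report <- stage("stats", study_statistics(features))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("twitchtdi")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    started = format(t_start, "%Y-%m-%dT%H:%M:%OS3"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
    artifacts = list(features = "features.csv", report = "report.json"),
    n_twitches = nrow(features)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE)
  file.rename(tmp, manifest_path)
  invisible(manifest)
}

measure_columns <- c("torque_nm", "peak_velocity_mps", "time_to_zero_s",
                     "total_duration_s", "peak_vti_m",
                     "peak_strain_rate_per_s")

#' Run the statistics stage on a measured feature table
#'
#' @param features A table from [measure_study_features()] (or read back
#'   from `features.csv`).
#' @return A nested list: `paired_tests`, `rm_anova`, `recovery_trends`
#'   (per measure and round), `stepwise` (per subject).
#' @export
study_statistics <- function(features) {
  measures <- intersect(measure_columns, names(features))
  norm <- normalize_to_baseline(features, measures)

  ## pooled baseline vs first post-fatigue twitch, per measure
  r1min <- min(norm$round[norm$phase == "recovery"])
  first <- dplyr::filter(norm, .data$phase == "recovery",
                         .data$round == r1min, .data$twitch_index == 1)
  base_means <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(norm, .data$phase == "baseline"),
                    .data$subject),
    dplyr::across(dplyr::all_of(measures), ~mean(.x, na.rm = TRUE)),
    .groups = "drop")
  paired <- NULL
  common <- intersect(base_means$subject, first$subject)
  if (length(common) >= 3) {
    pairs <- lapply(measures, function(m) {
      list(x = first[[m]][match(common, first$subject)],
           y = base_means[[m]][match(common, base_means$subject)])
    })
    names(pairs) <- measures
    pairs <- purrr::keep(pairs, ~all(is.finite(.x$x)) && all(is.finite(.x$y)))
    if (length(pairs)) paired <- holm_paired_tests(pairs)
  }

  ## rmANOVA across the recovery twitches of the first round, per measure
  r1 <- dplyr::filter(norm, .data$phase == "recovery",
                      .data$round == r1min)
  anovas <- purrr::map(setNames(measures, measures), function(m) {
    wide <- tidyr::pivot_wider(r1[, c("subject", "twitch_index", m)],
                               names_from = "twitch_index",
                               values_from = dplyr::all_of(m))
    mat <- as.matrix(wide[, -1])
    if (anyNA(mat) || nrow(mat) < 2 || ncol(mat) < 2) return(NULL)
    glance(rm_anova(mat))
  })
  anovas <- purrr::compact(anovas)

  ## power recovery trend per measure and round, pooled over subjects
  rec <- dplyr::filter(norm, .data$phase == "recovery")
  trends <- list()
  for (m in measures) {
    for (r in sort(unique(rec$round))) {
      d <- dplyr::filter(rec, .data$round == r)
      ok <- is.finite(d[[m]]) & d[[m]] > 0
      if (sum(ok) < 3) next
      fit <- fit_power_trend(d$twitch_index[ok], d[[m]][ok])
      trends[[length(trends) + 1]] <- tibble(
        measure = m, round = r, b0 = fit$b0, b1 = fit$b1,
        r_squared = fit$r_squared, f_statistic = fit$f_statistic,
        p_value = fit$p_value, n = fit$n)
    }
  }
  trends <- if (length(trends)) dplyr::bind_rows(trends) else NULL

  ## per-subject stepwise regression of raw torque on raw features
  feats5 <- setdiff(measures, "torque_nm")
  stepwise <- purrr::map(
    setNames(sort(unique(features$subject)),
             paste0("subject_", sort(unique(features$subject)))),
    function(s) {
      d <- dplyr::filter(features, .data$subject == s)
      d <- d[stats::complete.cases(d[, c("torque_nm", feats5)]), ]
      if (nrow(d) <= length(feats5) + 2) return(NULL)
      fit <- stepwise_regression(d, "torque_nm", feats5)
      list(selected = as.list(fit$selected_features),
           coefficients = as.list(fit$coefficients),
           intercept = fit$intercept,
           r_squared = fit$r_squared,
           overall_p = fit$overall_p, n = fit$n)
    })
  stepwise <- purrr::compact(stepwise)

  list(paired_tests = paired, rm_anova = anovas,
       recovery_trends = trends, stepwise = stepwise)
}
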