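trial_cols <- c("participant_id", "experiment", "group", "device",
                "block_label", "trial_index", "attempt", "context",
                "target_angle", "rotation_deg", "probe_flag",
                "return_feedback", "time_limit_ms", "outcome")
sample_cols <- c("participant_id", "trial_index", "attempt", "t",
                 "input_x", "input_y", "cursor_x", "cursor_y")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: schema mismatch, missing column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read / write trial tables
#'
#' Plain-CSV serialization of the trial metadata table; a lossless round-trip
#' of all fields. `read_trials` validates the schema, names any missing
#' columns, and fails if more than 1% of rows are malformed (unparseable
#' values in required numeric columns).
#'
#' @param path CSV file path.
#' @param trials Trial table.
#' @return `read_trials`: a tibble; `write_trials`: `path`, invisibly.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_schema(df, trial_cols, basename(path))
  bad <- !is.finite(df$trial_index) | !is.finite(df$target_angle) |
    !is.finite(df$rotation_deg)
  if (mean(bad) > 0.01) {
    stop(sprintf("%s: %d malformed rows (>1%%)", basename(path), sum(bad)))
  }
  if (any(bad)) {
    warning(sprintf("%s: dropped %d malformed rows", basename(path),
                    sum(bad)))
    df <- df[!bad, ]
  }
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  check_schema(trials, trial_cols, "trial table")
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Read / write long-format trajectory tables
#'
#' @param path CSV file path.
#' @param samples Long trajectory table (`participant_id`, `trial_index`,
#'   `attempt`, `t`, `input_x`, `input_y`, `cursor_x`, `cursor_y`).
#' @return `read_trajectories`: a tibble; `write_trajectories`: `path`,
#'   invisibly.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_schema(df, sample_cols, basename(path))
  df
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(samples, path) {
  check_schema(samples, sample_cols, "trajectory table")
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the per-stage configuration for a reproducible end-to-end run.
#' Every output of [run_pipeline()] is stamped with the seed and a hash of
#' this configuration.
#'
#' @param experiment Experiment id.
#' @param n_per_group Participants per between-group arm.
#' @param seed Master seed.
#' @param learner A `vm_learner`.
#' @param preprocess A `vm_preprocess`.
#' @param layout A `vm_layout`.
#' @param inverted_axes Inverted-Look convention (`"both"` or
#'   `"vertical_only"`).
#' @param trajectories Render trajectories (TRUE) or use the fast
#'   ground-truth path.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `vm_config`.
#' @export
run_config <- function(experiment = "exp1", n_per_group = 15, seed = 1L,
                       learner = learner_params(),
                       preprocess = preprocess_config(),
                       layout = task_layout(),
                       inverted_axes = "both",
                       trajectories = TRUE,
                       out_dir = NULL) {
  stopifnot(n_per_group >= 1, experiment %in% c("exp1", "exp2a", "exp2b",
                                                "exp3"))
  structure(
    list(experiment = experiment, n_per_group = n_per_group,
         seed = as.integer(seed), learner = learner, preprocess = preprocess,
         layout = layout, inverted_axes = inverted_axes,
         trajectories = trajectories, out_dir = out_dir),
    class = "vm_config"
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' Builds a [run_config()] from a flat file. Recognized top-level keys:
#' `experiment`, `n_per_group`, `seed`, `inverted_axes`, `trajectories`,
#' `out_dir`, plus `learner` and `preprocess` sections whose entries override
#' the corresponding defaults of [learner_params()] and
#' [preprocess_config()]. Unknown keys are an error, so typos never silently
#' fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `vm_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("experiment", "n_per_group", "seed", "inverted_axes",
             "trajectories", "out_dir", "learner", "preprocess")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  learner <- do.call(learner_params, as.list(raw$learner))
  preprocess <- do.call(preprocess_config, as.list(raw$preprocess))
  args <- raw[setdiff(names(raw), c("learner", "preprocess"))]
  do.call(run_config, c(args, list(learner = learner,
                                   preprocess = preprocess)))
}

#' Run the full pipeline: simulate, preprocess, extract, analyze
#'
#' Executes the stages in order on a synthetic cohort (or on supplied trial +
#' trajectory tables), producing per-trial metrics, cycle series, period
#' summaries, derived measures and the experiment's statistical results.
#' The pipeline is a pure function of (config, seed, input tables): the same
#' config and seed give identical outputs. Per-stage exclusion counts are
#' collected in `log`.
#'
#' @param config A `vm_config`.
#' @param trials,samples Optional externally supplied tables (skips
#'   simulation).
#' @return A list of class `vm_results`: `trials`, `metrics`, `cycles`,
#'   `periods`, `measures`, `stats`, `log`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), trials = NULL,
                         samples = NULL) {
  stopifnot(inherits(config, "vm_config"))
  log <- list()
  if (is.null(trials)) {
    sim <- simulate_cohort(
      config$experiment, config$n_per_group, config$learner,
      seed = config$seed, trajectories = config$trajectories,
      inverted_axes = config$inverted_axes
    )
    trials <- sim$trials
    samples <- sim$samples
  }
  log$n_trials_in <- nrow(trials)

  if (!is.null(samples)) {
    pp <- preprocess_trials(samples, config$preprocess)
    metrics <- extract_metrics(trials, pp)
  } else {
    # ground-truth fast path: executed aim angles stand in for extracted ones
    metrics <- trials
    dirmap <- participant_rotation_direction(trials)
    dirs <- unlist(dirmap[trials$participant_id])
    ang <- normalize_sign(trials$aim_exec, dirs)
    metrics$hand_angle_peak <- ang
    metrics$hand_angle_takeoff <- ang
    metrics$valid <- !trials$jump_start_true
    metrics$jump_start <- trials$jump_start_true
    metrics$glitch <- FALSE
    pp <- list(exclusions = tibble::tibble())
  }
  log$n_excluded_preprocess <- nrow(pp$exclusions)
  log$n_jump_start <- sum(metrics$jump_start %in% TRUE)
  log$pct_excluded <- 100 * mean(!metrics$valid)

  measures <- list()
  stats_out <- list()
  if (config$experiment == "exp3") {
    periods <- period_means(metrics, "exp3")
    gen <- baseline_correct(metrics, config$inverted_axes)
    topup <- topup_asymptote(metrics)
    measures$generalization <- gen
    measures$topup <- topup
    cycles <- NULL
    vert <- gen[gen$handspace_relation != "lateral", ]
    anova_in <- data.frame(
      value = vert$corrected_hand_angle,
      participant = vert$participant_id,
      group = vert$probe_context,
      period = vert$handspace_relation
    )
    stats_out$generalization_anova <- mixed_anova(anova_in)
  } else {
    cycles <- assign_cycles(metrics)
    periods <- period_means(cycles, config$experiment)
    pw <- tidyr::pivot_wider(periods, names_from = "period",
                             values_from = "mean_hand_angle")
    groups <- participant_groups(trials)
    pw$group <- groups[pw$participant_id]
    anova_in <- periods[periods$period %in% c("early_rotation",
                                              "late_rotation"), ]
    anova_in <- data.frame(
      value = anova_in$mean_hand_angle,
      participant = anova_in$participant_id,
      group = groups[anova_in$participant_id],
      period = anova_in$period
    )
    stats_out$learning_anova <- mixed_anova(anova_in)
    if (config$experiment == "exp1") {
      measures$after_effect <- merge_group(after_effect(periods), groups)
    } else {
      measures$transfer <- merge_group(transfer_measure(periods), groups)
      measures$after_effect <- NULL
    }
  }
  structure(
    list(trials = trials, metrics = metrics, cycles = cycles,
         periods = periods, measures = measures, stats = stats_out,
         log = log, seed = config$seed, config_hash = config_hash(config)),
    class = "vm_results"
  )
}

participant_groups <- function(trials) {
  sp <- split(trials$group, trials$participant_id)
  vapply(sp, `[`, character(1), 1)
}

merge_group <- function(df, groups) {
  df$group <- groups[df$participant_id]
  df
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' @export
print.vm_results <- function(x, ...) {
  cat("<vm_results>\n")
  cat("  trials:", x$log$n_trials_in, " excluded:",
      sprintf("%.1f%%", x$log$pct_excluded), "\n")
  cat("  seed:", x$seed, " config:", x$config_hash, "\n")
  for (nm in names(x$stats)) {
    cat("  ", nm, ":\n", sep = "")
    print(as.data.frame(x$stats[[nm]]), digits = 3)
  }
  invisible(x)
}
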