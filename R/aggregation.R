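#' Collapse trials into cycles of four movements
#'
#' Groups consecutive trials (one per cardinal target) into cycles and
#' averages hand angle over the valid trials of each cycle. Aborted
#' (online-flagged, repeated) attempts are dropped first, so the repeat
#' occupies its original slot. Cycles are numbered globally across the
#' experiment; a cycle with no valid trial yields `NA`.
#'
#' @param metrics Per-attempt metrics table from [extract_metrics()].
#' @param value Column to aggregate (default `hand_angle_peak`).
#' @return Tibble: `participant_id`, `block_label`, `cycle_index`,
#'   `mean_hand_angle`, `n_valid`.
#' @export
assign_cycles <- function(metrics, value = "hand_angle_peak") {
  m <- metrics[metrics$outcome != "jump_start_repeat", ]
  m <- m[order(m$participant_id, m$trial_index), ]
  sp <- split(m, m$participant_id)
  out <- lapply(sp, function(d) {
    if (nrow(d) %% 4 != 0) stop("block length not divisible by 4")
    d$cycle_index <- (seq_len(nrow(d)) - 1) %/% 4 + 1
    v <- ifelse(d$valid, d[[value]], NA_real_)
    agg <- tapply(v, d$cycle_index, function(z) {
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    })
    tibble::tibble(
      participant_id = d$participant_id[1],
      block_label = tapply(d$block_label, d$cycle_index, function(b) b[1]),
      cycle_index = as.integer(names(agg)),
      mean_hand_angle = as.numeric(agg),
      n_valid = as.integer(tapply(d$valid, d$cycle_index, sum))
    )
  })
  dplyr::bind_rows(out)
}

# Cycle windows (exp1/2) or trial windows (exp3) defining each analysis
# period: the last 10 baseline cycles, and the first/last 10 cycles (exp1/2)
# or trials (exp3) of the rotation/washout/transfer blocks.
period_windows <- function(index, block) {
  first_n <- function(b, n) {
    idx <- sort(unique(index[block == b]))
    utils::head(idx, n)
  }
  last_n <- function(b, n) {
    idx <- sort(unique(index[block == b]))
    utils::tail(idx, n)
  }
  w <- list()
  if ("baseline" %in% block) w$baseline <- last_n("baseline", 10)
  if ("baseline_trained" %in% block) w$baseline <- last_n("baseline_trained", 10)
  if ("rotation" %in% block) {
    w$early_rotation <- first_n("rotation", 10)
    w$late_rotation <- last_n("rotation", 10)
  }
  if ("washout" %in% block) {
    w$early_washout <- first_n("washout", 10)
    w$late_washout <- last_n("washout", 10)
  }
  if ("transfer" %in% block) w$early_transfer <- first_n("transfer", 10)
  w
}

#' Per-participant period means
#'
#' Averages hand angle over the experiment's predefined analysis windows.
#' For exp1/2 the windows are cycles (last 10 baseline cycles; first/last 10
#' rotation, washout and transfer cycles); for exp3 learning they are the
#' first/last 10 trials of the rotation block.
#'
#' @param series Cycle series from [assign_cycles()] (exp1/2) or a per-attempt
#'   metrics table (exp3).
#' @param experiment Experiment id.
#' @return Tibble: `participant_id`, `period`, `mean_hand_angle`.
#' @export
period_means <- function(series, experiment = "exp1") {
  if (experiment == "exp3") {
    m <- series[series$outcome != "jump_start_repeat" & series$valid, ]
    sp <- split(m, m$participant_id)
    out <- lapply(sp, function(d) {
      w <- list(
        early_learning_trials =
          utils::head(sort(d$trial_index[d$block_label == "rotation"]), 10),
        late_learning_trials =
          utils::tail(sort(d$trial_index[d$block_label == "rotation"]), 10)
      )
      tibble::tibble(
        participant_id = d$participant_id[1],
        period = names(w),
        mean_hand_angle = unname(vapply(w, function(idx) {
          mean(d$hand_angle_peak[d$trial_index %in% idx], na.rm = TRUE)
        }, numeric(1)))
      )
    })
    return(dplyr::bind_rows(out))
  }
  sp <- split(series, series$participant_id)
  out <- lapply(sp, function(d) {
    w <- period_windows(d$cycle_index, d$block_label)
    if (length(w) == 0) stop("no analysis windows found")
    tibble::tibble(
      participant_id = d$participant_id[1],
      period = names(w),
      mean_hand_angle = unname(vapply(w, function(idx) {
        v <- d$mean_hand_angle[d$cycle_index %in% idx]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1)))
    )
  })
  dplyr::bind_rows(out)
}

#' After-effect: early washout minus late learning
#'
#' @param summary Period summary from [period_means()].
#' @return Tibble: `participant_id`, `after_effect` (degrees). Negative values
#'   indicate decay of the learned compensation once the rotation is removed.
#' @export
after_effect <- function(summary) {
  wide <- tidyr::pivot_wider(summary, names_from = "period",
                             values_from = "mean_hand_angle")
  late_col <- intersect(c("late_rotation", "late_learning_trials"),
                        names(wide))
  if (!"early_washout" %in% names(wide) || length(late_col) == 0) {
    stop("missing period")
  }
  late <- wide[[late_col[1]]]
  tibble::tibble(participant_id = wide$participant_id,
                 after_effect = wide$early_washout - late)
}

#' Transfer: early transfer-block cycles minus late learning
#'
#' @param summary Period summary from [period_means()] (exp2 designs).
#' @return Tibble: `participant_id`, `transfer` (degrees). Values near zero
#'   indicate full transfer of the learned compensation to the untrained
#'   context.
#' @export
transfer_measure <- function(summary) {
  wide <- tidyr::pivot_wider(summary, names_from = "period",
                             values_from = "mean_hand_angle")
  if (!all(c("early_transfer", "late_rotation") %in% names(wide))) {
    stop("missing period")
  }
  tibble::tibble(participant_id = wide$participant_id,
                 transfer = wide$early_transfer - wide$late_rotation)
}

#' Relation of a probe to the trained hand direction
#'
#' Labels a probe by the relation of its planned hand direction to the
#' trained (upward, 90 degree) hand direction: `"trained"`, `"untrained"`
#' (opposite), or `"lateral"` (orthogonal).
#'
#' @param target_angle Probe target angle(s), degrees.
#' @param context Probe context string(s).
#' @param inverted_axes Inverted-Look axis convention.
#' @return Character vector.
#' @export
handspace_relation <- function(target_angle, context,
                               inverted_axes = "both") {
  hd <- ideal_hand_direction(target_angle, context, inverted_axes) %% 360
  ifelse(hd == 90, "trained", ifelse(hd == 270, "untrained", "lateral"))
}

#' Baseline-corrected generalization table
#'
#' For each participant, probed context and probe target, subtracts the mean
#' hand angle in the baseline generalization block from that in the
#' generalization block, removing intrinsic reach biases. Each probe is
#' labelled by the relation of its planned hand direction to the trained
#' (upward) hand direction: `trained`, `untrained`, or `lateral` (the 0/180
#' degree probes, retained in the table but excluded from the
#' trained-vs-untrained contrast).
#'
#' @param metrics Per-attempt metrics table (exp3).
#' @param inverted_axes Inverted-Look axis convention.
#' @return Tibble: `participant_id`, `probe_context`, `probe_target`,
#'   `handspace_relation`, `corrected_hand_angle`.
#' @export
baseline_correct <- function(metrics, inverted_axes = "both") {
  p <- metrics[metrics$probe_flag & metrics$valid &
                 metrics$outcome != "jump_start_repeat", ]
  agg <- dplyr::summarise(
    dplyr::group_by(p, .data$participant_id, .data$block_label,
                    .data$context, .data$target_angle),
    mean_angle = mean(.data$hand_angle_peak, na.rm = TRUE), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = "block_label",
                             values_from = "mean_angle")
  if (!all(c("generalization", "baseline_generalization") %in%
             names(wide))) {
    stop("unmatched generalization blocks")
  }
  tibble::tibble(
    participant_id = wide$participant_id,
    probe_context = wide$context,
    probe_target = wide$target_angle,
    handspace_relation = handspace_relation(wide$target_angle, wide$context,
                                            inverted_axes),
    corrected_hand_angle = wide$generalization - wide$baseline_generalization
  )
}

#' Mean hand angle over the last top-up trials of each generalization cycle
#'
#' Reports, per participant, the mean hand angle over the final `n_last`
#' Point top-up trials of each generalization cycle — a check that learning
#' was re-established at asymptote before each probe set.
#'
#' @param metrics Per-attempt metrics table (exp3).
#' @param n_last Top-up trials per cycle to average (5).
#' @return Tibble: `participant_id`, `mean_topup_hand_angle`.
#' @export
topup_asymptote <- function(metrics, n_last = 5) {
  m <- metrics[metrics$block_label == "generalization" &
                 metrics$outcome != "jump_start_repeat", ]
  m <- m[order(m$participant_id, m$trial_index), ]
  sp <- split(m, m$participant_id)
  out <- lapply(sp, function(d) {
    pos <- seq_len(nrow(d))
    in_cycle <- (pos - 1) %% 18 + 1 # 1-3 probes, 4-18 top-ups
    keep <- in_cycle > (18 - n_last) & d$valid
    tibble::tibble(participant_id = d$participant_id[1],
                   mean_topup_hand_angle = mean(d$hand_angle_peak[keep],
                                                na.rm = TRUE))
  })
  dplyr::bind_rows(out)
}
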