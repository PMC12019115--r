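#' Generate one trial's trajectory samples
#'
#' Produces raw (pre-resampling) trajectory samples for a single reach: the
#' hand follows a minimum-jerk radial profile of 1 au amplitude along the
#' planned direction, optionally followed by a late feedback-driven corrective
#' sub-movement toward the position that lands the cursor on the target
#' (producing the corrective hooks seen early in rotation blocks and in
#' washout). Samples are emitted at jittered frame times (uniform +/-10% of
#' the nominal frame period), and the cursor channel is obtained by running
#' the input deltas through [forward_map()].
#'
#' @param aim_angle Planned deviation (degrees, ccw positive) from the trial's
#'   ideal hand direction, including any execution noise.
#' @param target_angle Target direction (degrees).
#' @param cfg A `vm_context`.
#' @param rot A `vm_rotation` (or signed degrees).
#' @param layout A `vm_layout`.
#' @param frame_rate_hz Nominal sampling rate (typically 60-144 Hz).
#' @param rng RNG stream from `make_rng()`, used for frame jitter.
#' @param duration_s Movement duration (s).
#' @param correct_gain Fraction (0-1) of the remaining cursor error removed by
#'   the late corrective sub-movement; 0 disables it.
#' @param hold_frames Number of stationary frames appended at the endpoint.
#' @return A tibble with columns `t`, `input_x`, `input_y`, `cursor_x`,
#'   `cursor_y` (cursor is task-plane-relative; input is the raw, unrotated
#'   hand displacement).
#' @export
generate_trajectory <- function(aim_angle, target_angle,
                                cfg = context_config("point"),
                                rot = rotation_spec(),
                                layout = task_layout(),
                                frame_rate_hz = 60,
                                rng = make_rng(1L),
                                duration_s = 0.4,
                                correct_gain = 1,
                                hold_frames = 4L) {
  ang <- if (inherits(rot, "vm_rotation")) rotation_signed(rot) else rot
  ideal <- ideal_hand_direction(target_angle, cfg$context, cfg$inverted_axes)
  plan_dir <- (ideal + aim_angle) * pi / 180
  u <- c(cos(plan_dir), sin(plan_dir))
  # hand endpoint that puts the cursor on the target (full compensation)
  end_dir <- (ideal - ang) * pi / 180
  v <- c(cos(end_dir), sin(end_dir))

  n_frames <- ceiling(duration_s * frame_rate_hz * 1.25) + 2
  dt <- (1 / frame_rate_hz) * (1 + runif_rng(rng, n_frames, -0.1, 0.1))
  t <- cumsum(dt)
  t <- c(0, t[t < duration_s], duration_s)
  tau <- t / duration_s
  r <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  # corrective sub-movement ramps in over the final 35% of the movement
  tau0 <- 0.65
  w <- pmax(0, pmin(1, (tau - tau0) / (1 - tau0)))
  w <- 10 * w^3 - 15 * w^4 + 6 * w^5
  hand <- outer(r, u) + correct_gain * outer(w, v - u)
  if (hold_frames > 0) {
    tail_dt <- (1 / frame_rate_hz) * (1 + runif_rng(rng, hold_frames, -0.1, 0.1))
    t <- c(t, t[length(t)] + cumsum(tail_dt))
    hand <- rbind(hand, hand[rep(nrow(hand), hold_frames), ])
  }
  deltas <- rbind(hand[1, ], diff(hand))
  fm <- forward_map(deltas, cfg, rot)
  new_tbl(
    t = t,
    input_x = fm$input[, 1], input_y = fm$input[, 2],
    cursor_x = fm$cursor_plane[, 1], cursor_y = fm$cursor_plane[, 2]
  )
}

#' Inject single-frame input glitches
#'
#' With probability `glitch_rate`, one interior sample is displaced (on both
#' input and cursor channels) far enough that the cursor speed change between
#' neighbouring frames exceeds the 40 au/s rejection threshold, emulating the
#' large single-frame mouse inputs seen in browser-delivered experiments.
#'
#' @param samples Trajectory tibble from [generate_trajectory()].
#' @param glitch_rate Probability of injecting a glitch into this trial.
#' @param rng RNG stream.
#' @param threshold Speed-change threshold to exceed (au/s).
#' @return The (possibly modified) samples, with attribute `glitched`.
#' @export
inject_artifacts <- function(samples, glitch_rate, rng = make_rng(1L),
                             threshold = 40) {
  glitched <- runif_rng(rng, 1) < glitch_rate
  if (glitched && nrow(samples) >= 4) {
    i <- 1 + sample_rng(rng, seq_len(nrow(samples) - 2), size = 1)
    dt <- max(diff(samples$t))
    mag <- 2.5 * threshold * dt
    th <- runif_rng(rng, 1, 0, 2 * pi)
    shift <- mag * c(cos(th), sin(th))
    samples$input_x[i] <- samples$input_x[i] + shift[1]
    samples$input_y[i] <- samples$input_y[i] + shift[2]
    samples$cursor_x[i] <- samples$cursor_x[i] + shift[1]
    samples$cursor_y[i] <- samples$cursor_y[i] + shift[2]
  }
  attr(samples, "glitched") <- glitched
  samples
}

# Default per-experiment jump-start probabilities: time pressure in the
# staircased designs makes anticipatory launches to an uncued target more
# common; removing the time limit (exp3) nearly eliminates them.
default_jump_rate <- function(experiment) {
  switch(experiment, exp1 = 0.10, exp2a = 0.05, exp2b = 0.05, exp3 = 0.016)
}

#' Simulate a synthetic cohort end-to-end
#'
#' Generates trial tables and trajectory samples for `n_per_group` simulated
#' participants per between-group arm of the requested design. Rotation
#' direction and input device are counterbalanced within groups. For designs
#' with the online jump-start check (exp2a/2b everywhere; exp3 on Point and
#' first-baseline trials), jump-started trials are recorded with outcome
#' `jump_start_repeat` and repeated in place.
#'
#' @param experiment `"exp1"`, `"exp2a"`, `"exp2b"`, or `"exp3"`.
#' @param n_per_group Participants per between-group arm (exp1/2: trained
#'   context point vs look; exp3: probed context look vs inverted look).
#' @param params A `vm_learner`; `p_jump_start = NULL` in `...` overrides.
#' @param seed Master integer seed.
#' @param p_jump_start Jump-start probability; defaults per experiment.
#' @param frame_rates Candidate participant frame rates (Hz).
#' @param trajectories If `FALSE`, skip trajectory rendering and return only
#'   the trial table with ground-truth executed hand angles (fast path for
#'   statistical simulations).
#' @param inverted_axes Inverted-Look axis convention.
#' @return A list with `trials` (one row per attempt) and `samples` (long
#'   trajectory table; `NULL` when `trajectories = FALSE`).
#' @export
simulate_cohort <- function(experiment = "exp1", n_per_group = 15,
                            params = learner_params(), seed = 1L,
                            p_jump_start = NULL,
                            frame_rates = c(60, 120, 144),
                            trajectories = TRUE,
                            inverted_axes = "both") {
  stopifnot(n_per_group >= 1)
  if (is.null(p_jump_start)) p_jump_start <- default_jump_rate(experiment)
  groups <- if (experiment == "exp1") {
    c("point", "look")
  } else if (experiment %in% c("exp2a", "exp2b")) {
    c("point", "look") # trained context
  } else {
    c("look", "inverted_look") # probed context
  }
  trials_all <- list()
  samples_all <- list()
  pid <- 0L
  for (g in seq_along(groups)) {
    for (k in seq_len(n_per_group)) {
      pid <- pid + 1L
      pseed <- (seed * 10007L + pid * 211L) %% 2000000011L
      rng <- make_rng(pseed)
      dir <- if (k %% 2 == 0) "ccw" else "cw"
      device <- if ((k %% 4) < 2) "mouse" else "trackpad"
      fr <- sample_rng(rng, frame_rates, size = 1)
      sched <- build_schedule(experiment, dir, seed = pseed,
                              context = groups[g],
                              trained_context = groups[g],
                              probe_context = groups[g])
      sim <- simulate_participant(
        pid = sprintf("P%03d", pid), experiment = experiment,
        group = groups[g], device = device, frame_rate = fr,
        schedule = sched, params = params, rng = rng,
        p_jump_start = p_jump_start, trajectories = trajectories,
        inverted_axes = inverted_axes
      )
      trials_all[[pid]] <- sim$trials
      samples_all[[pid]] <- sim$samples
    }
  }
  list(
    trials = dplyr::bind_rows(trials_all),
    samples = if (trajectories) dplyr::bind_rows(samples_all) else NULL
  )
}

simulate_participant <- function(pid, experiment, group, device, frame_rate,
                                 schedule, params, rng, p_jump_start,
                                 trajectories, inverted_axes) {
  n <- nrow(schedule)
  aim <- simulate_learner(params, schedule, inverted_axes = inverted_axes)
  noise <- rnorm_rng(rng, n, 0, params$motor_noise_sd)
  jump <- runif_rng(rng, n) < p_jump_start
  jump_side <- sample_rng(rng, c(-90, 90), size = n, replace = TRUE)
  staircased <- experiment %in% c("exp1", "exp2a", "exp2b")
  online_check <- online_check_flags(experiment, schedule)
  st <- if (staircased) init_staircases(device) else NULL
  block_of <- schedule$block_label

  cfgs <- list(
    point = context_config("point"),
    look = context_config("look"),
    inverted_look = context_config("inverted_look",
                                   inverted_axes = inverted_axes)
  )
  rows <- vector("list", n)
  samps <- vector("list", n)
  prev_block <- ""
  for (i in seq_len(n)) {
    if (staircased && block_of[i] != prev_block) {
      st <- reset_staircase_block(st)
    }
    prev_block <- block_of[i]
    limit <- NA_real_
    if (staircased) {
      st <- next_limit(st, tiebreak = sample_rng(rng, 1:2, size = 1))
      limit <- st$limits[st$active]
    }
    attempt_rows <- list()
    attempt_samps <- list()
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      is_jump <- if (attempt == 1L) jump[i] else FALSE
      aim_exec <- if (is_jump) jump_side[i] + noise[i] else aim[i] + noise[i]
      cfg <- cfgs[[schedule$context[i]]]
      rot <- schedule$rotation_deg[i]
      traj <- NULL
      if (trajectories || (is_jump && online_check[i])) {
        # jump starts launch toward the uncued target with no corrective
        # sub-movement: the participant never homes in on the cued target
        traj <- generate_trajectory(
          aim_exec, schedule$target_angle[i], cfg, rot,
          frame_rate_hz = frame_rate, rng = rng,
          correct_gain = if (is_jump) 0 else 1
        )
        traj <- inject_artifacts(traj, params$glitch_rate, rng)
      }
      aborted <- is_jump && online_check[i]
      outcome <- if (aborted) {
        "jump_start_repeat"
      } else if (staircased) {
        p <- stats::plogis((limit - params$rt_limit_threshold_ms) /
                             params$rt_limit_slope)
        if (runif_rng(rng, 1) < p) "hit" else "timeout"
      } else {
        "hit"
      }
      attempt_rows[[attempt]] <- new_tbl(
        participant_id = pid, experiment = experiment, group = group,
        device = device, block_label = block_of[i],
        trial_index = schedule$trial_index[i], attempt = attempt,
        context = schedule$context[i],
        target_angle = schedule$target_angle[i],
        rotation_deg = schedule$rotation_deg[i],
        probe_flag = schedule$probe_flag[i],
        return_feedback = schedule$return_feedback[i],
        time_limit_ms = limit, outcome = outcome,
        aim_true = aim[i], aim_exec = aim_exec, jump_start_true = is_jump
      )
      if (trajectories && !is.null(traj)) {
        traj$participant_id <- pid
        traj$trial_index <- schedule$trial_index[i]
        traj$attempt <- attempt
        attempt_samps[[attempt]] <- traj
      }
      if (!aborted) break
    }
    if (staircased) {
      final <- attempt_rows[[length(attempt_rows)]]
      st <- update_staircase(st, final$outcome == "hit")
    }
    rows[[i]] <- dplyr::bind_rows(attempt_rows)
    if (trajectories) samps[[i]] <- dplyr::bind_rows(attempt_samps)
  }
  list(trials = dplyr::bind_rows(rows),
       samples = if (trajectories) dplyr::bind_rows(samps) else NULL)
}

# Trials subject to the online jump-start check: all of exp2a/2b; in exp3 the
# first baseline block (both contexts) and Point trials thereafter; never the
# probe trials; exp1 predates the check.
online_check_flags <- function(experiment, schedule) {
  if (experiment %in% c("exp2a", "exp2b")) return(rep(TRUE, nrow(schedule)))
  if (experiment == "exp1") return(rep(FALSE, nrow(schedule)))
  (schedule$block_label == "baseline") |
    (schedule$context == "point" & !schedule$probe_flag)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
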