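#' State-space learner parameters
#'
#' Parameters of the synthetic participant: a linear state-space learner with
#' Gaussian generalization around the planned hand vector, plus the nuisance
#' processes needed to emulate recorded data.
#'
#' The compensation state x (degrees, one state per cardinal hand direction)
#' evolves on every trial as retention `x <- A * x`, and on trials with error
#' feedback additionally as `x_d <- x_d + B * e * exp(-D^2 / (2 * sigma^2))`,
#' where `e = s - x_trial` is the residual error at the trial's hand
#' direction, `s` the compensation demanded by the signed rotation, and `D`
#' the angular distance between the state's and the trial's planned hand
#' vectors. With feedback on every trial at one direction the state converges
#' to `s * B / (1 - A + B)`.
#'
#' Defaults are chosen to reproduce the adaptation profile typical of online
#' 30-degree rotation studies: a cycle-level rise to a 21-24 degree asymptote
#' over 120 rotation cycles with four interleaved targets, and ~10 degrees of
#' compensation over the first 10 single-target rotation trials.
#'
#' @param retention_A Per-trial retention factor in `[0, 1]`.
#' @param learning_rate_B Error correction rate in `[0, 1]`.
#' @param gen_sigma Width (degrees) of generalization around the planned hand
#'   vector.
#' @param motor_noise_sd Per-trial angular execution noise SD (degrees).
#' @param p_jump_start Probability a trial launches toward an uncued target.
#' @param glitch_rate Per-trial probability of a single-frame input glitch.
#' @param rt_limit_threshold_ms Observer's 50%-success time limit (ms).
#' @param rt_limit_slope Logistic slope of the success psychometric (ms).
#' @return A list of class `vm_learner`.
#' @export
learner_params <- function(retention_A = 0.99,
                           learning_rate_B = 0.1,
                           gen_sigma = 30,
                           motor_noise_sd = 4,
                           p_jump_start = 0.03,
                           glitch_rate = 0.004,
                           rt_limit_threshold_ms = 600,
                           rt_limit_slope = 100) {
  stopifnot(
    retention_A >= 0, retention_A <= 1,
    learning_rate_B >= 0, learning_rate_B <= 1,
    gen_sigma > 0, motor_noise_sd >= 0,
    p_jump_start >= 0, p_jump_start <= 1,
    glitch_rate >= 0, glitch_rate <= 1
  )
  structure(
    list(retention_A = retention_A, learning_rate_B = learning_rate_B,
         gen_sigma = gen_sigma, motor_noise_sd = motor_noise_sd,
         p_jump_start = p_jump_start, glitch_rate = glitch_rate,
         rt_limit_threshold_ms = rt_limit_threshold_ms,
         rt_limit_slope = rt_limit_slope),
    class = "vm_learner"
  )
}

#' Ideal hand direction for a trial
#'
#' The hand movement direction whose unperturbed mapping lands the cursor on
#' the target: equal to the target angle in the Point and Look contexts, and
#' reflected through the configured inverted axes under Inverted Look (with
#' the default both-axes convention, the opposite direction).
#'
#' @param target_angle Target direction(s), degrees.
#' @param context Context string(s).
#' @param inverted_axes `"both"` or `"vertical_only"`.
#' @return Hand direction(s) in degrees, wrapped to (-180, 180].
#' @export
ideal_hand_direction <- function(target_angle, context,
                                 inverted_axes = "both") {
  out <- target_angle
  inv <- context == "inverted_look"
  if (any(inv)) {
    if (inverted_axes == "both") {
      out[inv] <- wrap_angle(target_angle[inv] + 180)
    } else {
      out[inv] <- wrap_angle(-target_angle[inv])
    }
  }
  out
}

#' Simulate the planned aim sequence of a state-space learner
#'
#' Runs the learner over a schedule and returns, per trial, the planned aim
#' deviation (degrees, counter-clockwise positive) relative to the trial's
#' ideal hand direction. The state is carried across context switches — the
#' learner is a single internal model shared by the Point, Look, and Inverted
#' Look contexts — and updates only on trials with error feedback.
#'
#' @param params A `vm_learner`.
#' @param schedule A `vm_schedule` from [build_schedule()].
#' @param seed Unused placeholder kept for interface stability (the aim
#'   sequence is deterministic; execution noise is added downstream).
#' @param inverted_axes Inverted-Look axis convention.
#' @return Numeric vector of per-trial aim deviations (raw, ccw positive).
#' @export
simulate_learner <- function(params, schedule, seed = NULL,
                             inverted_axes = "both") {
  A <- params$retention_A
  B <- params$learning_rate_B
  sigma <- params$gen_sigma
  dirs <- c(0, 90, 180, 270)
  x <- stats::setNames(numeric(4), dirs)
  hand_dir <- ideal_hand_direction(schedule$target_angle, schedule$context,
                                   inverted_axes)
  hand_dir <- (hand_dir %% 360)
  s <- -schedule$rotation_deg # compensation demanded, ccw positive
  has_feedback <- rep(TRUE, nrow(schedule)) # all trials show the outward cursor
  aim <- numeric(nrow(schedule))
  gen <- outer(dirs, dirs, function(a, b) {
    d <- abs(wrap_angle(a - b))
    exp(-d^2 / (2 * sigma^2))
  })
  rownames(gen) <- colnames(gen) <- dirs
  for (i in seq_len(nrow(schedule))) {
    d <- as.character(hand_dir[i])
    aim[i] <- x[d]
    e <- s[i] - x[d] # error experienced on this trial's movement
    x <- A * x
    if (has_feedback[i]) {
      x <- x + B * e * gen[d, ]
    }
  }
  aim
}

#' Fit retention and learning rate to cohort cycle means
#'
#' Least-squares recovery of the state-space parameters (A, B) from observed
#' cycle-mean hand angles: the candidate model is the noise-free learner run
#' on the same schedule, aggregated to cycle means, and (A, B) minimize the
#' sum of squared deviations from the observed series.
#'
#' @param cycle_means Numeric vector of observed cycle-mean hand angles
#'   (normalized sign), in cycle order over the whole experiment.
#' @param schedule The schedule the cohort was generated from.
#' @param params Template `vm_learner` (non-fitted fields are reused).
#' @param inverted_axes Inverted-Look axis convention.
#' @return A list with `retention_A`, `learning_rate_B`, `sse`.
#' @export
fit_state_space <- function(cycle_means, schedule, params = learner_params(),
                            inverted_axes = "both") {
  sgn <- if (attr(schedule, "rotation_direction") == "ccw") -1 else 1
  predict_cycles <- function(A, B) {
    p <- params
    p$retention_A <- A
    p$learning_rate_B <- B
    aim <- sgn * simulate_learner(p, schedule, inverted_axes = inverted_axes)
    colMeans(matrix(aim, nrow = 4))
  }
  obj <- function(par) {
    pred <- predict_cycles(par[1], par[2])
    sum((pred - cycle_means)^2, na.rm = TRUE)
  }
  fit <- stats::optim(c(0.95, 0.15), obj, method = "L-BFGS-B",
                      lower = c(0.5, 1e-4), upper = c(1, 0.9))
  list(retention_A = fit$par[1], learning_rate_B = fit$par[2],
       sse = fit$value)
}
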