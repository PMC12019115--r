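#' Radial speed of a trajectory
#'
#' Time derivative (central differences; one-sided at the ends) of the
#' Euclidean distance of the input position from the start-point.
#'
#' @param samples Preprocessed trajectory tibble.
#' @param start Start-point position.
#' @param channel `"input"` or `"cursor"`.
#' @return Numeric vector of speeds (au/s), one per sample.
#' @export
radial_speed <- function(samples, start = c(0, 0), channel = "input") {
  x <- samples[[paste0(channel, "_x")]] - start[1]
  y <- samples[[paste0(channel, "_y")]] - start[2]
  r <- sqrt(x^2 + y^2)
  t <- samples$t
  n <- length(r)
  if (n < 2) return(rep(0, n))
  v <- numeric(n)
  if (n > 2) {
    v[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  v[1] <- (r[2] - r[1]) / (t[2] - t[1])
  v[n] <- (r[n] - r[n - 1]) / (t[n] - t[n - 1])
  v
}

# Signed ccw angle (degrees) of a position about the start-point.
position_angle <- function(x, y) atan2(y, x) * 180 / pi

#' Hand angle at peak radial speed
#'
#' Finds the peak radial speed of the input channel (the raw hand
#' displacement, unaffected by perturbations) and returns the signed angle
#' between the start-to-target line and the start-to-input line at that time.
#' Positive angles are counter-clockwise.
#'
#' @param samples Preprocessed trajectory tibble.
#' @param target_angle Target direction (degrees).
#' @param start Start-point position.
#' @return List with `angle` (degrees, raw), `peak_speed` (au/s), `t_peak`
#'   (s); `angle` is `NA` if the input is at the start-point at peak speed.
#' @export
hand_angle_at_peak <- function(samples, target_angle, start = c(0, 0)) {
  v <- radial_speed(samples, start, "input")
  i <- which.max(v)
  x <- samples$input_x[i] - start[1]
  y <- samples$input_y[i] - start[2]
  if (sqrt(x^2 + y^2) < 1e-12) {
    return(list(angle = NA_real_, peak_speed = v[i], t_peak = samples$t[i]))
  }
  ang <- wrap_angle(position_angle(x, y) - target_angle)
  list(angle = ang, peak_speed = v[i], t_peak = samples$t[i])
}

#' Hand angle at a fixed radius (take-off angle)
#'
#' Same angle convention as [hand_angle_at_peak()], evaluated at the first
#' crossing of radius `r` by the input path, with the angle linearly
#' interpolated between the bracketing samples.
#'
#' @param samples Preprocessed trajectory tibble.
#' @param target_angle Target direction (degrees).
#' @param start Start-point position.
#' @param r Radius (au), 0.2 by default.
#' @return Degrees (raw), or `NA` if the path never reaches radius `r`.
#' @export
hand_angle_at_radius <- function(samples, target_angle, start = c(0, 0),
                                 r = 0.2) {
  x <- samples$input_x - start[1]
  y <- samples$input_y - start[2]
  rad <- sqrt(x^2 + y^2)
  i <- which(rad >= r)[1]
  if (is.na(i)) return(NA_real_)
  a_i <- position_angle(x[i], y[i])
  if (i == 1) return(wrap_angle(a_i - target_angle))
  f <- (r - rad[i - 1]) / (rad[i] - rad[i - 1])
  a_prev <- position_angle(x[i - 1], y[i - 1])
  a <- a_prev + f * wrap_angle(a_i - a_prev)
  wrap_angle(a - target_angle)
}

#' Normalize hand-angle sign across perturbation directions
#'
#' Flips the sign for counter-clockwise-perturbation participants so that,
#' for both directions, positive hand angles reflect movement of the hand
#' opposite to the perturbation. Unperturbed trials are normalized with the
#' participant's assigned direction so they share the group's convention.
#'
#' @param raw_angle Raw (ccw-positive) hand angle(s), degrees.
#' @param rotation_direction `"cw"` or `"ccw"` (participant's assignment).
#' @return Normalized angle(s).
#' @export
normalize_sign <- function(raw_angle, rotation_direction) {
  stopifnot(all(rotation_direction %in% c("cw", "ccw")))
  ifelse(rotation_direction == "ccw", -raw_angle, raw_angle)
}

#' 180-degree correction for Inverted-Look trials
#'
#' Inverted-Look hand movements are directed opposite to the screen target;
#' adding 180 degrees (wrapped into (-180, 180]) re-expresses the hand angle
#' relative to the ideal aim location, making Look and Inverted-Look trials
#' directly comparable.
#'
#' @param angle Degrees.
#' @return Corrected degrees in (-180, 180].
#' @export
correct_inverted_look <- function(angle) {
  wrap_angle(angle + 180)
}

#' Classify jump-start trials
#'
#' Offline rule: the trial launched toward an uncued target if the absolute
#' raw hand angle at both peak speed and take-off exceeds `threshold`.
#' Online rule (the in-task check): take-off angle alone exceeds `threshold`.
#'
#' @param hand_angle_peak Raw hand angle at peak speed (degrees).
#' @param hand_angle_takeoff Raw take-off angle (degrees).
#' @param mode `"offline"` or `"online"`.
#' @param threshold Degrees (60).
#' @return Logical.
#' @export
classify_jump_start <- function(hand_angle_peak, hand_angle_takeoff,
                                mode = c("offline", "online"),
                                threshold = 60) {
  mode <- match.arg(mode)
  if (mode == "online") {
    abs(hand_angle_takeoff) > threshold
  } else {
    abs(hand_angle_peak) > threshold & abs(hand_angle_takeoff) > threshold
  }
}

#' Extract per-trial kinematic metrics
#'
#' Runs the hand-angle extraction over a preprocessed trajectory table joined
#' with its trial metadata, producing one row of metrics per attempt:
#' peak speed and its time, raw and normalized hand angles at peak speed and
#' take-off (Inverted-Look trials receive the 180-degree correction after
#' sign normalization), the offline jump-start flag, and validity.
#'
#' @param trials Trial metadata table (from [simulate_cohort()] or
#'   [read_trials()]); must carry `participant_id`, `trial_index`, `attempt`,
#'   `target_angle`, `rotation_deg`, `context`, and a participant-level
#'   rotation direction (inferred from the sign of `rotation_deg` in the
#'   rotation block).
#' @param preprocessed Result of [preprocess_trials()].
#' @param takeoff_radius au, 0.2 by default.
#' @param jump_threshold Degrees, 60 by default.
#' @return Tibble of per-attempt metrics merged onto `trials`; excluded or
#'   unanalyzable attempts carry `valid = FALSE` and an `exclusion_reason`.
#' @export
extract_metrics <- function(trials, preprocessed,
                            takeoff_radius = 0.2, jump_threshold = 60) {
  samples <- preprocessed$samples
  exclusions <- preprocessed$exclusions
  if (!"attempt" %in% names(trials)) trials$attempt <- 1L
  rot_dir <- participant_rotation_direction(trials)
  key <- function(p, tr, at) paste(p, tr, at, sep = "\r")
  skey <- key(samples$participant_id, samples$trial_index, samples$attempt)
  sidx <- split(seq_len(nrow(samples)), factor(skey, levels = unique(skey)))
  chan <- c("t", "input_x", "input_y", "cursor_x", "cursor_y")
  n <- nrow(trials)
  peak_speed <- t_peak <- peak_raw <- takeoff_raw <- rep(NA_real_, n)
  glitch <- rep(TRUE, n)
  tkey <- key(trials$participant_id, trials$trial_index, trials$attempt)
  for (i in seq_len(n)) {
    ii <- sidx[[tkey[i]]]
    if (is.null(ii)) next
    g <- as_tbl_fast(lapply(samples[, chan], `[`, ii))
    hp <- hand_angle_at_peak(g, trials$target_angle[i])
    peak_speed[i] <- hp$peak_speed
    t_peak[i] <- hp$t_peak
    peak_raw[i] <- hp$angle
    takeoff_raw[i] <- hand_angle_at_radius(g, trials$target_angle[i],
                                           r = takeoff_radius)
    glitch[i] <- FALSE
  }
  dirs <- unlist(rot_dir[trials$participant_id])
  norm_peak <- normalize_sign(peak_raw, dirs)
  norm_takeoff <- normalize_sign(takeoff_raw, dirs)
  inv <- trials$context == "inverted_look"
  norm_peak[inv] <- correct_inverted_look(norm_peak[inv])
  norm_takeoff[inv] <- correct_inverted_look(norm_takeoff[inv])
  # classification angles are measured from the ideal aim location: on
  # inverted-look trials that is the raw angle after the 180-degree correction
  cls_peak <- peak_raw
  cls_takeoff <- takeoff_raw
  cls_peak[inv] <- correct_inverted_look(cls_peak[inv])
  cls_takeoff[inv] <- correct_inverted_look(cls_takeoff[inv])
  js <- classify_jump_start(cls_peak, cls_takeoff, "offline", jump_threshold)
  unanalyzable <- is.na(peak_raw) | is.na(takeoff_raw)
  out <- dplyr::bind_cols(trials, as_tbl_fast(list(
    peak_speed = peak_speed, t_peak = t_peak,
    hand_angle_peak_raw = peak_raw, hand_angle_takeoff_raw = takeoff_raw,
    hand_angle_peak = norm_peak, hand_angle_takeoff = norm_takeoff,
    jump_start = js, glitch = glitch,
    valid = !glitch & !unanalyzable & !isTRUE_vec(js)
  )))
  out$exclusion_reason <- NA_character_
  out$exclusion_reason[!out$valid & isTRUE_vec(out$jump_start)] <- "jump_start"
  out$exclusion_reason[out$glitch %in% TRUE] <- "glitch_or_missing"
  if (nrow(exclusions) > 0) {
    k_excl <- key(exclusions$participant_id, exclusions$trial_index,
                  exclusions$attempt)
    k_out <- key(out$participant_id, out$trial_index, out$attempt)
    m <- match(k_out, k_excl)
    out$exclusion_reason[!is.na(m)] <- exclusions$reason[m[!is.na(m)]]
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

# Rotation direction assigned to each participant, inferred from the signed
# rotation on their perturbed trials (ccw positive). Participants with no
# perturbed trials default to "cw" (identity normalization).
participant_rotation_direction <- function(trials) {
  sp <- split(trials$rotation_deg, trials$participant_id)
  lapply(sp, function(r) {
    r <- r[r != 0]
    if (length(r) == 0) "cw" else if (r[1] > 0) "ccw" else "cw"
  })
}
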