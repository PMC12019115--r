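#' Preprocessing configuration
#'
#' @param resample_hz Target uniform sampling rate (Hz).
#' @param filter_order Butterworth order per pass.
#' @param cutoff_hz Low-pass cutoff (-3 dB point per pass, Hz).
#' @param glitch_threshold Speed-change rejection threshold (au/s), applied to
#'   raw, pre-resampling frames.
#' @param pad_samples Reflection-padding length per side; defaults to
#'   `max(9 * filter_order, 24)`.
#' @return A list of class `vm_preprocess`.
#' @export
preprocess_config <- function(resample_hz = 100, filter_order = 2,
                              cutoff_hz = 15, glitch_threshold = 40,
                              pad_samples = NULL) {
  if (is.null(pad_samples)) pad_samples <- max(9 * filter_order, 24)
  stopifnot(cutoff_hz < resample_hz / 2, pad_samples >= 3 * filter_order)
  structure(
    list(resample_hz = resample_hz, filter_order = filter_order,
         cutoff_hz = cutoff_hz, glitch_threshold = glitch_threshold,
         pad_samples = pad_samples),
    class = "vm_preprocess"
  )
}

#' Detect single-frame glitches in a raw trajectory
#'
#' A trial is rejected when the cursor (or input) speed changes by more than
#' `threshold` au/s between consecutive inter-frame intervals, computed on the
#' raw, pre-resampling samples with first-order finite differences. The
#' comparison is strict (`>`), so a change of exactly the threshold passes.
#'
#' @param samples Trajectory tibble (`t`, `input_x`, `input_y`, `cursor_x`,
#'   `cursor_y`).
#' @param threshold au/s.
#' @param channels Channels to check.
#' @return `TRUE` if the trial should be excluded. Trials with fewer than 3
#'   samples are unanalyzable and return `NA`.
#' @export
detect_glitches <- function(samples, threshold = 40,
                            channels = c("cursor", "input")) {
  if (nrow(samples) < 3) return(NA)
  dt <- diff(samples$t)
  bad <- FALSE
  for (ch in channels) {
    dx <- diff(samples[[paste0(ch, "_x")]])
    dy <- diff(samples[[paste0(ch, "_y")]])
    speed <- sqrt(dx^2 + dy^2) / dt
    # strict >, with a guard for floating-point representation at the bound
    if (any(abs(diff(speed)) > threshold * (1 + 1e-9))) bad <- TRUE
  }
  bad
}

#' Resample a trajectory onto a uniform grid
#'
#' Linear interpolation of every channel onto a fixed-rate grid running from
#' the first to the last recorded timestamp (no extrapolation).
#'
#' @param samples Trajectory tibble with strictly increasing `t`.
#' @param resample_hz Target rate (Hz).
#' @return Resampled tibble.
#' @export
resample_uniform <- function(samples, resample_hz = 100) {
  if (is.unsorted(samples$t, strictly = TRUE)) {
    stop("non-monotone timestamps")
  }
  grid <- seq(samples$t[1], samples$t[nrow(samples)], by = 1 / resample_hz)
  out <- list(t = grid)
  for (ch in setdiff(names(samples), "t")) {
    if (is.numeric(samples[[ch]])) {
      out[[ch]] <- stats::approx(samples$t, samples[[ch]], xout = grid)$y
    } else {
      out[[ch]] <- rep(samples[[ch]][1], length(grid))
    }
  }
  as_tbl_fast(out)
}

# Direct-form IIR filter (zero initial conditions): vectorized FIR numerator
# followed by the C-level recursive denominator. Equivalent to
# signal::filter(Arma(b, a), x) without its time-series bookkeeping.
iir_filter <- function(b, a, x) {
  n <- length(x)
  z <- b[1] * x
  for (k in seq_along(b)[-1]) {
    if (n >= k) z[k:n] <- z[k:n] + b[k] * x[1:(n - k + 1)]
  }
  if (length(a) > 1) {
    z <- stats::filter(z, -a[-1], method = "recursive")
  }
  as.numeric(z)
}

# Odd (rotational) reflection padding about the end samples.
reflect_pad <- function(x, n) {
  stopifnot(length(x) > n)
  N <- length(x)
  head_pad <- 2 * x[1] - x[(n + 1):2]
  tail_pad <- 2 * x[N] - x[(N - 1):(N - n)]
  c(head_pad, x, tail_pad)
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a digital Butterworth filter (bilinear transform, cutoff at the
#' -3 dB point per pass) forward and backward, giving squared magnitude
#' response and net zero phase. Each channel is padded with an odd reflection
#' of `pad_samples` points before filtering, and the padding is removed
#' afterwards.
#'
#' @param samples Uniformly resampled trajectory tibble.
#' @param cfg A `vm_preprocess`.
#' @return Filtered tibble. Trials shorter than the padding length raise an
#'   error (callers mark such trials unanalyzable).
#' @export
lowpass_zero_phase <- function(samples, cfg = preprocess_config(),
                               bf = NULL) {
  n <- nrow(samples)
  if (n <= cfg$pad_samples) stop("trial too short to filter")
  if (is.null(bf)) {
    bf <- signal::butter(cfg$filter_order,
                         cfg$cutoff_hz / (cfg$resample_hz / 2), type = "low")
  }
  out <- samples
  for (ch in c("input_x", "input_y", "cursor_x", "cursor_y")) {
    if (!ch %in% names(samples)) next
    xp <- reflect_pad(samples[[ch]], cfg$pad_samples)
    y <- iir_filter(bf$b, bf$a, xp)
    y <- rev(iir_filter(bf$b, bf$a, rev(y)))
    out[[ch]] <- y[(cfg$pad_samples + 1):(cfg$pad_samples + n)]
  }
  out
}

#' Preprocess one trial: glitch check, resample, filter
#'
#' Stages run in the fixed order glitch detection (on raw frames), uniform
#' resampling, zero-phase filtering. Returns `NULL` with an exclusion reason
#' attribute when the trial cannot be analyzed.
#'
#' @param samples Raw trajectory tibble for one trial.
#' @param cfg A `vm_preprocess`.
#' @return Filtered tibble with attribute `excluded` (`NA` or a reason string
#'   among `"glitch"`, `"too-short"`, `"non-monotone"`).
#' @export
preprocess_trial <- function(samples, cfg = preprocess_config(), bf = NULL) {
  fail <- function(reason) {
    structure(samples, excluded = reason)
  }
  if (nrow(samples) < 3) return(fail("too-short"))
  if (is.unsorted(samples$t, strictly = TRUE)) return(fail("non-monotone"))
  g <- detect_glitches(samples, cfg$glitch_threshold)
  if (isTRUE(g)) return(fail("glitch"))
  rs <- resample_uniform(samples, cfg$resample_hz)
  if (nrow(rs) <= cfg$pad_samples) return(fail("too-short"))
  out <- lowpass_zero_phase(rs, cfg, bf)
  attr(out, "excluded") <- NA_character_
  out
}

#' Preprocess a long-format trajectory table
#'
#' Splits the table by (participant, trial, attempt), preprocesses each trial,
#' and returns the filtered samples together with an exclusion log.
#'
#' @param samples Long trajectory table (`participant_id`, `trial_index`,
#'   `attempt`, `t`, channels).
#' @param cfg A `vm_preprocess`.
#' @return A list with `samples` (filtered, excluded trials dropped) and
#'   `exclusions` (tibble of participant/trial/reason).
#' @export
preprocess_trials <- function(samples, cfg = preprocess_config()) {
  if (!"attempt" %in% names(samples)) samples$attempt <- 1L
  bf <- signal::butter(cfg$filter_order,
                       cfg$cutoff_hz / (cfg$resample_hz / 2), type = "low")
  key <- paste(samples$participant_id, samples$trial_index, samples$attempt,
               sep = "\r")
  idx <- split(seq_len(nrow(samples)), factor(key, levels = unique(key)))
  chan <- c("t", "input_x", "input_y", "cursor_x", "cursor_y")
  out <- vector("list", length(idx))
  excl_p <- character(0); excl_t <- integer(0)
  excl_a <- integer(0); excl_r <- character(0)
  j <- 0L
  for (ii in idx) {
    j <- j + 1L
    g <- as_tbl_fast(lapply(samples[, chan], `[`, ii))
    res <- preprocess_trial(g, cfg, bf)
    reason <- attr(res, "excluded")
    if (is.na(reason)) {
      res$participant_id <- rep(samples$participant_id[ii[1]], nrow(res))
      res$trial_index <- rep(samples$trial_index[ii[1]], nrow(res))
      res$attempt <- rep(samples$attempt[ii[1]], nrow(res))
      out[[j]] <- res
    } else {
      excl_p <- c(excl_p, samples$participant_id[ii[1]])
      excl_t <- c(excl_t, samples$trial_index[ii[1]])
      excl_a <- c(excl_a, samples$attempt[ii[1]])
      excl_r <- c(excl_r, reason)
    }
  }
  list(
    samples = dplyr::bind_rows(out),
    exclusions = tibble::tibble(participant_id = excl_p,
                                trial_index = excl_t,
                                attempt = excl_a, reason = excl_r)
  )
}
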