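#' Initialize the pair of time-limit staircases
#'
#' Two interleaved 1-up/1-down staircases set the per-trial time limit; they
#' are used equally within each block. Initial limits depend on the input
#' device: 450 and 1050 ms for mouse users, 780 and 1380 ms for trackpad
#' users. Each staircase moves by 30 ms: down after a success, up after a
#' failure, targeting ~50% success.
#'
#' @param device `"mouse"` or `"trackpad"`.
#' @return A list of class `vm_staircase` with fields `limits` (ms), `step`
#'   (30 ms), `active` (index of the staircase governing the current trial,
#'   NA until [next_limit()] is called), and `usage` (per-staircase counts in
#'   the current block).
#' @export
init_staircases <- function(device = c("mouse", "trackpad")) {
  device <- match.arg(device)
  limits <- if (device == "mouse") c(450, 1050) else c(780, 1380)
  structure(
    list(limits = limits, step = 30, active = NA_integer_,
         usage = c(0L, 0L), device = device),
    class = "vm_staircase"
  )
}

#' Draw the time limit for the upcoming trial
#'
#' Selects the less-used staircase of the pair (ties broken by `tiebreak`),
#' enforcing equal use within a block.
#'
#' @param state A `vm_staircase`.
#' @param tiebreak 1 or 2: which staircase to use when usage counts are tied.
#' @return The updated state; the drawn limit is `state$limits[state$active]`.
#' @export
next_limit <- function(state, tiebreak = 1L) {
  idx <- if (state$usage[1] < state$usage[2]) 1L
         else if (state$usage[2] < state$usage[1]) 2L
         else as.integer(tiebreak)
  state$active <- idx
  state$usage[idx] <- state$usage[idx] + 1L
  state
}

#' Update the active staircase after a trial outcome
#'
#' The staircase that set the current trial's limit is decreased by 30 ms
#' after a success and increased by 30 ms after a failure.
#'
#' @param state A `vm_staircase` whose `active` field is set.
#' @param success Logical trial outcome.
#' @return The updated state.
#' @export
update_staircase <- function(state, success) {
  stopifnot(!is.na(state$active))
  delta <- if (isTRUE(success)) -state$step else state$step
  state$limits[state$active] <- state$limits[state$active] + delta
  state
}

#' Reset per-block staircase usage counts
#'
#' @param state A `vm_staircase`.
#' @return State with usage counts zeroed (limits carry over across blocks).
#' @export
reset_staircase_block <- function(state) {
  state$usage <- c(0L, 0L)
  state
}

#' Run the staircase against a simulated observer
#'
#' Simulates `n_trials` staircased trials for an observer whose success
#' probability is a logistic function of the time limit:
#' `plogis((limit - threshold) / slope)`. Used to verify that the 1-up/1-down
#' rule converges to ~50% success for any monotone observer.
#'
#' @param n_trials Number of trials.
#' @param device Input device (sets initial limits).
#' @param threshold Observer's 50%-success time limit (ms).
#' @param slope Logistic slope (ms).
#' @param seed Integer seed.
#' @param block_length Trials per block (usage counts reset at block starts).
#' @return A tibble with per-trial `limit`, `staircase`, `success`.
#' @export
run_staircase <- function(n_trials = 480, device = "mouse",
                          threshold = 600, slope = 100, seed = 1L,
                          block_length = 80) {
  rng <- make_rng(seed)
  st <- init_staircases(device)
  limit <- integer(n_trials)
  which_sc <- integer(n_trials)
  success <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    if ((i - 1) %% block_length == 0) st <- reset_staircase_block(st)
    st <- next_limit(st, tiebreak = sample_rng(rng, 1:2, size = 1))
    limit[i] <- st$limits[st$active]
    which_sc[i] <- st$active
    p <- stats::plogis((limit[i] - threshold) / slope)
    success[i] <- runif_rng(rng, 1) < p
    st <- update_staircase(st, success[i])
  }
  tibble::tibble(trial = seq_len(n_trials), limit = limit,
                 staircase = which_sc, success = success)
}
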