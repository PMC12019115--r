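#' Build an experiment trial schedule
#'
#' Constructs the ordered trial plan for one participant of one of the four
#' experiment designs:
#'
#' \describe{
#'   \item{exp1}{680 trials in a single context: 100 unperturbed baseline,
#'     480 with a 30 degree rotation, 100 washout. Cycles of four trials visit
#'     each cardinal target once in random order.}
#'   \item{exp2a}{800 trials: 100 baseline in the untrained context, 100
#'     baseline in the trained context, 480 rotation trials in the trained
#'     context, then (rotation off) 100 trials in the untrained context and 20
#'     in the trained context.}
#'   \item{exp2b}{As exp2a but the rotation stays on during the final 120
#'     trials.}
#'   \item{exp3}{760 trials: 60 baseline to the top/bottom targets (40 with 20
#'     contiguous trials per context in random order, then 20 with contexts
#'     interleaved), 20 Point trials to the top target introducing the
#'     no-feedback return, a 270-trial baseline generalization block (15 cycles
#'     of 18 trials), 120 Point rotation trials to the top target, a 270-trial
#'     generalization block (Point top-up trials perturbed, probes never), and
#'     20 unperturbed Point trials. Each generalization cycle has 3 probe
#'     trials in the probed context (a lateral 0/180 target first, then top and
#'     bottom, top first in seven or eight of the 15 cycles in random order)
#'     followed by 15 Point top-target top-up trials.}
#' }
#'
#' @param experiment `"exp1"`, `"exp2a"`, `"exp2b"`, or `"exp3"`.
#' @param rotation_direction `"cw"` or `"ccw"` (participant counterbalancing).
#' @param seed Integer seed controlling target/context randomization.
#' @param context Context for exp1 (`"point"` or `"look"`).
#' @param trained_context Trained context for exp2a/2b.
#' @param probe_context Probed context for exp3 (`"look"` or `"inverted_look"`).
#' @return A tibble of class `vm_schedule` with one row per trial:
#'   `trial_index`, `block_label`, `context`, `target_angle`, `rotation_deg`
#'   (signed, ccw positive), `probe_flag`, `return_feedback`, plus attributes
#'   `experiment` and `rotation_direction`.
#' @export
build_schedule <- function(experiment = c("exp1", "exp2a", "exp2b", "exp3"),
                           rotation_direction = c("cw", "ccw"),
                           seed = 1L,
                           context = "point",
                           trained_context = "point",
                           probe_context = "look") {
  experiment <- match.arg(experiment)
  rotation_direction <- match.arg(rotation_direction)
  rng <- make_rng(seed)
  rot <- if (rotation_direction == "cw") -30 else 30

  cycles_of <- function(n_trials) {
    stopifnot(n_trials %% 4 == 0)
    unlist(lapply(seq_len(n_trials / 4),
                  function(i) sample_rng(rng, c(0, 90, 180, 270))))
  }

  if (experiment == "exp1") {
    stopifnot(context %in% c("point", "look"))
    blocks <- list(
      list(label = "baseline", n = 100, rot = 0),
      list(label = "rotation", n = 480, rot = rot),
      list(label = "washout", n = 100, rot = 0)
    )
    df <- dplyr::bind_rows(lapply(blocks, function(b) {
      tibble::tibble(block_label = b$label, context = context,
                     target_angle = cycles_of(b$n), rotation_deg = b$rot,
                     probe_flag = FALSE, return_feedback = TRUE)
    }))
  } else if (experiment %in% c("exp2a", "exp2b")) {
    stopifnot(trained_context %in% c("point", "look"))
    untrained <- setdiff(c("point", "look"), trained_context)
    post_rot <- if (experiment == "exp2b") rot else 0
    blocks <- list(
      list(label = "baseline_untrained", n = 100, rot = 0, ctx = untrained),
      list(label = "baseline_trained", n = 100, rot = 0, ctx = trained_context),
      list(label = "rotation", n = 480, rot = rot, ctx = trained_context),
      list(label = "transfer", n = 100, rot = post_rot, ctx = untrained),
      list(label = "post", n = 20, rot = post_rot, ctx = trained_context)
    )
    df <- dplyr::bind_rows(lapply(blocks, function(b) {
      tibble::tibble(block_label = b$label, context = b$ctx,
                     target_angle = cycles_of(b$n), rotation_deg = b$rot,
                     probe_flag = FALSE, return_feedback = TRUE)
    }))
  } else {
    stopifnot(probe_context %in% c("look", "inverted_look"))
    # 40 trials: 20 contiguous per context (order randomized), top/bottom only
    ctx_order <- sample_rng(rng, c("point", probe_context))
    tb <- function(n) {
      unlist(lapply(seq_len(n / 2), function(i) sample_rng(rng, c(90, 270))))
    }
    intro <- tibble::tibble(
      block_label = "baseline",
      context = rep(ctx_order, each = 20),
      target_angle = c(tb(20), tb(20)),
      rotation_deg = 0, probe_flag = FALSE, return_feedback = TRUE
    )
    inter <- tibble::tibble(
      block_label = "baseline",
      context = sample_rng(rng, rep(c("point", probe_context), 10)),
      target_angle = tb(20),
      rotation_deg = 0, probe_flag = FALSE, return_feedback = TRUE
    )
    nfb <- tibble::tibble(
      block_label = "baseline_nofeedback", context = "point",
      target_angle = 90, rotation_deg = 0, probe_flag = FALSE,
      return_feedback = FALSE
    )[rep(1, 20), ]
    gen_block <- function(label, topup_rot) {
      n_top <- sample_rng(rng, 7:8, size = 1)
      top_first <- sample_rng(rng, rep(c(TRUE, FALSE), c(n_top, 15 - n_top)))
      dplyr::bind_rows(lapply(seq_len(15), function(cyc) {
        lateral <- sample_rng(rng, c(0, 180), size = 1)
        vert <- if (top_first[cyc]) c(90, 270) else c(270, 90)
        probes <- tibble::tibble(
          block_label = label, context = probe_context,
          target_angle = c(lateral, vert), rotation_deg = 0,
          probe_flag = TRUE, return_feedback = TRUE
        )
        topup <- tibble::tibble(
          block_label = label, context = "point", target_angle = 90,
          rotation_deg = topup_rot, probe_flag = FALSE, return_feedback = FALSE
        )[rep(1, 15), ]
        dplyr::bind_rows(probes, topup)
      }))
    }
    rot_block <- tibble::tibble(
      block_label = "rotation", context = "point", target_angle = 90,
      rotation_deg = rot, probe_flag = FALSE, return_feedback = FALSE
    )[rep(1, 120), ]
    wash <- tibble::tibble(
      block_label = "washout", context = "point", target_angle = 90,
      rotation_deg = 0, probe_flag = FALSE, return_feedback = FALSE
    )[rep(1, 20), ]
    df <- dplyr::bind_rows(intro, inter, nfb,
                           gen_block("baseline_generalization", 0),
                           rot_block,
                           gen_block("generalization", rot),
                           wash)
  }
  df$trial_index <- seq_len(nrow(df))
  df <- df[, c("trial_index", "block_label", "context", "target_angle",
               "rotation_deg", "probe_flag", "return_feedback")]
  attr(df, "experiment") <- experiment
  attr(df, "rotation_direction") <- rotation_direction
  class(df) <- c("vm_schedule", class(df))
  df
}

# Package-local counter-based RNG stream: a closure over a seeded
# sample.int-compatible state, so schedule/learner/trajectory draws do not
# perturb the caller's .Random.seed.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  local_seed <- as.integer(seed %% .Machine$integer.max)
  withr::with_seed(local_seed, env$state <- .Random.seed)
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  eval.parent(substitute(expr))
}

sample_rng <- function(rng, x, size = length(x), replace = FALSE) {
  with_rng(rng, sample(x, size = size, replace = replace))
}

runif_rng <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

rnorm_rng <- function(rng, n, mean = 0, sd = 1) {
  with_rng(rng, stats::rnorm(n, mean, sd))
}
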