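test_that("cycle means average valid trials in groups of four", {
  m <- make_metrics("P1", "rotation", as.numeric(1:8))
  cs <- assign_cycles(m)
  expect_equal(cs$mean_hand_angle, c(2.5, 6.5))
  expect_equal(cs$n_valid, c(4L, 4L))
  # an excluded jump start does not contribute to the mean
  m2 <- make_metrics("P1", "rotation", c(10, 10, 10, 55),
                     valid = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(assign_cycles(m2)$mean_hand_angle, 10)
  # a fully invalid cycle is missing
  m3 <- make_metrics("P1", "rotation", rep(1, 4), valid = FALSE)
  expect_true(is.na(assign_cycles(m3)$mean_hand_angle))
  expect_error(assign_cycles(make_metrics("P1", "rotation", 1:6)),
               "divisible by 4")
})

test_that("cycle means ignore excluded values and trial order within cycle", {
  set.seed(9)
  vals <- rnorm(8)
  m <- make_metrics("P1", "baseline", vals)
  perm <- c(sample(1:4), 4 + sample(1:4))
  mp <- make_metrics("P1", "baseline", vals[perm])
  expect_equal(assign_cycles(m)$mean_hand_angle,
               assign_cycles(mp)$mean_hand_angle)
  # the magnitude of an excluded trial is irrelevant
  m4 <- make_metrics("P1", "baseline", c(vals[1:3], 1e6),
                     valid = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(assign_cycles(m4)$mean_hand_angle[1], mean(vals[1:3]))
})

test_that("period means use the published cycle windows", {
  # constant series: every period mean equals the constant
  cs <- tibble::tibble(
    participant_id = "P1",
    block_label = rep(c("baseline", "rotation", "washout"),
                      c(25, 120, 25)),
    cycle_index = 1:170,
    mean_hand_angle = 20, n_valid = 4L
  )
  pm <- period_means(cs, "exp1")
  expect_setequal(pm$period, c("baseline", "early_rotation", "late_rotation",
                               "early_washout", "late_washout"))
  expect_true(all(pm$mean_hand_angle == 20))
  # rotation cycles numbered 1..120 by value: early 5.5, late 115.5
  cs2 <- cs
  cs2$mean_hand_angle <- c(rep(0, 25), 1:120, rep(0, 25))
  pm2 <- period_means(cs2, "exp1")
  expect_equal(pm2$mean_hand_angle[pm2$period == "early_rotation"], 5.5)
  expect_equal(pm2$mean_hand_angle[pm2$period == "late_rotation"], 115.5)
  # missing cycles are skipped, not imputed
  cs3 <- cs2
  cs3$mean_hand_angle[26] <- NA
  pm3 <- period_means(cs3, "exp1")
  expect_equal(pm3$mean_hand_angle[pm3$period == "early_rotation"],
               mean(2:10))
})

test_that("exp3 learning periods use trials, not cycles", {
  m <- make_metrics("P1", "rotation", as.numeric(1:120))
  m$block_label <- "rotation"
  pm <- period_means(m, "exp3")
  expect_equal(pm$mean_hand_angle[pm$period == "early_learning_trials"],
               mean(1:10))
  expect_equal(pm$mean_hand_angle[pm$period == "late_learning_trials"],
               mean(111:120))
})

test_that("after-effect and transfer are the defined period differences", {
  s <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 3),
    period = rep(c("late_rotation", "early_washout", "early_transfer"), 2),
    mean_hand_angle = c(20, 15, 21, 22, 22, 22)
  )
  ae <- after_effect(s)
  expect_equal(ae$after_effect, c(-5, 0))
  tm <- transfer_measure(s)
  expect_equal(tm$transfer, c(1, 0))
  expect_error(after_effect(s[s$period == "late_rotation", ]),
               "missing period")
})

test_that("baseline correction subtracts per-target baseline probes", {
  probes <- function(block, vals) {
    m <- make_metrics("P1", block, vals,
                      target_angle = rep(c(0, 90, 270), length.out =
                                           length(vals)),
                      context = "look", probe_flag = TRUE)
    m
  }
  m <- rbind(probes("baseline_generalization", c(2, 2, 2, 2, 2, 2)),
             probes("generalization", c(12, 12, 12, 12, 12, 12)))
  m$trial_index <- seq_len(nrow(m))
  g <- baseline_correct(m)
  expect_equal(g$corrected_hand_angle, rep(10, 3))
  expect_setequal(g$handspace_relation, c("lateral", "trained", "untrained"))
  # identical blocks give zero everywhere
  m0 <- rbind(probes("baseline_generalization", rep(3, 6)),
              probes("generalization", rep(3, 6)))
  m0$trial_index <- seq_len(nrow(m0))
  expect_true(all(baseline_correct(m0)$corrected_hand_angle == 0))
})

test_that("handspace relation follows the planned hand vector", {
  expect_equal(handspace_relation(90, "look"), "trained")
  expect_equal(handspace_relation(270, "look"), "untrained")
  # inverted look: the top-screen target needs a downward hand movement
  expect_equal(handspace_relation(90, "inverted_look"), "untrained")
  expect_equal(handspace_relation(270, "inverted_look"), "trained")
  expect_equal(handspace_relation(0, "look"), "lateral")
  expect_equal(handspace_relation(180, "inverted_look"), "lateral")
})

test_that("top-up asymptote averages the last trials of each cycle", {
  vals <- rep(c(rep(0, 3), rep(c(10, 20, 30), each = 5)), 15)
  m <- make_metrics("P1", "generalization", vals)
  m$probe_flag <- rep(c(TRUE, TRUE, TRUE, rep(FALSE, 15)), 15)
  tp <- topup_asymptote(m, n_last = 5)
  expect_equal(tp$mean_topup_hand_angle, 30)
})
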