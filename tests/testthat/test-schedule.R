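test_that("schedules have the published trial counts and block structure", {
  s1 <- build_schedule("exp1", "cw", seed = 1)
  expect_equal(nrow(s1), 680)
  expect_equal(as.vector(table(s1$block_label)[c("baseline", "rotation",
                                                 "washout")]),
               c(100L, 480L, 100L))
  expect_true(all(s1$rotation_deg[s1$block_label == "rotation"] == -30))
  expect_true(all(s1$rotation_deg[s1$block_label != "rotation"] == 0))

  for (e in c("exp2a", "exp2b")) {
    s2 <- build_schedule(e, "ccw", seed = 2, trained_context = "look")
    expect_equal(nrow(s2), 800)
    expect_equal(sum(s2$block_label == "transfer"), 100)
    expect_equal(sum(s2$block_label == "post"), 20)
    expect_true(all(s2$context[s2$block_label == "rotation"] == "look"))
    expect_true(all(s2$context[s2$block_label == "transfer"] == "point"))
    expect_true(all(s2$context[s2$block_label == "post"] == "look"))
  }
  # exp2a turns the rotation off after learning; exp2b leaves it on
  s2a <- build_schedule("exp2a", "cw", seed = 3)
  s2b <- build_schedule("exp2b", "cw", seed = 3)
  expect_true(all(s2a$rotation_deg[s2a$block_label %in%
                                     c("transfer", "post")] == 0))
  expect_true(all(s2b$rotation_deg[s2b$block_label %in%
                                     c("transfer", "post")] == -30))

  s3 <- build_schedule("exp3", "cw", seed = 4, probe_context = "look")
  expect_equal(nrow(s3), 760)
  expect_equal(
    as.vector(table(s3$block_label)[c("baseline", "baseline_nofeedback",
                                      "baseline_generalization", "rotation",
                                      "generalization", "washout")]),
    c(60L, 20L, 270L, 120L, 270L, 20L))
})

test_that("cycled blocks visit each target once per run of four, all seeds", {
  for (seed in 1:5) {
    s <- build_schedule("exp1", "ccw", seed = seed)
    tg <- matrix(s$target_angle, nrow = 4)
    expect_true(all(apply(tg, 2, function(z) setequal(z, c(0, 90, 180, 270)))))
    s2 <- build_schedule("exp2a", "cw", seed = seed)
    tg2 <- matrix(s2$target_angle, nrow = 4)
    expect_true(all(apply(tg2, 2, function(z) {
      setequal(z, c(0, 90, 180, 270))
    })))
  }
})

test_that("exp3 generalization cycles are 3 probes then 15 top-up trials", {
  s <- build_schedule("exp3", "cw", seed = 7, probe_context = "inverted_look")
  for (blk in c("baseline_generalization", "generalization")) {
    b <- s[s$block_label == blk, ]
    expect_equal(nrow(b), 270)
    top_first <- logical(15)
    for (cyc in 1:15) {
      cycle <- b[((cyc - 1) * 18 + 1):(cyc * 18), ]
      expect_true(all(cycle$probe_flag[1:3]))
      expect_false(any(cycle$probe_flag[4:18]))
      expect_true(cycle$target_angle[1] %in% c(0, 180))
      expect_setequal(cycle$target_angle[2:3], c(90, 270))
      expect_true(all(cycle$context[1:3] == "inverted_look"))
      expect_true(all(cycle$context[4:18] == "point"))
      expect_true(all(cycle$target_angle[4:18] == 90))
      top_first[cyc] <- cycle$target_angle[2] == 90
    }
    expect_true(sum(top_first) %in% c(7, 8))
  }
  # top-up trials perturbed only in the generalization block; probes never
  expect_true(all(s$rotation_deg[s$probe_flag] == 0))
  gen_topup <- s$block_label == "generalization" & !s$probe_flag
  expect_true(all(s$rotation_deg[gen_topup] == -30))
})

test_that("staircases start at the device limits and step by 30 ms", {
  expect_equal(init_staircases("mouse")$limits, c(450, 1050))
  expect_equal(init_staircases("trackpad")$limits, c(780, 1380))
  expect_equal(init_staircases("mouse")$step, 30)
  expect_error(init_staircases("keyboard"))
  st <- next_limit(init_staircases("mouse"))
  expect_equal(update_staircase(st, TRUE)$limits[st$active], 420)
  expect_equal(update_staircase(st, FALSE)$limits[st$active], 480)
})

test_that("the two staircases are used equally within each block", {
  res <- run_staircase(480, seed = 5, block_length = 80)
  for (b in split(res$staircase, (res$trial - 1) %/% 80)) {
    expect_equal(sum(b == 1), sum(b == 2))
  }
})

test_that("1-up/1-down staircase converges to ~50% success", {
  rates <- vapply(1:5, function(s) {
    mean(run_staircase(480, threshold = 600, slope = 100, seed = s)$success)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.5), 0.03)
  # monotone observer with a different psychometric still converges
  steep <- mean(run_staircase(480, threshold = 900, slope = 30,
                              seed = 2)$success)
  expect_lt(abs(steep - 0.5), 0.06)
})
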