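rand_mixed_data <- function(n_per_group = 4, k = 2, effect = 0,
                            interaction = 0) {
  id <- rep(seq_len(2 * n_per_group), each = k)
  g <- rep(rep(c("g1", "g2"), each = n_per_group), each = k)
  w <- rep(paste0("w", seq_len(k)), 2 * n_per_group)
  y <- rnorm(length(id)) + effect * (w == "w2") +
    interaction * (g == "g2" & w == "w2")
  data.frame(value = y, participant = id, group = g, period = w)
}

test_that("mixed_anova matches the brute-force sums-of-squares oracle", {
  set.seed(100)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    d <- rand_mixed_data(n_per_group = sample(3:8, 1), k = k)
    res <- mixed_anova(d)
    orc <- mixed_anova_oracle(d$value, d$participant, d$group, d$period)
    expect_equal(res$F[1], orc$F_g, tolerance = 1e-8)
    expect_equal(res$F[2], orc$F_w, tolerance = 1e-8)
    expect_equal(res$F[3], orc$F_gw, tolerance = 1e-8)
    expect_equal(res$df_den[1], unname(orc$df["subj"]))
    expect_equal(res$df_den[2], unname(orc$df["err"]))
  }
})

test_that("degenerate and constructed designs give the expected F pattern", {
  # identical constant data in both groups: all F = 0
  d0 <- rand_mixed_data(4)
  d0$value <- 5
  expect_true(all(mixed_anova(d0)$F == 0))
  # a pure within effect leaves the interaction at zero
  set.seed(101)
  d <- rand_mixed_data(6)
  base <- d$value[d$period == "w1"]
  d$value[d$period == "w2"] <- base + 10 # rows are id-ordered within level
  res <- mixed_anova(d)
  expect_lt(res$F[res$effect == "group:period"], 1e-6)
  expect_gt(res$F[res$effect == "period"], 100)
})

test_that("between-groups F equals the squared pooled t when one level", {
  set.seed(102)
  for (i in 1:10) {
    d <- rand_mixed_data(n_per_group = sample(4:10, 1), k = 1)
    res <- mixed_anova(d)
    tt <- t.test(value ~ group, data = d, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("partial eta squared satisfies its identity for every effect", {
  set.seed(103)
  d <- rand_mixed_data(8, effect = 1, interaction = 0.5)
  res <- mixed_anova(d)
  expect_equal(res$eta_p2,
               res$F * res$df_num / (res$F * res$df_num + res$df_den))
})

test_that("marginal-mean contrasts match the closed-form pooled t", {
  set.seed(104)
  d <- rand_mixed_data(5)
  # equal group means at w1
  d$value[d$period == "w1"] <- rep(c(1, 2, 3, 4, 5), 2)
  c1 <- emm_contrast(d, at = "w1")
  expect_equal(c1$estimate, 0)
  expect_lt(abs(c1$t), 1e-10)
  # +2 offset for group 2 at w2
  base <- c(0.3, -1, 2, 0.1, 1.2)
  d$value[d$period == "w2"] <- c(base, base + 2)
  c2 <- emm_contrast(d, at = "w2")
  expect_equal(c2$estimate, -2)
  a <- base; b <- base + 2
  sp <- sqrt(((4) * var(a) + (4) * var(b)) / 8)
  expect_equal(c2$t, (mean(a) - mean(b)) / (sp * sqrt(2 / 5)),
               tolerance = 1e-12)
  expect_equal(c2$df, 8)
  expect_error(emm_contrast(d, at = "w9"), "unknown within-level")
})

test_that("contrast CI excludes zero exactly when p < 0.05", {
  set.seed(105)
  for (i in 1:30) {
    d <- rand_mixed_data(5, interaction = runif(1, 0, 3))
    cc <- emm_contrast(d, at = "w2")
    excl <- cc$ci_low > 0 || cc$ci_high < 0
    expect_equal(excl, cc$p < 0.05)
  }
})

test_that("t tests cover paired, degenerate, and Welch cases", {
  p0 <- t_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(p0$estimate, 0)
  expect_equal(p0$p, 1)
  pd <- t_tests(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_equal(pd$estimate, -1)
  expect_true(pd$degenerate)
  w <- t_tests(c(0, 1, 2), c(1, 2, 3))
  expect_equal(w$estimate, -1)
  expect_equal(w$t, -1 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(unname(w$t), -1.2247, tolerance = 1e-4)
})

test_that("BIC Bayes factor approximation inverts correctly", {
  expect_equal(bf10_approx(-10, -10, 20, 2, 2), 1)
  # a BIC difference of 2 log 3 gives BF ~ 3
  ll1 <- -10
  ll0 <- ll1 - log(3) # same k: BIC0 - BIC1 = 2 log 3
  expect_equal(bf10_approx(ll0, ll1, 50, 2, 2), 3, tolerance = 1e-12)
  expect_error(bf10_approx(-1, -1, 2, 2, 3))
})

test_that("mixed_lm recovers a noiseless line and falls back gracefully", {
  d <- expand.grid(participant = paste0("P", 1:5), cycle = 1:10)
  d$value <- 2 + 0.5 * d$cycle
  fit <- suppressMessages(suppressWarnings(
    mixed_lm(d, center_cycle = 0)
  ))
  expect_equal(fit$beta[fit$term == "cyc"], 0.5, tolerance = 1e-8)
  expect_equal(fit$beta[fit$term == "(Intercept)"], 2, tolerance = 1e-6)
  # single participant: random intercept inestimable
  d1 <- d[d$participant == "P1", ]
  d1$value <- d1$value + rnorm(10, 0, 0.1)
  expect_warning(f1 <- mixed_lm(d1, center_cycle = 0), "falling back")
  expect_true(all(f1$fallback))
  expect_equal(f1$beta[f1$term == "cyc"], 0.5, tolerance = 0.2)
})

test_that("mixed_lm covers the generating slope at the nominal rate", {
  set.seed(106)
  hits <- 0
  n_sims <- 120
  for (i in 1:n_sims) {
    u <- rnorm(30, 0, 3)
    d <- expand.grid(participant = 1:30, cycle = 1:26)
    d$value <- 5 + 0.1 * d$cycle + u[d$participant] + rnorm(nrow(d), 0, 1)
    fit <- suppressMessages(mixed_lm(d, center_cycle = 0))
    s <- fit[fit$term == "cyc", ]
    if (s$ci_low <= 0.1 && 0.1 <= s$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n_sims, 0.9)
})

test_that("intercepts can be tested against a reference value", {
  set.seed(107)
  d <- expand.grid(participant = 1:20, cycle = 0:10)
  d$value <- 21 + rnorm(nrow(d), 0, 1) + rnorm(20, 0, 2)[d$participant]
  fit <- suppressMessages(mixed_lm(d, intercept_ref = 21))
  ic <- fit[fit$term == "(Intercept)", ]
  expect_true(ic$ci_low <= 0 && 0 <= ic$ci_high)
})
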