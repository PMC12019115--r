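make_samples <- function(t, x, y = 0 * x) {
  tibble::tibble(t = t, input_x = x, input_y = y, cursor_x = x, cursor_y = y)
}

test_that("glitch detection triggers on >40 au/s speed changes, strictly", {
  t <- seq(0, 0.5, by = 0.01)
  smooth <- make_samples(t, t) # constant 1 au/s
  expect_false(detect_glitches(smooth))
  jump <- smooth
  jump$cursor_x[25] <- jump$cursor_x[25] + 0.5 # 50 au/s speed change
  expect_true(detect_glitches(jump))
  # change of exactly the threshold passes (strict >)
  exact <- smooth
  exact$cursor_x[25:length(t)] <- exact$cursor_x[25:length(t)] + 0.4
  dx <- diff(exact$cursor_x) / diff(exact$t)
  expect_equal(max(abs(diff(dx))), 40, tolerance = 1e-9)
  expect_false(detect_glitches(exact))
  expect_true(is.na(detect_glitches(smooth[1:2, ])))
})

test_that("glitches on the input channel alone are caught", {
  t <- seq(0, 0.5, by = 0.01)
  s <- make_samples(t, t)
  s$input_y[30] <- s$input_y[30] + 1
  expect_true(detect_glitches(s))
  expect_false(detect_glitches(s, channels = "cursor"))
})

test_that("uniform resampling is exact on its grid and on affine signals", {
  t <- seq(0, 1, by = 0.01)
  s <- make_samples(t, sin(2 * pi * t))
  expect_equal(resample_uniform(s, 100)$input_x, s$input_x, tolerance = 1e-12)
  # 60 Hz ramp: linear interpolation is exact for affine signals
  t60 <- seq(0, 1, by = 1 / 60)
  ramp <- make_samples(t60, 2 * t60 - 0.3)
  rs <- resample_uniform(ramp, 100)
  expect_equal(rs$input_x, 2 * rs$t - 0.3, tolerance = 1e-12)
  expect_equal(diff(range(diff(rs$t))), 0, tolerance = 1e-12)
  # 2 Hz sinusoid at 144 Hz: standard linear-interpolation error bound
  t144 <- seq(0, 1, by = 1 / 144)
  sine <- make_samples(t144, sin(2 * pi * 2 * t144))
  rs2 <- resample_uniform(sine, 100)
  bound <- (2 * pi * 2 / 144)^2 / 8
  expect_lt(max(abs(rs2$input_x - sin(2 * pi * 2 * rs2$t))), bound + 1e-12)
  expect_error(resample_uniform(make_samples(c(0, 0.2, 0.1), 1:3), 100),
               "non-monotone")
})

test_that("zero-phase filter matches the two-pass Butterworth magnitude", {
  cfg <- preprocess_config()
  t <- seq(0, 4, by = 0.01)
  gain <- function(f) {
    s <- make_samples(t, sin(2 * pi * f * t))
    y <- lowpass_zero_phase(s, cfg)$input_x
    core <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
    fit <- lm(y[core] ~ sin(2 * pi * f * t[core]) + cos(2 * pi * f * t[core]))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  analytic <- function(f) 1 / (1 + (f / 15)^4)
  expect_lt(abs(gain(2) - analytic(2)), 0.01)
  expect_lt(abs(gain(15) - analytic(15)), 0.02)
  expect_lt(abs(gain(30) - analytic(30)), 0.05)
  # DC passes untouched
  dc <- make_samples(t, rep(2.5, length(t)))
  expect_equal(lowpass_zero_phase(dc, cfg)$input_x, dc$input_x,
               tolerance = 1e-6)
})

test_that("filtering is zero-phase and time-reversal symmetric", {
  cfg <- preprocess_config()
  t <- seq(0, 3, by = 0.01)
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(length(t)), rep(1 / 15, 15),
                                sides = 2))
  x[is.na(x)] <- 0
  s <- make_samples(t, x)
  y <- lowpass_zero_phase(s, cfg)$input_x
  cc <- ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # time reversal: filter(rev(x)) == rev(filter(x))
  sr <- make_samples(t, rev(x))
  yr <- lowpass_zero_phase(sr, cfg)$input_x
  expect_equal(rev(yr), y, tolerance = 1e-6)
})

test_that("monotone non-increasing magnitude response", {
  cfg <- preprocess_config()
  t <- seq(0, 4, by = 0.01)
  gains <- vapply(c(1, 5, 10, 15, 20, 30, 40), function(f) {
    s <- make_samples(t, sin(2 * pi * f * t))
    y <- lowpass_zero_phase(s, cfg)$input_x
    core <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
    fit <- lm(y[core] ~ sin(2 * pi * f * t[core]) + cos(2 * pi * f * t[core]))
    sqrt(sum(coef(fit)[2:3]^2))
  }, numeric(1))
  expect_true(all(diff(gains) < 1e-6))
})

test_that("preprocess_trial runs stages in order with reason codes", {
  t <- seq(0, 0.5, by = 1 / 60)
  s <- make_samples(t, t)
  out <- preprocess_trial(s)
  expect_true(is.na(attr(out, "excluded")))
  expect_equal(diff(range(diff(out$t))), 0, tolerance = 1e-12)
  bad <- s
  bad$cursor_x[10] <- bad$cursor_x[10] + 1
  expect_equal(attr(preprocess_trial(bad), "excluded"), "glitch")
  expect_equal(attr(preprocess_trial(s[1:2, ]), "excluded"), "too-short")
  ns <- s
  ns$t[5] <- ns$t[7]
  expect_equal(attr(preprocess_trial(ns), "excluded"), "non-monotone")
  # a trial shorter than the padding after resampling is unanalyzable
  short <- make_samples(seq(0, 0.1, by = 1 / 60),
                        seq(0, 0.1, by = 1 / 60))
  expect_equal(attr(preprocess_trial(short), "excluded"), "too-short")
})
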