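#' BIC-approximate Bayes factor
#'
#' Transparent approximation to the Bayes factor for model 1 over model 0
#' from maximized log-likelihoods: `BF10 ~= exp((BIC0 - BIC1) / 2)` with
#' `BIC = k log(n) - 2 loglik`. Clearly an approximation to default-prior
#' Bayes factors; reported alongside p values, never as a substitute for them.
#'
#' @param loglik0,loglik1 Maximized log-likelihoods of the two models.
#' @param n Number of observations.
#' @param k0,k1 Parameter counts.
#' @return Approximate BF10 (unitless).
#' @export
bf10_approx <- function(loglik0, loglik1, n, k0, k1) {
  stopifnot(n > max(k0, k1))
  bic0 <- k0 * log(n) - 2 * loglik0
  bic1 <- k1 * log(n) - 2 * loglik1
  exp((bic0 - bic1) / 2)
}

# Gaussian profile log-likelihood given a residual sum of squares.
loglik_rss <- function(rss, n) {
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

#' Two-factor mixed-design ANOVA
#'
#' One between-participant factor crossed with one within-participant factor,
#' fitted by the standard mixed-design sums-of-squares decomposition (via
#' `stats::aov` with a participant error stratum). Reports F, degrees of
#' freedom, p, partial eta squared
#' (`eta_p2 = F * df_num / (F * df_num + df_den)`), and a BIC-approximate
#' Bayes factor per effect (computed on participant means for the between
#' effect and on within-participant differences for the within and
#' interaction effects; two within levels are required for the BF shortcut).
#'
#' @param data Long data frame with one row per participant x within-level.
#' @param value,participant,between,within Column names.
#' @return Tibble of class `vm_anova`: `effect`, `F`, `df_num`, `df_den`,
#'   `p`, `eta_p2`, `bf10_approx`.
#' @export
mixed_anova <- function(data, value = "value", participant = "participant",
                        between = "group", within = "period") {
  d <- data.frame(
    y = data[[value]],
    id = factor(data[[participant]]),
    g = factor(data[[between]]),
    w = factor(data[[within]])
  )
  counts <- table(d$id, d$w)
  if (any(counts != 1)) stop("each participant needs every within-level once")
  if (nlevels(d$w) == 1) {
    # degenerate one-within-level design: a one-way between-groups ANOVA
    fit1 <- stats::lm(y ~ g, data = d)
    a1 <- stats::anova(fit1)
    Fv <- a1$`F value`[1]
    if (a1$`Sum Sq`[1] < 1e-12) Fv <- 0
    n <- nrow(d)
    rss1 <- sum(stats::resid(fit1)^2)
    rss0 <- sum((d$y - mean(d$y))^2)
    out <- tibble::tibble(
      effect = between, F = Fv, df_num = a1$Df[1], df_den = a1$Df[2],
      p = if (Fv == 0) 1 else a1$`Pr(>F)`[1],
      eta_p2 = Fv * a1$Df[1] / (Fv * a1$Df[1] + a1$Df[2]),
      bf10_approx = bf10_approx(loglik_rss(rss0, n), loglik_rss(rss1, n),
                                n, 2, 3)
    )
    class(out) <- c("vm_anova", class(out))
    return(out)
  }
  fit <- stats::aov(y ~ g * w + Error(id / w), data = d)
  s <- summary(fit)
  tab <- do.call(rbind, lapply(s, function(stratum) {
    df <- as.data.frame(stratum[[1]])
    df$term <- trimws(rownames(df))
    df
  }))
  get_row <- function(term) tab[tab$term == term, , drop = FALSE]
  res_between <- tab[tab$term == "Residuals", ][1, ]
  res_within <- tab[tab$term == "Residuals", ][2, ]
  effects <- list(
    list(name = between, term = "g", res = res_between),
    list(name = within, term = "w", res = res_within),
    list(name = paste0(between, ":", within), term = "g:w", res = res_within)
  )
  bf <- anova_bfs(d)
  out <- lapply(effects, function(e) {
    r <- get_row(e$term)
    Fv <- r$`F value`
    df1 <- r$Df
    df2 <- e$res$Df
    pv <- r$`Pr(>F)`
    if (is.nan(Fv) || r$`Sum Sq` < 1e-12) {
      # no effect variance (e.g. identical constant data): report F = 0
      Fv <- 0
      pv <- 1
    }
    tibble::tibble(
      effect = e$name, F = Fv, df_num = df1, df_den = df2,
      p = pv,
      eta_p2 = Fv * df1 / (Fv * df1 + df2),
      bf10_approx = bf[[e$term]]
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("vm_anova", class(out))
  out
}

# BIC-approximate Bayes factors for the three effects of the 2 x k mixed
# design, via model comparisons on participant summaries: between-group on
# participant means; within and interaction on within-participant contrasts
# (requires exactly two within levels, the designs used here).
anova_bfs <- function(d) {
  pm <- tapply(d$y, d$id, mean)
  gg <- tapply(as.character(d$g), d$id, `[`, 1)
  n <- length(pm)
  rss1 <- sum(stats::resid(stats::lm(pm ~ factor(gg)))^2)
  rss0 <- sum((pm - mean(pm))^2)
  bf_g <- bf10_approx(loglik_rss(rss0, n), loglik_rss(rss1, n), n,
                      k0 = 2, k1 = 3)
  lv <- levels(d$w)
  if (length(lv) != 2) {
    return(list(g = bf_g, w = NA_real_, `g:w` = NA_real_))
  }
  y1 <- d$y[d$w == lv[1]][order(d$id[d$w == lv[1]])]
  y2 <- d$y[d$w == lv[2]][order(d$id[d$w == lv[2]])]
  diff <- y2 - y1
  # within main effect: mean(diff) == 0 vs free mean
  rss_free <- sum((diff - mean(diff))^2)
  rss_zero <- sum(diff^2)
  bf_w <- bf10_approx(loglik_rss(rss_zero, n), loglik_rss(rss_free, n), n,
                      k0 = 1, k1 = 2)
  # interaction: group effect on the differences
  gd <- tapply(as.character(d$g), d$id, `[`, 1)
  rss_int1 <- sum(stats::resid(stats::lm(diff ~ factor(gd)))^2)
  bf_int <- bf10_approx(loglik_rss(rss_free, n), loglik_rss(rss_int1, n), n,
                        k0 = 2, k1 = 3)
  list(g = bf_g, w = bf_w, `g:w` = bf_int)
}

#' Between-group contrast of marginal means at a within-level
#'
#' Estimated marginal-mean difference between the two between-groups at one
#' level of the within factor, tested with a pooled-variance two-sample t
#' test on the cell values (df = n1 + n2 - 2) with a 95% confidence interval
#' and a BIC-approximate Bayes factor.
#'
#' @param data Long data frame as for [mixed_anova()].
#' @param at Within-level at which to compare the groups.
#' @param value,participant,between,within Column names.
#' @return Tibble of class `vm_contrast`: `estimate`, `ci_low`, `ci_high`,
#'   `t`, `df`, `p`, `bf10_approx`.
#' @export
emm_contrast <- function(data, at, value = "value",
                         participant = "participant",
                         between = "group", within = "period") {
  d <- data[data[[within]] == at, ]
  if (nrow(d) == 0) stop("unknown within-level: ", at)
  gl <- sort(unique(as.character(d[[between]])))
  stopifnot(length(gl) == 2)
  a <- d[[value]][d[[between]] == gl[1]]
  b <- d[[value]][d[[between]] == gl[2]]
  n1 <- length(a); n2 <- length(b)
  est <- mean(a) - mean(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tval <- if (se == 0) 0 else est / se
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(tval), df)
  ci <- est + c(-1, 1) * stats::qt(0.975, df) * se
  y <- c(a, b)
  g <- rep(gl, c(n1, n2))
  rss1 <- sum(stats::resid(stats::lm(y ~ factor(g)))^2)
  rss0 <- sum((y - mean(y))^2)
  bf <- bf10_approx(loglik_rss(rss0, n1 + n2), loglik_rss(rss1, n1 + n2),
                    n1 + n2, 2, 3)
  out <- tibble::tibble(
    contrast = paste(gl[1], "-", gl[2]), at = at,
    estimate = est, ci_low = ci[1], ci_high = ci[2],
    t = tval, df = df, p = p, bf10_approx = bf
  )
  class(out) <- c("vm_contrast", class(out))
  out
}

#' t tests with confidence intervals and approximate Bayes factors
#'
#' Paired or independent (Welch) two-tailed t test reporting the mean
#' difference, its 95% confidence interval, and a BIC-approximate Bayes
#' factor. Degenerate zero-variance inputs are guarded: the test is flagged
#' and p set to 1 when the difference is exactly constant at 0, or flagged
#' `degenerate` when constant non-zero.
#'
#' @param a,b Numeric samples (`b` may be omitted for a one-sample test
#'   against `mu`).
#' @param paired Logical.
#' @param mu Null value for one-sample tests.
#' @return Tibble of class `vm_contrast` with `estimate`, `ci_low`,
#'   `ci_high`, `t`, `df`, `p`, `bf10_approx`, `degenerate`.
#' @export
t_tests <- function(a, b = NULL, paired = FALSE, mu = 0) {
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    return(one_sample_t(d, 0))
  }
  if (is.null(b)) return(one_sample_t(a, mu))
  stopifnot(length(a) >= 2, length(b) >= 2)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  n <- length(a) + length(b)
  y <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  rss1 <- sum(stats::resid(stats::lm(y ~ factor(g)))^2)
  rss0 <- sum((y - mean(y))^2)
  bf <- bf10_approx(loglik_rss(rss0, n), loglik_rss(rss1, n), n, 2, 3)
  out <- tibble::tibble(
    contrast = "a - b", at = NA_character_,
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, bf10_approx = bf, degenerate = FALSE
  )
  class(out) <- c("vm_contrast", class(out))
  out
}

one_sample_t <- function(d, mu) {
  stopifnot(length(d) >= 2)
  n <- length(d)
  s <- stats::sd(d)
  est <- mean(d) - mu
  if (s == 0) {
    out <- tibble::tibble(
      contrast = "mean - mu", at = NA_character_,
      estimate = est, ci_low = est, ci_high = est,
      t = if (est == 0) 0 else Inf * sign(est),
      df = n - 1, p = if (est == 0) 1 else 0,
      bf10_approx = NA_real_, degenerate = est != 0
    )
    class(out) <- c("vm_contrast", class(out))
    return(out)
  }
  tt <- stats::t.test(d, mu = mu)
  rss1 <- sum((d - mean(d))^2)
  rss0 <- sum((d - mu)^2)
  bf <- bf10_approx(loglik_rss(rss0, n), loglik_rss(rss1, n), n, 1, 2)
  out <- tibble::tibble(
    contrast = "mean - mu", at = NA_character_,
    estimate = est,
    ci_low = tt$conf.int[1] - mu, ci_high = tt$conf.int[2] - mu,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, bf10_approx = bf, degenerate = FALSE
  )
  class(out) <- c("vm_contrast", class(out))
  out
}

#' Random-intercept mixed-effects regression over cycles
#'
#' Fits `value ~ cycle + (1 | participant)` by REML (lme4) with Satterthwaite
#' degrees of freedom (lmerTest), reporting slope and intercept with 95%
#' confidence intervals. The intercept can be tested against a reference
#' value (e.g. asymptotic learning) via `intercept_ref`, which is subtracted
#' from the response before fitting. If the random-intercept fit is singular
#' or inestimable, a fixed-effects fit is used and flagged.
#'
#' @param data Data frame with `participant`, `cycle`, `value` columns (names
#'   configurable).
#' @param value,participant,cycle Column names.
#' @param intercept_ref Numeric reference subtracted from the response.
#' @param center_cycle Value subtracted from `cycle` so the intercept refers
#'   to a meaningful cycle (default: first observed cycle).
#' @return Tibble of class `vm_mixedlm`: one row per coefficient with
#'   `term`, `beta`, `ci_low`, `ci_high`, `t`, `df`, `p`, `fallback`.
#' @export
mixed_lm <- function(data, value = "value", participant = "participant",
                     cycle = "cycle", intercept_ref = 0,
                     center_cycle = NULL) {
  d <- data.frame(
    y = data[[value]] - intercept_ref,
    id = factor(data[[participant]]),
    cyc = data[[cycle]]
  )
  if (is.null(center_cycle)) center_cycle <- min(d$cyc)
  d$cyc <- d$cyc - center_cycle
  fallback <- FALSE
  fit <- NULL
  if (nlevels(d$id) >= 2) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(y ~ cyc + (1 | id), data = d,
                                      REML = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
      # singular random effect: keep the fit but note it; estimates equal the
      # fixed-effects fit in this case
      fallback <- FALSE
    }
  }
  if (is.null(fit)) {
    fallback <- TRUE
    warning("random intercept inestimable; falling back to fixed effects")
    lmfit <- stats::lm(y ~ cyc, data = d)
    cf <- summary(lmfit)$coefficients
    df <- stats::df.residual(lmfit)
    out <- tibble::tibble(
      term = rownames(cf), beta = unname(cf[, 1]),
      ci_low = unname(cf[, 1] - stats::qt(0.975, df) * cf[, 2]),
      ci_high = unname(cf[, 1] + stats::qt(0.975, df) * cf[, 2]),
      t = unname(cf[, 3]), df = df, p = unname(cf[, 4]), fallback = TRUE
    )
    class(out) <- c("vm_mixedlm", class(out))
    return(out)
  }
  cf <- stats::coef(summary(fit)) # lmerTest: Satterthwaite df column
  est <- unname(cf[, "Estimate"])
  se <- unname(cf[, "Std. Error"])
  dfs <- unname(cf[, "df"])
  out <- tibble::tibble(
    term = rownames(cf), beta = est,
    ci_low = est - stats::qt(0.975, dfs) * se,
    ci_high = est + stats::qt(0.975, dfs) * se,
    t = unname(cf[, "t value"]), df = dfs, p = unname(cf[, "Pr(>|t|)"]),
    fallback = fallback
  )
  class(out) <- c("vm_mixedlm", class(out))
  out
}
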