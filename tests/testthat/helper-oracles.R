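# Independent brute-force oracle for the balanced two-factor mixed design
# (equal group sizes, every subject at every within-level): cell-mean
# sums-of-squares decomposition computed from first principles.
mixed_anova_oracle <- function(y, id, g, w) {
  id <- as.character(id); g <- as.character(g); w <- as.character(w)
  G <- sort(unique(g)); W <- sort(unique(w))
  k <- length(W)
  subj <- sort(unique(id))
  N <- length(subj)
  n_g <- table(vapply(subj, function(s) g[id == s][1], character(1)))
  stopifnot(length(unique(n_g)) == 1) # balanced groups only
  M <- mean(y)
  M_g <- tapply(y, g, mean)
  M_w <- tapply(y, w, mean)
  M_gw <- tapply(y, list(g, w), mean)
  S <- tapply(y, id, mean)
  g_of <- vapply(subj, function(s) g[id == s][1], character(1))
  n <- unname(n_g[1])
  SS_g <- k * n * sum((M_g - M)^2)
  SS_subj <- k * sum((S[subj] - M_g[g_of])^2)
  SS_w <- length(G) * n * sum((M_w - M)^2)
  int <- outer(seq_along(G), seq_along(W), Vectorize(function(i, j) {
    (M_gw[G[i], W[j]] - M_g[G[i]] - M_w[W[j]] + M)^2
  }))
  SS_gw <- n * sum(int)
  SS_err <- sum((y - M_gw[cbind(g, w)] - S[id] + M_g[g])^2)
  df_g <- length(G) - 1
  df_subj <- N - length(G)
  df_w <- k - 1
  df_gw <- df_g * df_w
  df_err <- df_subj * df_w
  list(
    F_g = (SS_g / df_g) / (SS_subj / df_subj),
    F_w = (SS_w / df_w) / (SS_err / df_err),
    F_gw = (SS_gw / df_gw) / (SS_err / df_err),
    df = c(g = df_g, subj = df_subj, w = df_w, gw = df_gw, err = df_err)
  )
}

# Minimal metrics-like table for aggregation tests.
make_metrics <- function(participant_id, block_label, hand_angle,
                         valid = TRUE, target_angle = 90, context = "point",
                         probe_flag = FALSE) {
  n <- length(hand_angle)
  tibble::tibble(
    participant_id = rep_len(participant_id, n),
    block_label = rep_len(block_label, n),
    trial_index = seq_len(n),
    attempt = 1L,
    context = rep_len(context, n),
    target_angle = rep_len(target_angle, n),
    rotation_deg = 0,
    probe_flag = rep_len(probe_flag, n),
    outcome = "hit",
    hand_angle_peak = hand_angle,
    valid = rep_len(valid, n)
  )
}
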