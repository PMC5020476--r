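# Independent oracles and small fixture builders used across tests.

# closed-form half-sine pulse on a constant baseline (continuous time)
oracle_half_sine <- function(t, onset, duration, peak, baseline) {
  u <- (t - onset) / duration
  ifelse(u > 0 & u < 1, baseline + (peak - baseline) * sin(pi * u), baseline)
}

# exact two-tailed Mann-Whitney p by enumerating all group labelings
oracle_mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# regular polygon approximating a circle
circle_poly <- function(r, n = 64L, center = c(0, 0)) {
  ang <- 2 * pi * (0:(n - 1L)) / n
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / abs(truth), tol)
}

# simulated four-location distensibility cohort with known effects
simulate_lme_cohort <- function(n_subj, beta_repair = -0.15, beta_mri = 0,
                                loc_effects = c(0, -1.2, -1.0, -0.9),
                                ri_sd = 1, res_sd = 1, seed = 1) {
  set.seed(seed)
  locs <- c("descending aorta at diaphragm", "aortic root",
            "ascending aorta", "isthmus")
  age_rep <- runif(n_subj, 0, 15)
  age_mri <- age_rep + runif(n_subj, 2, 25)
  b <- rnorm(n_subj, 0, ri_sd)
  df <- expand.grid(subject_id = seq_len(n_subj), loc = 1:4)
  df$location <- locs[df$loc]
  df$age_at_repair <- age_rep[df$subject_id]
  df$age_at_mri <- age_mri[df$subject_id]
  df$distensibility <- 8 + beta_repair * df$age_at_repair +
    beta_mri * df$age_at_mri + loc_effects[df$loc] + b[df$subject_id] +
    rnorm(nrow(df), 0, res_sd)
  df
}
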