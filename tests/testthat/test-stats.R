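test_that("Mann-Whitney agrees with full enumeration for small samples", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p, 1 / 3, tolerance = 1e-12)

  # all split sizes with n + m <= 10 on distinct values
  set.seed(99)
  pool <- sample(100, 10)
  for (n in 2:5) {
    for (m in 2:(10 - n)) {
      x <- pool[seq_len(n)]
      y <- pool[n + seq_len(m)]
      got <- mann_whitney(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p, oracle_mw_exact_p(x, y), tolerance = 1e-12,
                   label = sprintf("exact p at n=%d m=%d", n, m))
    }
  }

  # identical samples separate nothing
  expect_equal(mann_whitney(c(5, 6, 7), c(5, 6, 7))$p, 1, tolerance = 1e-9)
  # fully degenerate input is flagged
  dg <- mann_whitney(rep(3, 4), rep(3, 5))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  # ties or larger samples fall back to the corrected normal approximation
  expect_equal(mann_whitney(c(1, 2, 2), c(2, 3, 4))$method, "normal-approx")
})

test_that("Spearman correlation: sign, monotone invariance, t-approximation", {
  x <- c(1, 4, 9, 16, 30)
  expect_equal(spearman_rank(x, x^2)$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)

  set.seed(7)
  a <- rnorm(40); b <- a + rnorm(40)
  base <- spearman_rank(a, b)
  expect_equal(spearman_rank(exp(a), b)$rho, base$rho)
  expect_equal(spearman_rank(a, qlogis(plogis(b)))$rho, base$rho,
               tolerance = 1e-12)
  # rho matches the reference implementation; p is the documented t-approx
  expect_equal(base$rho, unname(cor(a, b, method = "spearman")))
  tval <- base$rho * sqrt((40 - 2) / (1 - base$rho^2))
  expect_equal(base$p, 2 * pt(-abs(tval), 38))

  expect_error(spearman_rank(rep(1, 5), 1:5), "rank variance")
  expect_error(spearman_rank(1:2, 2:1), "n >= 3")
})

test_that("simulated cohort reproduces the published age-at-repair association", {
  rhos <- vapply(1:20, function(s) {
    co <- make_cohort(cohort_spec(seed = 100 + s), materialize = FALSE)
    pat <- co$truth[co$subjects$group == "patient", ]
    spearman_rank(pat$age_repair_y, pat$pwv_dao_ms)$rho
  }, numeric(1))
  # n = 51 draws targeting rho 0.33
  expect_lt(abs(median(rhos) - 0.33), 0.15)
  expect_gt(mean(abs(rhos - 0.33) < 0.15), 0.6)
})

test_that("adult hypertension staging composes systolic and diastolic bands", {
  expect_equal(stage_hypertension_adult(120, 70), "normal")
  expect_equal(stage_hypertension_adult(145, 85), "stage1")
  expect_equal(stage_hypertension_adult(132, 95), "stage1")
  # the higher component stage wins
  expect_equal(stage_hypertension_adult(150, 102), "stage2")
  expect_equal(stage_hypertension_adult(165, 85), "stage2")
  expect_equal(stage_hypertension_adult(185, 70), "above-stage2")
  expect_equal(stage_hypertension_adult(120, 112), "above-stage2")
  # band edges
  expect_equal(stage_hypertension_adult(c(139, 140, 159, 160, 179, 180),
                                        rep(70, 6)),
               c("normal", "stage1", "stage1", "stage2", "stage2",
                 "above-stage2"))
})


test_that("mixed model with no between-subject variance matches OLS", {
  df <- simulate_lme_cohort(40, ri_sd = 0, seed = 3)
  fit <- fit_distensibility_lme(df)
  ols <- lm(distensibility ~ age_at_repair + age_at_mri +
              factor(location, levels = c("descending aorta at diaphragm",
                                          "isthmus", "ascending aorta",
                                          "aortic root")), data = df)
  b_lme <- coef(fit)
  b_ols <- coef(ols)
  # same design, same order after matching names by location text
  expect_equal(unname(b_lme["(Intercept)"]), unname(b_ols["(Intercept)"]),
               tolerance = 1e-6)
  expect_equal(unname(b_lme["age_at_repair"]), unname(b_ols["age_at_repair"]),
               tolerance = 1e-6)
  expect_equal(unname(b_lme["age_at_mri"]), unname(b_ols["age_at_mri"]),
               tolerance = 1e-6)
  expect_equal(sort(unname(b_lme[grep("location", names(b_lme))])),
               sort(unname(b_ols[grep("location", names(b_ols))])),
               tolerance = 1e-6)
  expect_lt(fit$random_intercept_sd, 0.2)
})

test_that("mixed model recovers known fixed effects with a random intercept", {
  df <- simulate_lme_cohort(60, beta_repair = -0.15, ri_sd = 1, res_sd = 1,
                            seed = 5)
  fit <- fit_distensibility_lme(df)
  fe <- fit$fixed_effects
  est <- fe$estimate[fe$term == "age_at_repair"]
  se <- fe$std_error[fe$term == "age_at_repair"]
  expect_lt(abs(est - (-0.15)), 3 * se)
  # the reference level is the descending aorta: its name never appears
  expect_false(any(grepl("descending", fe$term)))
  expect_true(all(c("locationaortic root", "locationascending aorta",
                    "locationisthmus") %in% fe$term))
  expect_gt(fit$random_intercept_sd, 0.5)
  expect_lt(fit$random_intercept_sd, 1.6)
})

test_that("mixed model fit is a local optimum of its objective", {
  df <- simulate_lme_cohort(30, seed = 11)
  fit <- fit_distensibility_lme(df, reml = FALSE)
  # profiled deviance as a function of theta (random-intercept sd / sigma)
  dev_fun <- update(fit$fit, devFunOnly = TRUE)
  theta_opt <- lme4::getME(fit$fit, "theta")
  at_opt <- dev_fun(theta_opt)
  set.seed(2)
  worse <- vapply(1:100, function(i) {
    dev_fun(abs(theta_opt * (1 + rnorm(1, 0, 0.3)) + 1e-3)) >= at_opt - 1e-8
  }, logical(1))
  expect_true(all(worse))
})

test_that("mixed model guards degenerate designs", {
  df <- simulate_lme_cohort(20, seed = 4)
  one_loc <- df[df$location == "isthmus", ]
  expect_error(fit_distensibility_lme(one_loc), "singular|one measurement")
  dup <- rbind(df, df[1, ])
  expect_error(fit_distensibility_lme(dup), "more than once")
  df_bad <- df; df_bad$location[1] <- "abdominal aorta"
  expect_error(fit_distensibility_lme(df_bad), "unknown location")
})
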