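test_that("REML matches the closed-form ANOVA estimators on balanced one-way data", {
  set.seed(1)
  m <- 5; ng <- 30
  g <- factor(rep(seq_len(ng), each = m))
  y <- 1.5 + rnorm(ng, 0, 2)[as.integer(g)] + rnorm(ng * m, 0, 1.3)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list(grp = list(Z = matrix(1, length(y), 1,
                                       dimnames = list(NULL, "(intercept)")),
                            group = g))
  fit <- reml_fit(y, X, blocks, cluster = g)

  gm <- tapply(y, g, mean)
  MSB <- m * sum((gm - mean(y))^2) / (ng - 1)
  MSW <- sum((y - gm[as.integer(g)])^2) / (ng * (m - 1))
  expect_equal(fit$vc$grp[1, 1], (MSB - MSW) / m, tolerance = 1e-6)
  expect_equal(unname(fit$vc$residual_var), MSW, tolerance = 1e-6)
  expect_equal(unname(fit$beta), mean(y), tolerance = 1e-10)
})

test_that("with zero planted random variances REML reduces to OLS", {
  set.seed(2)
  n <- 400
  g <- factor(rep(seq_len(100), each = 4))
  x <- rnorm(n)
  y <- 0.5 + 0.8 * x + rnorm(n, 0, 1.2)
  X <- cbind(`(Intercept)` = 1, x = x)
  blocks <- list(grp = list(Z = matrix(1, n, 1), group = g))
  fit <- reml_fit(y, X, blocks, cluster = g)
  ols <- stats::lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 0.02)
  # residual variance near the planted 1.2^2; the spurious group variance is
  # small (its REML sampling error at 100 groups of 4 is ~0.1)
  expect_equal(unname(fit$vc$residual_var), 1.2^2, tolerance = 0.15)
  expect_lt(fit$vc$grp[1, 1], 0.15)
})

test_that("Satterthwaite df recovers the classical and Welch formulas", {
  set.seed(3)
  y <- rnorm(25)
  X <- matrix(1, 25, 1, dimnames = list(NULL, "mu"))
  fit <- reml_fit(y, X, list(), cluster = factor(seq_len(25)))
  expect_equal(satterthwaite_df(fit, 1), 24, tolerance = 1e-6)

  set.seed(7)
  yA <- rnorm(14, 0, 1); yB <- rnorm(9, 1, 2.5)
  yy <- c(yA, yB); grp <- factor(rep(c("A", "B"), c(14, 9)))
  X2 <- cbind(`(Intercept)` = 1, d = as.numeric(grp == "B"))
  fit2 <- reml_fit(yy, X2, list(), cluster = factor(seq_along(yy)),
                   resid_strata = grp)
  vA <- var(yA); vB <- var(yB)
  welch <- (vA / 14 + vB / 9)^2 / ((vA / 14)^2 / 13 + (vB / 9)^2 / 8)
  expect_equal(satterthwaite_df(fit2, c(0, 1)), welch, tolerance = 1e-4)
  # REML per-stratum variances are the sample variances
  expect_equal(unname(fit2$vc$residual_var), c(vA, vB), tolerance = 1e-5)

  # homogeneity of degree zero in the contrast
  expect_equal(satterthwaite_df(fit2, c(0, 1)),
               satterthwaite_df(fit2, c(0, 17.3)), tolerance = 1e-10)
})

test_that("the analytic REML gradient matches central differences", {
  tab <- small_trials(5)
  th <- tab[tab$modality == "thermal", ]
  enc <- encode_design(th, "intensity_z")
  des <- placebotwin:::compile_reml_design(enc$y, enc$X, enc$blocks, enc$cluster)
  set.seed(5)
  for (r in 1:3) {
    theta <- rnorm(19, -0.5, 0.4)
    vg <- placebotwin:::neg2_reml_with_grad(theta, des)
    expect_equal(vg$value, placebotwin:::neg2_reml(theta, des), tolerance = 1e-10)
    ng <- placebotwin:::numeric_grad(
      function(t) placebotwin:::neg2_reml(t, des), theta, h = 1e-6)
    expect_equal(vg$grad, ng, tolerance = 1e-4)
  }
})

test_that("pooled fast path and dense path agree on the same criterion", {
  tab <- small_trials(6, mz = 8L, dz = 8L, single = 4L)
  th <- tab[tab$modality == "thermal", ]
  enc <- encode_design(th, "intensity_z")
  des_fast <- placebotwin:::compile_reml_design(enc$y, enc$X, enc$blocks, enc$cluster)
  # forcing one residual stratum per observation group uses the dense path
  des_dense <- placebotwin:::compile_reml_design(enc$y, enc$X, enc$blocks,
                                                 enc$cluster,
                                                 resid_strata = factor(rep("all", length(enc$y))))
  set.seed(6)
  theta <- rnorm(19, -0.6, 0.3)
  expect_equal(placebotwin:::neg2_reml(theta, des_fast),
               placebotwin:::neg2_reml(theta, des_dense), tolerance = 1e-8)
})

test_that("twin fits match an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  co <- generate_cohort(cohort_spec(80, 0, 0, seed = 9))
  tab <- simulate_trial_table(co, seed = 9)
  th <- tab[tab$modality == "thermal", ]
  fit <- fit_twin_lmm(th, "intensity_z")
  lf <- lme4::lmer(
    intensity_z ~ level_code + condition_code +
      (1 + level_code + condition_code | family_id) +
      (1 + level_code + condition_code | participant_id),
    data = th, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                optCtrl = list(maxfun = 1e5),
                                check.conv.singular = "ignore"))
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(lf))))),
               tolerance = 1e-4)
})

test_that("the restricted likelihood is invariant to relabeling and shifts", {
  tab <- small_trials(19, mz = 10L, dz = 10L, single = 5L)
  th <- tab[tab$modality == "thermal", ]
  fit <- fit_twin_lmm(th, "intensity_z", control = reml_control(n_starts = 1))

  # relabel families (permute ids)
  th2 <- th
  fams <- unique(th$family_id)
  relab <- setNames(sample(fams), fams)
  th2$family_id <- unname(relab[th$family_id])
  fit2 <- fit_twin_lmm(th2, "intensity_z", control = reml_control(n_starts = 1))
  expect_equal(fit2$reml_loglik, fit$reml_loglik, tolerance = 1e-6)
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-6)

  # adding a constant shifts only the intercept
  th3 <- th; th3$intensity_z <- th3$intensity_z + 5
  fit3 <- fit_twin_lmm(th3, "intensity_z", control = reml_control(n_starts = 1))
  expect_equal(fit3$reml_loglik, fit$reml_loglik, tolerance = 1e-6)
  expect_equal(unname(fit3$beta["(Intercept)"] - fit$beta["(Intercept)"]), 5,
               tolerance = 1e-6)
  expect_equal(unname(fit3$beta[-1]), unname(fit$beta[-1]), tolerance = 1e-6)
})
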