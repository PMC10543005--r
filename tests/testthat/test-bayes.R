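test_that("the exact marginal matches numerical integration over the variance", {
  set.seed(26)
  y <- rnorm(12, 0.4, 1.3)
  N <- length(y)
  # intercept-only model: package closed form vs direct 1-D quadrature of
  # integral over sigma^2 (flat mean integrated analytically in both)
  ml <- marginal_likelihood_mc(y, list(), intercept = TRUE)
  R <- sum((y - mean(y))^2)
  oracle <- log(stats::integrate(function(s2)
    (2 * pi * s2)^(-(N - 1) / 2) * N^(-1 / 2) * exp(-R / (2 * s2)) / s2,
    0, Inf, rel.tol = 1e-12)$value)
  expect_equal(ml$logml, oracle, tolerance = 1e-6)
  expect_equal(ml$rel_se, 0)
})

test_that("the one-sample reduction matches the JZS quadrature oracle", {
  for (N in c(20, 50)) for (tt in c(0, 1, 2, 4)) {
    y <- y_with_t(tt, N, seed = 100 + N + tt)
    t_obs <- sqrt(N) * mean(y) / stats::sd(y)
    full <- marginal_likelihood_mc(y, list(effect = list(X = matrix(1, N, 1),
                                                         rscale = 1)),
                                   n_mc = 4000, seed = 5, intercept = FALSE)
    null <- marginal_likelihood_mc(y, list(), intercept = FALSE)
    bf <- exp(full$logml - null$logml)
    oracle <- jzs_onesample_bf(t_obs, N)
    tol <- 3 * sqrt(full$rel_se^2 + null$rel_se^2)
    expect_lt(abs(bf - oracle) / oracle, tol + 1e-6)
  }
})

test_that("a degenerate full-equals-null request gives bf10 = 1 exactly", {
  tab <- small_trials(27)
  th <- tab[tab$modality == "thermal", ]
  r <- bf_fixed_effect(th, "intensity_z", effect = character(0),
                       other_effects = c("stimulus_level", "condition"),
                       n_mc = 100, seed = 1)
  expect_identical(r$bf10, 1)
  expect_identical(r$proportional_error, 0)
})

test_that("Monte Carlo error shrinks like one over root n_mc", {
  set.seed(28)
  y <- rnorm(40) + 0.3
  grp <- list(effect = list(X = matrix(1, 40, 1), rscale = 1))
  ml_small <- vapply(1:24, function(s)
    marginal_likelihood_mc(y, grp, n_mc = 250, seed = s,
                           intercept = FALSE)$logml, numeric(1))
  ml_big <- vapply(1:24, function(s)
    marginal_likelihood_mc(y, grp, n_mc = 1000, seed = 1000 + s,
                           intercept = FALSE)$logml, numeric(1))
  ratio <- stats::sd(ml_small) / stats::sd(ml_big)
  expect_gt(ratio, 1.2)   # expect about 2 with wide Monte Carlo tolerance
  expect_lt(ratio, 3.4)
})

test_that("the log marginal is invariant to observation order", {
  set.seed(29)
  y <- rnorm(30, 0.2)
  X <- cbind(rnorm(30))
  grp <- function(yy, XX) list(e = list(X = XX, rscale = 1))
  perm <- sample(30)
  m1 <- marginal_likelihood_mc(y, grp(y, X), n_mc = 500, seed = 3)
  m2 <- marginal_likelihood_mc(y[perm], grp(y, X[perm, , drop = FALSE]),
                               n_mc = 500, seed = 3)
  expect_equal(m1$logml, m2$logml, tolerance = 1e-8)
})

test_that("Bayes factors are reciprocal and transitive through a common model", {
  set.seed(30)
  y <- rnorm(40) + 0.4
  gA <- list(e = list(X = matrix(1, 40, 1), rscale = 1))
  gB <- list(e = list(X = matrix(1, 40, 1), rscale = sqrt(2)))
  mlA1 <- marginal_likelihood_mc(y, gA, n_mc = 3000, seed = 1, intercept = FALSE)
  mlA2 <- marginal_likelihood_mc(y, gA, n_mc = 3000, seed = 2, intercept = FALSE)
  mlB1 <- marginal_likelihood_mc(y, gB, n_mc = 3000, seed = 3, intercept = FALSE)
  mlB2 <- marginal_likelihood_mc(y, gB, n_mc = 3000, seed = 4, intercept = FALSE)
  mlC <- marginal_likelihood_mc(y, list(), intercept = FALSE)
  # reciprocity with independent draws
  prod_recip <- exp(mlA1$logml - mlB1$logml) * exp(mlB2$logml - mlA2$logml)
  tol <- 3 * sqrt(sum(c(mlA1$rel_se, mlA2$rel_se, mlB1$rel_se, mlB2$rel_se)^2))
  expect_lt(abs(prod_recip - 1), tol)
  # transitivity through the null
  bf_AC <- exp(mlA1$logml - mlC$logml)
  bf_AB_BC <- exp(mlA2$logml - mlB1$logml) * exp(mlB2$logml - mlC$logml)
  expect_lt(abs(bf_AC / bf_AB_BC - 1), tol)
})

test_that("under a true null the BF is non-increasing in the prior scale", {
  # verified against the quadrature oracle in the one-sample reduction
  rscales <- c(sqrt(2) / 2, 1, sqrt(2))
  oracle <- vapply(rscales, function(r) jzs_onesample_bf(0.3, 40, r), numeric(1))
  expect_true(all(diff(oracle) < 0))
  y <- y_with_t(0.3, 40, seed = 31)
  bfs <- vapply(seq_along(rscales), function(i) {
    full <- marginal_likelihood_mc(y, list(e = list(X = matrix(1, 40, 1),
                                                    rscale = rscales[i])),
                                   n_mc = 4000, seed = 40 + i, intercept = FALSE)
    null <- marginal_likelihood_mc(y, list(), intercept = FALSE)
    exp(full$logml - null$logml)
  }, numeric(1))
  expect_equal(bfs, oracle, tolerance = 0.05)
})

test_that("evidence labels and odds strings follow the conventional bands", {
  r1 <- interpret_bf(0.044)
  expect_equal(r1$odds, "23:1 odds in favor of the null")
  expect_equal(r1$label, "strong evidence for null")
  r2 <- interpret_bf(0.036)
  expect_equal(r2$odds, "28:1 odds in favor of the null")
  r3 <- interpret_bf(1)
  expect_equal(r3$odds, "1:1")
  expect_equal(r3$label, "no evidence")
  expect_equal(interpret_bf(93.92)$label, "very strong evidence for alternative")
  expect_equal(interpret_bf(150)$label, "extreme evidence for alternative")
  expect_equal(interpret_bf(0.2)$label, "moderate evidence for null")
  expect_error(interpret_bf(-1), "positive")
})

test_that("the robustness scan covers the full prior-by-interaction grid", {
  tab <- small_trials(32, mz = 8L, dz = 8L, single = 4L)
  th <- tab[tab$modality == "thermal", ]
  grid <- bf_robustness(th, "intensity_z", n_mc = 400, seed = 2)
  expect_equal(nrow(grid), 6)
  expect_equal(sort(unique(grid$rscale)), sort(c(sqrt(2) / 2, 1, sqrt(2))))
  expect_setequal(unique(grid$interaction), c(TRUE, FALSE))
  expect_true(is.logical(attr(grid, "robust_null")))
  # a strongly planted placebo effect is detected in every cell
  expect_true(attr(grid, "robust_alternative"))
})

test_that("Bayes factors separate planted effects from planted nulls", {
  eff_null <- list(thermal = effect_spec(0, 0.409, 0, 0),
                   mechanical = effect_spec(0, 0.202, 0, 0))
  bf_eff <- vapply(1:3, function(r) {
    tab <- simulate_trial_table(small_cohort(300 + r), seed = 300 + r)
    th <- tab[tab$modality == "thermal", ]
    bf_fixed_effect(th, "intensity_z", n_mc = 1000, seed = r)$bf10
  }, numeric(1))
  bf_null <- vapply(1:3, function(r) {
    tab <- simulate_trial_table(small_cohort(400 + r), eff_null, seed = 400 + r)
    th <- tab[tab$modality == "thermal", ]
    bf_fixed_effect(th, "intensity_z", n_mc = 1000, seed = r)$bf10
  }, numeric(1))
  expect_gt(stats::median(bf_eff), 10)
  expect_lt(stats::median(bf_null), 1 / 3)
})
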