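test_that("cohort generation groups twins into families", {
  co <- generate_cohort(cohort_spec(142, 160, 93))
  expect_equal(nrow(co), 395)
  sizes <- table(co$family_id)
  zyg_by_fam <- tapply(co$zygosity, co$family_id, function(z) z[1])
  expect_equal(sum(zyg_by_fam == "MZ"), 71)
  expect_equal(sum(zyg_by_fam == "DZ"), 80)
  expect_equal(sum(zyg_by_fam == "singleton"), 93)
  expect_true(all(sizes[zyg_by_fam != "singleton"] == 2))
  expect_true(all(sizes[zyg_by_fam == "singleton"] == 1))
  expect_false(anyDuplicated(co$participant_id) > 0)

  expect_equal(nrow(generate_cohort(cohort_spec(0, 0, 0))), 0)

  co2 <- generate_cohort(cohort_spec(4, 2, 1))
  expect_equal(nrow(co2), 7)
  expect_equal(length(unique(co2$family_id)), 4)
  expect_equal(sort(as.integer(table(co2$family_id))), c(1, 2, 2, 2))

  expect_error(cohort_spec(3, 2, 1), "even")
  expect_error(cohort_spec(2, 5, 1), "even")
})

test_that("noise-free simulation reproduces the linear predictor at every cell", {
  vc0 <- variance_components(family_cov = matrix(0, 3, 3),
                             sd_individual_mz = c(0, 0, 0),
                             sd_individual_dz = c(0, 0, 0), sd_residual = 0)
  eff <- list(thermal = effect_spec(0.1, 0.409, -0.359, 0.2),
              mechanical = effect_spec(-0.1, 0.202, -0.244, 0))
  tab <- simulate_trial_table(small_cohort(2), eff, vc0, seed = 2)
  lp <- with(tab, ifelse(modality == "thermal",
    0.1 + 0.409 * level_code - 0.359 * condition_code + 0.2 * level_code * condition_code,
    -0.1 + 0.202 * level_code - 0.244 * condition_code))
  expect_equal(tab$intensity_z, lp, tolerance = 1e-12)
})

test_that("trial tables respect the run structure and rating bounds", {
  tab <- small_trials(4)
  expect_equal(nrow(tab), 56 * 32)
  expect_true(all(tab$condition[tab$run %in% c(1, 4)] == "control"))
  expect_true(all(tab$condition[tab$run %in% c(2, 3)] == "placebo"))
  per_run <- table(tab$participant_id, tab$run)
  expect_true(all(per_run == 8))
  mod_counts <- tapply(tab$modality, interaction(tab$participant_id, tab$run),
                       function(m) sum(m == "thermal"))
  expect_true(all(mod_counts == 4))
  expect_true(all(tab$intensity_rating >= 0 & tab$intensity_rating <= 1))
  expect_true(all(tab$unpleasantness_rating >= 0 & tab$unpleasantness_rating <= 1))
  expect_true(is.numeric(attr(tab, "clip_fraction")))
  # three stimulus levels within every modality x condition cell
  lev_counts <- tapply(tab$stimulus_level,
                       interaction(tab$participant_id, tab$modality, tab$condition),
                       function(l) length(unique(l)))
  expect_true(all(lev_counts == 3))
})

test_that("same seed gives bit-identical tables and volumes", {
  expect_identical(small_trials(11), small_trials(11))
  expect_false(identical(small_trials(11)$intensity_z, small_trials(12)$intensity_z))
  s1 <- make_synthetic_signature(seed = 5)
  s2 <- make_synthetic_signature(seed = 5)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$subregions, s2$subregions)
})

test_that("within-pair correlation is higher for MZ than DZ pairs", {
  co <- generate_cohort(cohort_spec(600, 600, 0, seed = 21))
  tab <- simulate_trial_table(co, seed = 21)
  pm <- tapply(tab$intensity_z[tab$modality == "thermal"],
               tab$participant_id[tab$modality == "thermal"], mean)
  co$mean_z <- pm[co$participant_id]
  pair_cor <- function(zyg) {
    d <- co[co$zygosity == zyg, ]
    w <- matrix(d$mean_z[order(d$family_id)], nrow = 2)
    stats::cor(w[1, ], w[2, ])
  }
  r_mz <- pair_cor("MZ"); r_dz <- pair_cor("DZ")
  expect_gt(r_mz, r_dz)
  expect_gt(r_mz, 0.3)
})

test_that("within-family correlation decreases with individual-level variance", {
  rs <- vapply(c(0.2, 0.6, 1.2), function(s) {
    vc <- variance_components(sd_individual_mz = rep(s, 3),
                              sd_individual_dz = rep(s, 3))
    co <- generate_cohort(cohort_spec(400, 0, 0, seed = 31))
    tab <- simulate_trial_table(co, vc = vc, seed = 31)
    pm <- tapply(tab$intensity_z, tab$participant_id, mean)
    w <- matrix(pm[co$participant_id[order(co$family_id)]], nrow = 2)
    stats::cor(w[1, ], w[2, ])
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("planted placebo effect is recovered in the empirical condition contrast", {
  co <- generate_cohort(cohort_spec(400, 400, 0, seed = 41))
  tab <- simulate_trial_table(co, seed = 41)
  th <- tab[tab$modality == "thermal", ]
  diff_hat <- mean(th$intensity_z[th$condition == "placebo"]) -
    mean(th$intensity_z[th$condition == "control"])
  # placebo-minus-control equals beta_placebo (codes +-0.5); the Monte Carlo
  # error of the mean over 800 participants' random placebo slopes is ~0.01
  expect_lt(abs(diff_hat - (-0.359)), 0.04)
})

test_that("singletons carry no individual-level draw", {
  vc <- variance_components(family_cov = matrix(0, 3, 3),
                            sd_individual_mz = c(1, 1, 1),
                            sd_individual_dz = c(1, 1, 1), sd_residual = 0)
  co <- generate_cohort(cohort_spec(4, 4, 5, seed = 6))
  tab <- simulate_trial_table(co, vc = vc, seed = 6)
  singles <- tab[tab$zygosity == "singleton" & tab$modality == "thermal", ]
  lp <- 0.409 * singles$level_code - 0.359 * singles$condition_code
  expect_equal(singles$intensity_z, lp, tolerance = 1e-12)
  twins <- tab[tab$zygosity == "MZ" & tab$modality == "thermal", ]
  expect_gt(stats::sd(twins$intensity_z - (0.409 * twins$level_code -
                                           0.359 * twins$condition_code)), 0.1)
})

test_that("generator validates its variance components", {
  bad <- diag(c(1, 1, 1)); bad[1, 2] <- bad[2, 1] <- 5  # not PSD
  expect_error(variance_components(family_cov = bad), "semidefinite")
  expect_error(simulate_trial_table(small_cohort(1), vc = list()), "variance_components")
})

test_that("synthetic signatures have disjoint signed subregions", {
  sig <- make_synthetic_signature(c(16, 16, 16), 2, 6, seed = 3)
  expect_equal(nrow(sig$legend), 8)
  expect_equal(sig$legend$sign, c(1L, 1L, rep(-1L, 6)))
  for (l in sig$legend$label) {
    w <- sig$weights[sig$subregions == l]
    expect_gt(sum(abs(w)), 0)
    expect_true(all(sign(w) == sig$legend$sign[l]))
  }
  expect_true(all((sig$subregions > 0) == sig$mask))
  expect_error(make_synthetic_signature(c(8, 8, 8), 10, 10, seed = 1), "disjoint")
  expect_error(make_synthetic_signature(c(6, 6, 6), 1, 1), "dimension")
})

test_that("contrast maps plant recoverable signature scores", {
  sig <- tiny_signature()
  maps0 <- simulate_contrast_maps(data.frame(target = c(2.5, 0, -1.2)), sig,
                                  noise_sd = 0, seed = 1)
  scores0 <- vapply(maps0, function(m) as.numeric(signature_score(m, sig)),
                    numeric(1))
  expect_equal(unname(scores0), c(2.5, 0, -1.2), tolerance = 1e-6)

  # with noise the dot product is unbiased for the target
  reps <- vapply(1:200, function(r) {
    m <- simulate_contrast_maps(data.frame(target = 1.5), sig,
                                noise_sd = 0.3, seed = r)[[1]]
    as.numeric(signature_score(m, sig))
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1.5), 3 * se)
})
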