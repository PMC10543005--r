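test_that("participant contrasts are z-scored and ranked as specified", {
  tab <- small_trials(33)
  pc <- participant_contrasts(tab)
  for (mod in c("thermal", "mechanical")) {
    v <- pc$behavioral_analgesia[pc$modality == mod]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(stats::sd(v) - 1), 1e-10)
  }
  # ranks are a permutation of 1..k within each modality x level cell
  cells <- split(pc$behavioral_analgesia_rank,
                 interaction(pc$modality, pc$stimulus_level))
  for (cl in cells) expect_equal(sort(cl), seq_along(cl))

  # hand computation: two participants with raw differences 0.1 and 0.3
  # z-score to -0.707 / +0.707
  expect_equal(as.numeric(scale(c(0.1, 0.3))), c(-1, 1) / sqrt(2),
               tolerance = 1e-10)
  # rank definition
  expect_equal(rank(c(5, 1, 3)), c(3, 1, 2))
})

test_that("degenerate equal conditions surface a constant-column error", {
  vc0 <- variance_components(matrix(0, 3, 3), c(0, 0, 0), c(0, 0, 0), 0)
  eff0 <- effect_spec(0, 0.4, 0, 0)  # no placebo effect, no noise
  tab <- simulate_trial_table(small_cohort(34), eff0, vc0, seed = 34)
  expect_error(participant_contrasts(tab), "constant")
})

mk_contrasts <- function(n_fam = 40, seed = 1, slope = 1, noise = 1e-6,
                         indep = FALSE) {
  co <- generate_cohort(cohort_spec(2 * ceiling(n_fam / 2), 2 * floor(n_fam / 2),
                                    6, seed = seed))
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
    data.frame(participant_id = co$participant_id[i],
               family_id = co$family_id[i], zygosity = co$zygosity[i],
               modality = rep(c("thermal", "mechanical"), each = 3),
               stimulus_level = rep(c("low", "medium", "high"), 2),
               stringsAsFactors = FALSE)
  }))
  rows$behavioral_analgesia <- rnorm(nrow(rows))
  neural <- if (indep) rnorm(nrow(rows)) else
    slope * rows$behavioral_analgesia + rnorm(nrow(rows), 0, noise)
  rows$neural_reduction <- neural
  rows$behavioral_analgesia_rank <- stats::ave(
    rows$behavioral_analgesia,
    interaction(rows$modality, rows$stimulus_level), FUN = rank)
  rows$neural_reduction_rank <- stats::ave(
    rows$neural_reduction,
    interaction(rows$modality, rows$stimulus_level), FUN = rank)
  rows
}

test_that("a noise-free plant recovers a unit brain-behavior slope", {
  pc <- mk_contrasts(slope = 1, noise = 1e-6, seed = 35)
  est <- brain_behavior_model(pc, "neural_reduction", "thermal",
                              control = reml_control(n_starts = 1))
  expect_equal(est$estimate, 1, tolerance = 1e-4)
})

test_that("rank-based slopes are invariant to monotone transforms", {
  pc <- mk_contrasts(slope = 0.6, noise = 0.5, seed = 36)
  r1 <- brain_behavior_model(pc, "neural_reduction", "thermal",
                             rank_based = TRUE,
                             control = reml_control(n_starts = 1))
  # strictly monotone transform of both raw variables, ranks recomputed
  pc2 <- pc
  pc2$behavioral_analgesia <- exp(pc$behavioral_analgesia)
  pc2$neural_reduction <- pc$neural_reduction^3
  pc2$behavioral_analgesia_rank <- stats::ave(
    pc2$behavioral_analgesia,
    interaction(pc2$modality, pc2$stimulus_level), FUN = rank)
  pc2$neural_reduction_rank <- stats::ave(
    pc2$neural_reduction,
    interaction(pc2$modality, pc2$stimulus_level), FUN = rank)
  r2 <- brain_behavior_model(pc2, "neural_reduction", "thermal",
                             rank_based = TRUE,
                             control = reml_control(n_starts = 1))
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  # z-scored and rank slopes agree in sign on a strongly planted effect
  rz <- brain_behavior_model(pc, "neural_reduction", "thermal",
                             control = reml_control(n_starts = 1))
  expect_equal(sign(rz$estimate), sign(r1$estimate))
})

test_that("planted brain-behavior slopes are recovered without bias", {
  ests <- vapply(1:20, function(r) {
    pc <- mk_contrasts(n_fam = 40, seed = 500 + r, slope = 0.2, noise = 1)
    brain_behavior_model(pc, "neural_reduction", "thermal",
                         control = reml_control(n_starts = 1))$estimate
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.2), 3 * se + 0.005)

  # independent plant: slope near zero
  ests0 <- vapply(1:20, function(r) {
    pc <- mk_contrasts(n_fam = 40, seed = 600 + r, indep = TRUE)
    brain_behavior_model(pc, "neural_reduction", "thermal",
                         control = reml_control(n_starts = 1))$estimate
  }, numeric(1))
  se0 <- stats::sd(ests0) / sqrt(length(ests0))
  expect_lt(abs(mean(ests0)), 3 * se0 + 0.005)
})

test_that("expectation models validate inputs and recover planted slopes", {
  pc <- mk_contrasts(seed = 37)
  const <- data.frame(participant_id = unique(pc$participant_id),
                      expected_efficacy = 50)
  expect_error(expectation_model(pc, const), "constant")

  ids <- unique(pc$participant_id)
  set.seed(37)
  ex <- data.frame(participant_id = ids,
                   expected_efficacy = pmin(pmax(rnorm(length(ids), 50, 15), 0), 100))
  exz <- (ex$expected_efficacy - mean(ex$expected_efficacy)) /
    stats::sd(ex$expected_efficacy)
  pc$behavioral_analgesia <- 0.107 * exz[match(pc$participant_id, ids)] +
    rnorm(nrow(pc), 0, 0.3)
  est <- expectation_model(pc, ex, control = reml_control(n_starts = 1))
  expect_lt(abs(est$estimate - 0.107), 0.1)
  expect_equal(est$term, "expected_efficacy_z")

  # shuffled expectations kill the association
  ex_shuf <- ex; ex_shuf$expected_efficacy <- sample(ex$expected_efficacy)
  est0 <- expectation_model(pc, ex_shuf, control = reml_control(n_starts = 1))
  expect_lt(abs(est0$estimate), 0.15)
})

test_that("transfer models link the two modalities through participants", {
  pc <- mk_contrasts(seed = 38)
  # mechanical contrast = thermal contrast exactly
  ther <- pc[pc$modality == "thermal", ]
  mech <- ther; mech$modality <- "mechanical"
  both <- rbind(ther, mech)
  both$behavioral_analgesia <- both$behavioral_analgesia +
    rnorm(nrow(both), 0, 1e-6)
  est <- transfer_model(both, control = reml_control(n_starts = 1))
  expect_equal(est$estimate, 1, tolerance = 1e-3)

  # independent modalities: slope near zero
  ests0 <- vapply(1:10, function(r) {
    pci <- mk_contrasts(seed = 700 + r, indep = TRUE)
    transfer_model(pci, control = reml_control(n_starts = 1))$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests0)), 3 * stats::sd(ests0) / sqrt(10) + 0.01)
})
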