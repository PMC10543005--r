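# shared fixtures, all generated in code

small_cohort <- function(seed = 1L, mz = 20L, dz = 24L, single = 12L) {
  generate_cohort(cohort_spec(mz, dz, single, seed = seed))
}

small_trials <- function(seed = 1L, mz = 20L, dz = 24L, single = 12L, ...) {
  simulate_trial_table(small_cohort(seed, mz, dz, single), seed = seed, ...)
}

# deterministic 6x6x6 signature fixture with 1 positive + 1 negative subregion
tiny_signature <- function(seed = 7L) {
  make_synthetic_signature(grid_dims = c(8, 8, 8), n_pos_subregions = 1,
                           n_neg_subregions = 1, seed = seed,
                           subregion_size = 2)
}

# closed-form JZS one-sample Bayes factor (quadrature oracle)
jzs_onesample_bf <- function(t, N, r = 1) {
  nu <- N - 1
  num <- stats::integrate(function(g)
    (1 + N * g)^(-1 / 2) * (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) *
      (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g)),
    0, Inf, rel.tol = 1e-10)$value
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# sample of size N with exactly the requested one-sample t statistic
y_with_t <- function(t, N, seed = 1) {
  z <- with_seed_local(seed, stats::rnorm(N))
  z <- drop(scale(z))
  z + t / sqrt(N)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
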