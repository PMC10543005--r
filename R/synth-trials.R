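#' Fixed-effect specification for the trial generator
#'
#' Effects are on the z-scored outcome scale with the centered design coding
#' (stimulus level -0.5/0/+0.5, control/placebo -0.5/+0.5), so
#' `beta_placebo = -0.359` plants the study-scale thermal rating effect.
#'
#' @param beta_intercept,beta_intensity,beta_placebo,beta_interaction fixed
#'   effects on the z scale.
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(beta_intercept = 0, beta_intensity = 0.409,
                        beta_placebo = -0.359, beta_interaction = 0) {
  b <- c(beta_intercept, beta_intensity, beta_placebo, beta_interaction)
  stop_if_not(all(is.finite(b)), "effects must be finite")
  structure(list(beta_intercept = beta_intercept,
                 beta_intensity = beta_intensity,
                 beta_placebo = beta_placebo,
                 beta_interaction = beta_interaction),
            class = "effect_spec")
}

#' Default per-modality effects
#'
#' Thermal effects default to the conditioned-modality rating effects
#' (intensity 0.409, placebo -0.359); mechanical to the transfer-modality
#' effects (0.202, -0.244).
#'
#' @return named list of [effect_spec()] for `thermal` and `mechanical`.
#' @export
default_effects <- function() {
  list(thermal = effect_spec(0, 0.409, -0.359, 0),
       mechanical = effect_spec(0, 0.202, -0.244, 0))
}

#' Variance components for the twin trial generator
#'
#' The family covariance applies to the (intercept, level slope, placebo
#' slope) triple shared within a family; individual deviations get
#' zygosity-specific per-term standard deviations, with DZ at least as
#' variable as MZ by default (DZ twins share less genetic variance, so more
#' of the family-level similarity breaks down within pairs).
#'
#' @param family_cov symmetric PSD 3x3 covariance (intercept, level, placebo).
#' @param sd_individual_mz,sd_individual_dz per-term nonnegative SDs (length 3).
#' @param sd_residual residual SD.
#' @return a list of class `variance_components`.
#' @export
variance_components <- function(family_cov = diag(c(0.5, 0.2, 0.2)^2),
                                sd_individual_mz = c(0.40, 0.15, 0.15),
                                sd_individual_dz = c(0.60, 0.25, 0.25),
                                sd_residual = 0.70) {
  stop_if_not(is.matrix(family_cov) && all(dim(family_cov) == 3),
              "family_cov must be a 3x3 matrix")
  stop_if_not(isTRUE(all.equal(family_cov, t(family_cov))),
              "family_cov must be symmetric")
  ev <- eigen(family_cov, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -1e-10 * max(abs(ev), 1),
              "family_cov must be positive semidefinite")
  stop_if_not(all(sd_individual_mz >= 0) && all(sd_individual_dz >= 0) &&
              sd_residual >= 0, "standard deviations must be nonnegative")
  structure(list(family_cov = family_cov,
                 sd_individual_mz = sd_individual_mz,
                 sd_individual_dz = sd_individual_dz,
                 sd_residual = sd_residual),
            class = "variance_components")
}

level_codes <- c(low = -0.5, medium = 0, high = 0.5)
condition_codes <- c(control = -0.5, placebo = 0.5)

# multiset of stimulus levels per modality x condition cell (8 trials):
# 3 low / 2 medium / 3 high, so the centered codes sum to zero exactly
cell_levels <- c("low", "low", "low", "medium", "medium",
                 "high", "high", "high")

# draw from N(0, S) given a PSD covariance (eigendecomposition; works at rank 0)
rmvn_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * stats::rnorm(nrow(S))))
}

#' Simulate a trial-level outcome table for a twin cohort
#'
#' Each participant contributes 32 trials in 4 runs (control, placebo,
#' placebo, control), 8 trials per run of which four are thermal and four
#' mechanical, with three stimulus levels per modality.  The z-scale outcome
#' is the linear predictor on the centered codes plus a family draw (shared
#' within family), an individual draw with zygosity-specific SD (zeroed for
#' singletons, whose individual effect is not identifiable from the family
#' effect), and residual noise.  Ratings are an affine map of the z outcome
#' into the gLMS [0, 1] range, clipped; the clipping fraction is recorded as
#' an attribute.  Unpleasantness is intensity plus noise calibrated to a
#' within-participant correlation near 0.9.
#'
#' @param cohort participant table from [generate_cohort()].
#' @param effects either one [effect_spec()] (applied to both modalities) or
#'   a named list with elements `thermal` and `mechanical`.
#' @param vc a [variance_components()].
#' @param seed root seed; child streams are derived per family, participant
#'   and (participant, run) via [child_seed()].
#' @param rt_outlier_frac fraction of trials with reaction times planted
#'   outside the [0.02, 5.01] s validity window (for QC testing).
#' @param rating_center,rating_scale affine map from the z scale to gLMS.
#' @param sigma_unpleasant SD of the unpleasantness noise on the z scale.
#' @return data.frame with one row per trial (see package vignette for the
#'   column dictionary), plus attributes `clip_fraction` and `seed`.
#' @export
simulate_trial_table <- function(cohort, effects = default_effects(),
                                 vc = variance_components(), seed = 1L,
                                 rt_outlier_frac = 0,
                                 rating_center = 0.15, rating_scale = 0.07,
                                 sigma_unpleasant = 0.48) {
  stop_if_not(nrow(cohort) > 0, "cohort must be nonempty")
  stop_if_not(inherits(vc, "variance_components"),
              "vc must be a variance_components object")
  if (inherits(effects, "effect_spec"))
    effects <- list(thermal = effects, mechanical = effects)
  stop_if_not(all(c("thermal", "mechanical") %in% names(effects)),
              "effects must name thermal and mechanical specs")

  n_part <- nrow(cohort)
  fam_levels <- unique(cohort$family_id)
  run_condition <- c("control", "placebo", "placebo", "control")
  modalities <- c("thermal", "mechanical")

  # family draws: one (intercept, level, placebo) triple per family x modality
  fam_draw <- array(0, dim = c(length(fam_levels), 2, 3),
                    dimnames = list(fam_levels, modalities, NULL))
  for (fi in seq_along(fam_levels)) {
    with_seed(child_seed(seed, 8000001L, fi), {
      for (mi in 1:2) fam_draw[fi, mi, ] <- rmvn_psd(vc$family_cov)
    })
  }

  nt <- 32L * n_part
  col_pid <- rep(cohort$participant_id, each = 32L)
  col_fid <- rep(cohort$family_id, each = 32L)
  col_zyg <- rep(cohort$zygosity, each = 32L)
  col_run <- integer(nt); col_trial <- integer(nt)
  col_mod <- character(nt); col_lev <- character(nt)
  col_z <- numeric(nt); col_rt <- numeric(nt); col_unp_z <- numeric(nt)

  for (pi in seq_len(n_part)) {
    zyg <- cohort$zygosity[pi]
    sd_ind <- switch(zyg, MZ = vc$sd_individual_mz, DZ = vc$sd_individual_dz,
                     singleton = c(0, 0, 0),
                     stop("unknown zygosity: ", zyg, call. = FALSE))
    ind_draw <- matrix(0, 2, 3)
    with_seed(child_seed(seed, 9500001L, pi), {
      for (mi in 1:2) ind_draw[mi, ] <- sd_ind * stats::rnorm(3)
    })

    # stimulus-level layout: shuffle each cell's level multiset, split 4/4
    # between the cell's two runs; shuffle trial order within run
    lev_by_run_mod <- array("", dim = c(4, 2), dimnames = list(NULL, modalities))
    run_levels <- vector("list", 4); for (r in 1:4) run_levels[[r]] <- list()
    with_seed(child_seed(seed, 9000001L, pi), {
      for (m in modalities) {
        for (cond in c("control", "placebo")) {
          runs <- which(run_condition == cond)
          levs <- sample(cell_levels)
          run_levels[[runs[1]]][[m]] <- levs[1:4]
          run_levels[[runs[2]]][[m]] <- levs[5:8]
        }
      }
      run_order <- lapply(1:4, function(r) sample(rep(modalities, each = 4L)))
    })

    fam_row <- fam_draw[cohort$family_id[pi], , , drop = FALSE]
    base <- (pi - 1L) * 32L
    for (r in 1:4) {
      cond_code <- condition_codes[[run_condition[r]]]
      mods <- run_order[[r]]
      taken <- c(thermal = 0L, mechanical = 0L)
      idx <- base + (r - 1L) * 8L + 1:8
      with_seed(child_seed(seed, pi, r), {
        resid <- stats::rnorm(8, 0, vc$sd_residual)
        unp_noise <- stats::rnorm(8, 0, sigma_unpleasant)
        rts <- stats::rlnorm(8, meanlog = log(1.1), sdlog = 0.4)
      })
      for (k in 1:8) {
        m <- mods[k]
        taken[m] <- taken[m] + 1L
        lev <- run_levels[[r]][[m]][taken[m]]
        lv <- level_codes[[lev]]
        mi <- match(m, modalities)
        ef <- effects[[m]]
        lp <- ef$beta_intercept + ef$beta_intensity * lv +
          ef$beta_placebo * cond_code + ef$beta_interaction * lv * cond_code
        re <- fam_row[1, mi, ] %*% c(1, lv, cond_code) +
          ind_draw[mi, ] %*% c(1, lv, cond_code)
        i <- idx[k]
        col_run[i] <- r; col_trial[i] <- (r - 1L) * 8L + k
        col_mod[i] <- m; col_lev[i] <- lev
        col_z[i] <- lp + drop(re) + resid[k]
        col_unp_z[i] <- col_z[i] + unp_noise[k]
        col_rt[i] <- min(rts[k], 4.9)  # in-window by construction
      }
    }
  }

  raw_int <- rating_center + rating_scale * col_z
  raw_unp <- rating_center + rating_scale * col_unp_z
  clip_fraction <- mean(raw_int < 0 | raw_int > 1)

  if (rt_outlier_frac > 0) {
    n_out <- round(rt_outlier_frac * nt)
    with_seed(child_seed(seed, 7000001L), {
      pick <- sample(nt, n_out)
      hi <- pick[seq_len(n_out %/% 2L)]
      lo <- setdiff(pick, hi)
      col_rt[hi] <- 5.02 + stats::rexp(length(hi), 2)
      col_rt[lo] <- stats::runif(length(lo), 0.001, 0.019)
    })
  }

  out <- data.frame(
    participant_id = col_pid, family_id = col_fid, zygosity = col_zyg,
    run = col_run, trial_index = col_trial,
    modality = col_mod, condition = run_condition[col_run],
    stimulus_level = col_lev,
    level_code = unname(level_codes[col_lev]),
    condition_code = unname(condition_codes[run_condition[col_run]]),
    intensity_z = col_z,
    intensity_rating = pmin(pmax(raw_int, 0), 1),
    unpleasantness_rating = pmin(pmax(raw_unp, 0), 1),
    rt_intensity = col_rt,
    stringsAsFactors = FALSE
  )
  attr(out, "clip_fraction") <- clip_fraction
  attr(out, "seed") <- seed
  out
}
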