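#' Jeffreys-Zellner-Siow marginal likelihood by importance-weighted Monte Carlo
#'
#' Computes the log marginal likelihood of a Gaussian linear model in which
#' each column group receives a normal prior `theta_j ~ N(0, g_j sigma^2)`
#' with `g_j` carrying a scaled inverse-chi-squared(1) prior — the JZS
#' construction (a Cauchy prior on each standardized effect after integrating
#' `g`).  The intercept gets a flat prior (integrated analytically) and the
#' error variance a Jeffreys prior.  Conditional on `g` the marginal is a
#' closed-form Gaussian integral; the `g` vector is integrated by
#' importance-weighted Monte Carlo on the log-g scale with a mode-calibrated
#' multivariate-t proposal (the raw prior is far too heavy-tailed to serve as
#' a proposal once several random-effect groups concentrate the integrand),
#' with the relative standard error of the weight mean reported by the delta
#' method.
#'
#' @param y numeric response (standardize before calling for the JZS scale
#'   interpretation).
#' @param groups list of column groups, each `list(X = <matrix>, rscale =
#'   <prior scale>)`; random-effect groups share one `g` across their
#'   columns, fixed effects of interest are one column each.
#' @param n_mc number of Monte Carlo draws.
#' @param seed integer seed for the draws.
#' @param intercept integrate a flat intercept (TRUE for the mixed models
#'   here; FALSE for the one-sample reduction where the mean is the effect).
#' @return list: `logml`, `se_log` (approximate SE of the log marginal),
#'   `rel_se` (relative SE of the marginal on the natural scale), `ess`
#'   (effective sample size), `n_mc`.
#' @export
marginal_likelihood_mc <- function(y, groups = list(), n_mc = 4000L, seed = 1L,
                                   intercept = TRUE) {
  N <- length(y)
  stop_if_not(N >= 3, "need at least 3 observations")
  q_each <- vapply(groups, function(g) ncol(g$X), integer(1))
  X <- if (length(groups)) do.call(cbind, lapply(groups, `[[`, "X"))
       else matrix(0, N, 0)
  q <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  Xt1 <- drop(crossprod(X, rep(1, N)))
  yty <- sum(y^2)
  sum_y <- sum(y)

  # conditional log marginal given the prior variance multipliers d (= g_j)
  cond_logml <- function(d) {
    if (q == 0L) {
      if (intercept) {
        R <- yty - sum_y^2 / N
        return(-((N - 1) / 2) * log(2 * pi) - 0.5 * log(N) +
                 lgamma((N - 1) / 2) - ((N - 1) / 2) * log(R / 2))
      }
      return(-(N / 2) * log(2 * pi) + lgamma(N / 2) - (N / 2) * log(yty / 2))
    }
    Wm <- XtX + diag(1 / d, q)
    R <- tryCatch(chol(Wm), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    ldSigma <- 2 * sum(log(diag(R))) + sum(log(d))  # log|I + X D X'|
    a_y <- backsolve(R, Xty, transpose = TRUE)
    ySy <- yty - sum(a_y^2)                          # y' Sigma^{-1} y
    if (!intercept)
      return(-(N / 2) * log(2 * pi) - 0.5 * ldSigma + lgamma(N / 2) -
               (N / 2) * log(ySy / 2))
    a_1 <- backsolve(R, Xt1, transpose = TRUE)
    oSo <- N - sum(a_1^2)                            # 1' Sigma^{-1} 1
    oSy <- sum_y - sum(a_1 * a_y)
    Rq <- ySy - oSy^2 / oSo
    -((N - 1) / 2) * log(2 * pi) - 0.5 * ldSigma - 0.5 * log(oSo) +
      lgamma((N - 1) / 2) - ((N - 1) / 2) * log(Rq / 2)
  }

  if (q == 0L) {
    # no scale parameters to integrate: the marginal is exact
    lm0 <- cond_logml(numeric(0))
    return(list(logml = lm0, se_log = 0, rel_se = 0, ess = n_mc, n_mc = n_mc))
  }

  # log integrand over u = log g (per group), prior included with Jacobian:
  # g ~ rscale^2 * inv-chi-squared(1)
  rsc <- vapply(groups, `[[`, numeric(1), "rscale")
  nG <- length(groups)
  log_prior_u <- function(u) {
    g <- exp(u)
    sum(0.5 * log(rsc^2 / 2) - lgamma(0.5) - 1.5 * u - rsc^2 / (2 * g) + u)
  }
  h <- function(u) {
    v <- cond_logml(rep(exp(u), times = q_each)) + log_prior_u(u)
    if (!is.finite(v)) -1e10 else v
  }
  opt <- stats::optim(rep(0, nG), function(u) -h(u), method = "BFGS",
                      control = list(maxit = 200))
  mode_u <- opt$par
  # proposal scale from the diagonal curvature at the mode, inflated
  sds <- vapply(seq_len(nG), function(j) {
    e <- numeric(nG); e[j] <- 1e-3
    d2 <- -(h(mode_u + e) - 2 * (-opt$value) + h(mode_u - e)) / 1e-6
    if (!is.finite(d2) || d2 <= 1e-4) 2 else min(1 / sqrt(d2), 5)
  }, numeric(1)) * 1.7
  tdf <- 4
  logw <- with_seed(seed, {
    U <- matrix(stats::rt(n_mc * nG, df = tdf), n_mc, nG)
    vapply(seq_len(n_mc), function(i) {
      u <- mode_u + sds * U[i, ]
      lq <- sum(stats::dt(U[i, ], df = tdf, log = TRUE) - log(sds))
      h(u) - lq
    }, numeric(1))
  })
  m <- max(logw)
  w <- exp(logw - m)
  wbar <- mean(w)
  logml <- m + log(wbar)
  rel_se <- stats::sd(w) / (wbar * sqrt(n_mc))
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 0.05 * n_mc)
    stop(sprintf(paste0("effective sample size of the importance weights is ",
                        "%.1f (< 5%% of n_mc = %d); increase n_mc"),
                 ess, n_mc), call. = FALSE)
  list(logml = logml, se_log = rel_se, rel_se = rel_se, ess = ess, n_mc = n_mc)
}

bf_groups_from_table <- function(table, effects, rscale) {
  # fixed effects of interest (Cauchy rscale each) + random intercepts for
  # family and zygosity-split participants (nuisance scale 1, no slopes)
  groups <- list()
  for (ef in effects) groups[[ef]] <- list(X = cbind(ef = table[[paste0(".code_", ef)]]),
                                           rscale = rscale)
  fam <- factor(table$family_id)
  Zf <- stats::model.matrix(~ 0 + fam)
  groups$family <- list(X = Zf, rscale = 1)
  for (zg in c("MZ", "DZ")) {
    sel <- table$zygosity == zg
    if (!any(sel)) next
    ids <- unique(table$participant_id[sel])
    Zp <- vapply(ids, function(id) as.numeric(table$participant_id == id),
                 numeric(nrow(table)))
    groups[[paste0("participant_", tolower(zg))]] <- list(X = Zp, rscale = 1)
  }
  groups
}

code_bf_table <- function(table, effects, interaction) {
  for (ef in effects) {
    table[[paste0(".code_", ef)]] <-
      if (ef %in% c("stimulus_level", "level"))
        code_column(table[[ef]], level_codes, "stimulus level")
      else if (ef %in% c("condition", "placebo_condition"))
        code_column(table[[ef]], condition_codes, "condition")
      else table[[ef]]
  }
  if (interaction) {
    table$.code_interaction <- table[[paste0(".code_", effects[1])]] *
      table[[paste0(".code_", effects[2])]]
  }
  table
}

#' Bayes factor for one fixed effect in the twin model
#'
#' JZS Bayes factor comparing the full model (all fixed mains, optionally
#' the interaction, with family and zygosity-split participant random
#' intercepts — no random slopes) against the same model without the fixed
#' effect of interest.  The outcome is standardized before computation.
#' `bf10 > 1` favours the model containing the effect.
#'
#' @param table QC-passed trial/score table for one modality.
#' @param outcome outcome column name.
#' @param effect fixed effect of interest (dropped in the null model).
#' @param other_effects remaining fixed effects kept in both models.
#' @param rscale Cauchy prior scale on the standardized effects of interest.
#' @param interaction include the interaction of the first two effects in
#'   the full model.
#' @param n_mc Monte Carlo draws per marginal likelihood.
#' @param seed integer seed.
#' @return list of class `bf_result`: `bf10`, `proportional_error` (relative
#'   MC standard error of bf10, quadrature-combined across numerator and
#'   denominator), `rscale`, `interaction`, `n_mc`, `seed`, plus the two
#'   marginal-likelihood objects.
#' @export
bf_fixed_effect <- function(table, outcome, effect = "condition",
                            other_effects = "stimulus_level", rscale = 1,
                            interaction = FALSE, n_mc = 4000L, seed = 1L) {
  stop_if_not(rscale > 0, "rscale must be positive")
  effects_full <- unique(c(other_effects, effect))
  table <- code_bf_table(table, effects_full, interaction)
  y <- as.numeric(scale(table[[outcome]]))
  eff_full <- c(effects_full, if (interaction) "interaction")
  eff_null <- setdiff(eff_full, effect)
  if (setequal(eff_full, eff_null)) {
    # degenerate request: the null model equals the full model
    return(structure(list(bf10 = 1, proportional_error = 0, rscale = rscale,
                          interaction = interaction, n_mc = n_mc, seed = seed,
                          full = NULL, null = NULL), class = "bf_result"))
  }
  gf <- bf_groups_from_table(table, eff_full, rscale)
  gn <- gf[setdiff(names(gf), effect)]
  mlf <- marginal_likelihood_mc(y, gf, n_mc = n_mc, seed = child_seed(seed, 1))
  mln <- marginal_likelihood_mc(y, gn, n_mc = n_mc, seed = child_seed(seed, 2))
  structure(list(bf10 = exp(mlf$logml - mln$logml),
                 proportional_error = sqrt(mlf$rel_se^2 + mln$rel_se^2),
                 rscale = rscale, interaction = interaction,
                 n_mc = n_mc, seed = seed, full = mlf, null = mln),
            class = "bf_result")
}

#' Robustness scan of a Bayes factor over prior scales and interaction
#'
#' One Bayes factor per combination of prior scale (default sqrt(2)/2, 1,
#' sqrt(2)) and inclusion of the interaction term in the alternative model.
#' A qualitative-conclusion flag reports whether every cell falls on the
#' same side of the conventional 1/3 or 3 evidence bounds.
#'
#' @inheritParams bf_fixed_effect
#' @param rscales prior scales to scan.
#' @param interactions logical values to scan.
#' @return data.frame with one row per cell (rscale, interaction, bf10,
#'   proportional_error, label, odds) and attributes `robust_null` /
#'   `robust_alternative`.
#' @export
bf_robustness <- function(table, outcome, effect = "condition",
                          other_effects = "stimulus_level",
                          rscales = c(sqrt(2) / 2, 1, sqrt(2)),
                          interactions = c(FALSE, TRUE),
                          n_mc = 4000L, seed = 1L) {
  grid <- expand.grid(rscale = rscales, interaction = interactions)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- bf_fixed_effect(table, outcome, effect, other_effects,
                         rscale = grid$rscale[i],
                         interaction = grid$interaction[i],
                         n_mc = n_mc, seed = child_seed(seed, 100L + i))
    ib <- interpret_bf(r$bf10)
    data.frame(rscale = grid$rscale[i], interaction = grid$interaction[i],
               bf10 = r$bf10, proportional_error = r$proportional_error,
               label = ib$label, odds = ib$odds, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "robust_null") <- all(out$bf10 < 1 / 3)
  attr(out, "robust_alternative") <- all(out$bf10 > 3)
  out
}

#' Evidence label and odds string for a Bayes factor
#'
#' Conventional evidence bands at 3, 10, 30 and 100 (and their reciprocals):
#' anecdotal / moderate / strong / very strong / extreme.  The odds string
#' rounds the Bayes factor (or its reciprocal) to integer odds, e.g.
#' `bf10 = 0.044` gives "23:1 odds in favor of the null".
#'
#' @param bf10 Bayes factor (alternative over null), positive.
#' @return list with `label` and `odds`.
#' @export
interpret_bf <- function(bf10) {
  stop_if_not(is.finite(bf10) && bf10 > 0, "bf10 must be a positive number")
  strength <- function(b) {
    if (b < 3) "anecdotal" else if (b < 10) "moderate"
    else if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  }
  if (bf10 == 1) return(list(label = "no evidence", odds = "1:1"))
  if (bf10 > 1) {
    list(label = paste(strength(bf10), "evidence for alternative"),
         odds = sprintf("%.0f:1 odds in favor of the alternative", round(bf10)))
  } else {
    list(label = paste(strength(1 / bf10), "evidence for null"),
         odds = sprintf("%.0f:1 odds in favor of the null", round(1 / bf10)))
  }
}
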