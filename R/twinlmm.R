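#' Centered design codes for the factorial
#'
#' Stimulus level is coded -0.5 / 0 / +0.5 (low / medium / high) and the
#' treatment condition -0.5 / +0.5 (control / placebo), so main effects are
#' differences across the factor range and the intercept is the grand cell
#' mean.
#'
#' @return list with `level_codes` and `condition_codes`.
#' @export
design_coding <- function() {
  list(level_codes = level_codes, condition_codes = condition_codes)
}

code_column <- function(x, codes, what) {
  if (is.numeric(x)) return(x)
  stop_if_not(all(x %in% names(codes)), "unknown %s value(s): %s", what,
              paste(setdiff(unique(x), names(codes)), collapse = ", "))
  unname(codes[x])
}

#' Encode the twin repeated-measures design
#'
#' Builds the fixed-effect matrix on the centered codes and the
#' zygosity-split random blocks: one (intercept, slope...) block per family,
#' and per-participant blocks duplicated into an MZ copy and a DZ copy with
#' the off-zygosity copy zeroed.  Keeping the copies in separate blocks with
#' separate covariance matrices is what makes the random-effect covariance
#' block diagonal by zygosity.  Singletons have both individual copies zeroed
#' (family and individual effects are not separable for one-member families).
#'
#' @param table data.frame with `participant_id`, `family_id`, `zygosity`
#'   and the predictor columns.
#' @param outcome name of the outcome column.
#' @param predictors character vector of fixed-effect columns; columns named
#'   `stimulus_level` / `condition` (or `placebo_condition`) are converted to
#'   the centered codes, other columns are used as-is (e.g. a continuous
#'   individual-difference predictor).
#' @param interaction include the product of the first two predictors.
#' @param covariates extra fixed-effect-only columns (no random terms).
#' @param random_terms predictors receiving random slopes (plus the
#'   intercept); defaults to all `predictors`.
#' @return list with `y`, `X`, `blocks`, `cluster` ready for [reml_fit()].
#' @export
encode_design <- function(table, outcome, predictors = c("stimulus_level", "condition"),
                          interaction = FALSE, covariates = NULL,
                          random_terms = predictors) {
  need <- c("participant_id", "family_id", "zygosity", outcome, predictors, covariates)
  stop_if_not(all(need %in% names(table)), "missing columns: %s",
              paste(setdiff(need, names(table)), collapse = ", "))
  zyg <- table$zygosity
  stop_if_not(all(zyg %in% c("MZ", "DZ", "singleton")),
              "unknown zygosity value(s): %s",
              paste(setdiff(unique(zyg), c("MZ", "DZ", "singleton")), collapse = ", "))

  coded <- lapply(predictors, function(p) {
    if (p %in% c("stimulus_level", "level")) code_column(table[[p]], level_codes, "stimulus level")
    else if (p %in% c("condition", "placebo_condition")) code_column(table[[p]], condition_codes, "condition")
    else {
      stop_if_not(is.numeric(table[[p]]), "predictor %s must be numeric or coded", p)
      table[[p]]
    }
  })
  names(coded) <- predictors

  X <- cbind(`(Intercept)` = 1, do.call(cbind, coded))
  colnames(X) <- c("(Intercept)", predictors)
  if (interaction) {
    stop_if_not(length(predictors) >= 2, "interaction needs two predictors")
    X <- cbind(X, coded[[1]] * coded[[2]])
    colnames(X)[ncol(X)] <- paste(predictors[1], predictors[2], sep = ":")
  }
  if (!is.null(covariates)) {
    for (cv in covariates) {
      stop_if_not(is.numeric(table[[cv]]), "covariate %s must be numeric", cv)
      X <- cbind(X, table[[cv]])
      colnames(X)[ncol(X)] <- cv
    }
  }

  Zbase <- cbind(`(intercept)` = 1,
                 do.call(cbind, coded[random_terms]))
  colnames(Zbase) <- c("(intercept)", random_terms)
  is_mz <- as.numeric(zyg == "MZ")
  is_dz <- as.numeric(zyg == "DZ")
  blocks <- list(
    family = list(Z = Zbase, group = factor(table$family_id)),
    participant_mz = list(Z = Zbase * is_mz, group = factor(table$participant_id)),
    participant_dz = list(Z = Zbase * is_dz, group = factor(table$participant_id))
  )
  list(y = table[[outcome]], X = X, blocks = blocks,
       cluster = factor(table$family_id))
}

#' Fit the zygosity-heteroskedastic twin mixed model
#'
#' REML fit of `outcome ~ 1 + predictors (+ interaction) (+ covariates)` with
#' correlated family random effects and zygosity-split individual random
#' effects (see [encode_design()]), the repeated-measures generalization of a
#' heteroskedastic twin error model.
#'
#' @inheritParams encode_design
#' @param control a [reml_control()].
#' @return a `twin_lmm` object: the underlying [reml_fit()] plus a tidy
#'   `fixed` table (estimate, SE, t, Satterthwaite DF, p, 95% CI per term).
#' @export
fit_twin_lmm <- function(table, outcome, predictors = c("stimulus_level", "condition"),
                         interaction = FALSE, covariates = NULL,
                         random_terms = predictors, control = reml_control()) {
  enc <- encode_design(table, outcome, predictors, interaction, covariates,
                       random_terms)
  fit <- reml_fit(enc$y, enc$X, enc$blocks, enc$cluster, control = control)
  fit$outcome <- outcome
  fit$n_participants <- length(unique(table$participant_id))
  fit$n_families <- length(unique(table$family_id))
  fit$fixed <- do.call(rbind, lapply(fit$terms, function(tm)
    test_fixed_effect(fit, tm)))
  class(fit) <- c("twin_lmm", class(fit))
  fit
}

#' Wald test of one fixed effect with Satterthwaite degrees of freedom
#'
#' @param fit a [reml_fit()] / `twin_lmm` object.
#' @param term fixed-effect name.
#' @return one-row data.frame: term, estimate, se, t, df, p, ci_lo, ci_hi.
#' @export
test_fixed_effect <- function(fit, term) {
  stop_if_not(term %in% fit$terms, "term %s not in the model", term)
  i <- match(term, fit$terms)
  cvec <- as.numeric(seq_along(fit$terms) == i)
  df <- satterthwaite_df(fit, cvec)
  b <- fit$beta[i]; se <- fit$se[i]
  tval <- b / se
  p <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(0.975, df)
  data.frame(term = term, estimate = unname(b), se = unname(se), t = unname(tval),
             df = df, p = p, ci_lo = unname(b - tcrit * se),
             ci_hi = unname(b + tcrit * se), stringsAsFactors = FALSE)
}

#' Interaction-then-mains fitting protocol
#'
#' Fits the model with the stimulus-by-treatment interaction; if the
#' interaction is not significant at `alpha` the model is refit without it
#' and the main effects are reported from the reduced model (the
#' interpretability convention of the factorial analysis).  Both fits are
#' retained and every reported row is flagged with its source model.
#'
#' @inheritParams fit_twin_lmm
#' @param alpha significance level for keeping the interaction.
#' @return list of class `interaction_protocol`: `full`, `reduced` (NULL if
#'   the interaction was kept), `final`, `interaction_p`, `report` (fixed
#'   table with a `source_model` column).
#' @export
interaction_protocol <- function(table, outcome,
                                 predictors = c("stimulus_level", "condition"),
                                 covariates = NULL, alpha = 0.05,
                                 control = reml_control()) {
  full <- fit_twin_lmm(table, outcome, predictors, interaction = TRUE,
                       covariates = covariates, control = control)
  int_term <- paste(predictors[1], predictors[2], sep = ":")
  p_int <- full$fixed$p[full$fixed$term == int_term]
  if (p_int >= alpha) {
    reduced <- fit_twin_lmm(table, outcome, predictors, interaction = FALSE,
                            covariates = covariates, control = control)
    report <- rbind(
      cbind(reduced$fixed, source_model = "reduced", stringsAsFactors = FALSE),
      cbind(full$fixed[full$fixed$term == int_term, ],
            source_model = "full", stringsAsFactors = FALSE))
    final <- reduced
  } else {
    reduced <- NULL
    report <- cbind(full$fixed, source_model = "full", stringsAsFactors = FALSE)
    final <- full
  }
  structure(list(full = full, reduced = reduced, final = final,
                 interaction_term = int_term, interaction_p = p_int,
                 report = report),
            class = "interaction_protocol")
}

#' Cohen's d across participants
#'
#' Mean over the sample standard deviation (n - 1 denominator), computed
#' across participants without accounting for the familial structure — the
#' descriptive effect-size convention for signature responses.
#'
#' @param values one value per participant.
#' @return list with `d` and `n`.
#' @export
cohens_d <- function(values) {
  values <- values[!is.na(values)]
  stop_if_not(length(values) >= 2, "need at least 2 values")
  s <- stats::sd(values)
  stop_if_not(s > 0, "zero standard deviation; d is undefined")
  list(d = mean(values) / s, n = length(values))
}
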