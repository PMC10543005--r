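#' Per-participant placebo contrasts (behavioral and neural)
#'
#' For every participant, modality and stimulus level, averages the outcome
#' over trials separately for the control and placebo conditions and takes
#' the control-minus-placebo difference; differences are then z-scored
#' across participants within each modality, and rank-transformed (average
#' ranks at ties) within each modality-by-level cell.  Cells a participant
#' is missing propagate as absent rows, never imputed.
#'
#' @param table QC-passed trial table.
#' @param outcomes named character vector: output contrast name ->
#'   input column (default behavioral analgesia from the intensity rating;
#'   add brain-score columns for neural reductions).
#' @return data.frame with participant, family, zygosity, modality,
#'   stimulus_level, and for each outcome `<name>` (z-scored difference),
#'   `<name>_raw` and `<name>_rank`.
#' @export
participant_contrasts <- function(table,
                                  outcomes = c(behavioral_analgesia = "intensity_z")) {
  stop_if_not(all(outcomes %in% names(table)), "missing outcome columns: %s",
              paste(setdiff(outcomes, names(table)), collapse = ", "))
  key_cols <- c("participant_id", "family_id", "zygosity", "modality",
                "stimulus_level")
  agg_key <- table[c(key_cols, "condition")]
  out <- NULL
  for (nm in names(outcomes)) {
    cellmean <- stats::aggregate(table[[outcomes[[nm]]]], by = agg_key,
                                 FUN = mean)
    names(cellmean)[ncol(cellmean)] <- "m"
    wide <- stats::reshape(cellmean, direction = "wide",
                           idvar = key_cols, timevar = "condition")
    # a participant missing either condition in a cell has no contrast there
    ctl <- wide[["m.control"]]; plc <- wide[["m.placebo"]]
    wide[[paste0(nm, "_raw")]] <- ctl - plc
    wide <- wide[!is.na(wide[[paste0(nm, "_raw")]]),
                 c(key_cols, paste0(nm, "_raw"))]
    out <- if (is.null(out)) wide else merge(out, wide, by = key_cols)
  }
  for (nm in names(outcomes)) {
    raw <- paste0(nm, "_raw")
    out <- zscore_within(out, "modality", raw, suffix = ".z")
    names(out)[names(out) == paste0(raw, ".z")] <- nm
    cellkey <- interaction(out$modality, out$stimulus_level, drop = TRUE)
    rk <- numeric(nrow(out))
    for (lev in levels(cellkey)) {
      i <- cellkey == lev
      rk[i] <- rank(out[[raw]][i], ties.method = "average")
    }
    out[[paste0(nm, "_rank")]] <- rk
  }
  out[order(out$participant_id, out$modality, out$stimulus_level), ]
}

contrast_model <- function(contrasts, outcome, predictor, modality,
                           control = reml_control()) {
  tab <- contrasts[contrasts$modality == modality, ]
  stop_if_not(nrow(tab) > 0, "no rows for modality %s", modality)
  stop_if_not(length(unique(tab$family_id)) >= 2, "need >= 2 families")
  fit <- fit_twin_lmm(tab, outcome,
                      predictors = c("stimulus_level", predictor),
                      control = control)
  fit$fixed[fit$fixed$term == predictor, ]
}

#' Brain-behavior correlation model
#'
#' Twin mixed model of the placebo-induced neural reduction on the
#' behavioral analgesia (`neural ~ 1 + stimulus_level + behavioral_analgesia`
#' with the full family and zygosity-split participant random structure),
#' fitted per modality.  The rank-based variant runs the identical model on
#' the within-cell ranks (a Spearman-type robustness check).
#'
#' @param contrasts output of [participant_contrasts()].
#' @param marker name of the neural contrast column (as passed to
#'   `participant_contrasts`' `outcomes`).
#' @param modality "thermal" or "mechanical".
#' @param rank_based use the rank columns instead of the z-scored values.
#' @param control a [reml_control()].
#' @return one-row data.frame: the behavioral-analgesia slope with SE,
#'   Satterthwaite DF, p and CI.
#' @export
brain_behavior_model <- function(contrasts, marker, modality = "thermal",
                                 rank_based = FALSE,
                                 control = reml_control()) {
  suffix <- if (rank_based) "_rank" else ""
  contrast_model(contrasts, paste0(marker, suffix),
                 paste0("behavioral_analgesia", suffix), modality, control)
}

#' Expectation correlation model
#'
#' Same twin machinery with pre-treatment expected-efficacy ratings (0-100,
#' z-scored within modality) predicting the placebo contrast.
#'
#' @param contrasts output of [participant_contrasts()].
#' @param expectations data.frame with `participant_id` and
#'   `expected_efficacy` in [0, 100] (one row per participant).
#' @param outcome contrast column to predict (default behavioral analgesia).
#' @param modality "thermal" or "mechanical".
#' @param control a [reml_control()].
#' @return one-row data.frame for the expectation slope.
#' @export
expectation_model <- function(contrasts, expectations,
                              outcome = "behavioral_analgesia",
                              modality = "thermal",
                              control = reml_control()) {
  stop_if_not(all(c("participant_id", "expected_efficacy") %in% names(expectations)),
              "expectations needs participant_id and expected_efficacy")
  stop_if_not(!anyDuplicated(expectations$participant_id),
              "one expectation per participant")
  stop_if_not(all(expectations$expected_efficacy >= 0 &
                  expectations$expected_efficacy <= 100),
              "expected_efficacy must be on the 0-100 scale")
  tab <- merge(contrasts, expectations, by = "participant_id")
  tab <- zscore_within(tab, "modality", "expected_efficacy", suffix = "_z")
  contrast_model(tab, outcome, "expected_efficacy_z", modality, control)
}

#' Cross-modality transfer model
#'
#' Predicts the placebo contrast in the (unconditioned) mechanical modality
#' from the same participant's contrast in the conditioned thermal modality,
#' matched by stimulus level, with the full twin random structure.  A
#' positive slope indicates that placebo responses generalize across pain
#' modalities.
#'
#' @param contrasts output of [participant_contrasts()].
#' @param outcome contrast column (default behavioral analgesia).
#' @param control a [reml_control()].
#' @return one-row data.frame for the thermal-contrast slope.
#' @export
transfer_model <- function(contrasts, outcome = "behavioral_analgesia",
                           control = reml_control()) {
  mech <- contrasts[contrasts$modality == "mechanical", ]
  ther <- contrasts[contrasts$modality == "thermal",
                    c("participant_id", "stimulus_level", outcome)]
  names(ther)[3] <- "thermal_contrast"
  tab <- merge(mech, ther, by = c("participant_id", "stimulus_level"))
  stop_if_not(nrow(tab) > 0, "no participants with both modalities")
  fit <- fit_twin_lmm(tab, outcome,
                      predictors = c("stimulus_level", "thermal_contrast"),
                      control = control)
  fit$fixed[fit$fixed$term == "thermal_contrast", ]
}
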