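#' First-level GLM configuration
#'
#' Defaults follow the acquisition and modelling choices of the study design
#' this package emulates: TR 0.46 s, 550 volumes per run, a 180 s high-pass
#' cutoff implemented as a cosine drift basis, and censoring of the first
#' eight frames of each run.
#'
#' @param tr repetition time in seconds.
#' @param n_volumes frames per run.
#' @param drift_cutoff high-pass cutoff period in seconds.
#' @param n_censor_lead number of lead frames censored per run.
#' @param hrf_shape1,hrf_rate1 gamma parameters of the response peak.
#' @param hrf_shape2,hrf_rate2 gamma parameters of the undershoot.
#' @param hrf_ratio undershoot amplitude ratio.
#' @param hrf_length HRF support in seconds.
#' @return list of class `glm_config`.
#' @export
glm_config <- function(tr = 0.46, n_volumes = 550L, drift_cutoff = 180,
                       n_censor_lead = 8L,
                       hrf_shape1 = 6, hrf_rate1 = 1,
                       hrf_shape2 = 16, hrf_rate2 = 1,
                       hrf_ratio = 1 / 6, hrf_length = 32) {
  stop_if_not(tr > 0, "tr must be positive")
  stop_if_not(drift_cutoff > 2 * tr, "drift_cutoff must exceed 2 * tr")
  stop_if_not(is_count(n_censor_lead), "n_censor_lead must be a nonnegative count")
  structure(list(tr = tr, n_volumes = as.integer(n_volumes),
                 drift_cutoff = drift_cutoff,
                 n_censor_lead = as.integer(n_censor_lead),
                 hrf_shape1 = hrf_shape1, hrf_rate1 = hrf_rate1,
                 hrf_shape2 = hrf_shape2, hrf_rate2 = hrf_rate2,
                 hrf_ratio = hrf_ratio, hrf_length = hrf_length),
            class = "glm_config")
}

hrf_continuous <- function(t, config) {
  stats::dgamma(t, config$hrf_shape1, config$hrf_rate1) -
    config$hrf_ratio * stats::dgamma(t, config$hrf_shape2, config$hrf_rate2)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak at 5 s, undershoot around 15 s,
#' ratio 1/6), sampled at the TR over 32 s and normalized to unit peak.
#'
#' @param config a [glm_config()].
#' @return numeric vector; attribute `times` holds the sample times.
#' @export
canonical_hrf <- function(config = glm_config()) {
  t <- seq(0, config$hrf_length, by = config$tr)
  h <- hrf_continuous(t, config)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

#' Cosine (DCT) drift basis for high-pass filtering
#'
#' `K = floor(2 * T / cutoff)` columns where `T` is the run duration, the
#' standard discrete-cosine count for a high-pass cutoff period.
#'
#' @param n_volumes frames in the run.
#' @param tr repetition time (s).
#' @param cutoff high-pass cutoff period (s).
#' @return matrix `n_volumes x K` (K may be 0).
#' @export
cosine_drift_basis <- function(n_volumes, tr, cutoff) {
  T_run <- n_volumes * tr
  K <- floor(2 * T_run / cutoff)
  n <- seq_len(n_volumes) - 0.5
  B <- vapply(seq_len(K), function(k)
    sqrt(2 / n_volumes) * cos(pi * k * n / n_volumes), numeric(n_volumes))
  if (K == 0) B <- matrix(0, n_volumes, 0)
  colnames(B) <- if (K > 0) sprintf("drift_%02d", seq_len(K))
  B
}

#' Build a first-level design matrix
#'
#' Columns: one HRF-convolved boxcar per event label (the 12 stimulus
#' conditions, 4 cue conditions and the rating regressor in the full task
#' model), a constant, the cosine drift basis, optional nuisance columns
#' (e.g. 24 motion regressors and mean CSF), and one indicator column per
#' censored frame (the lead frames of the run plus any spike frames), which
#' removes those frames' influence exactly.
#'
#' @param events data.frame with `onset`, `duration` (seconds) and `label`.
#' @param config a [glm_config()].
#' @param nuisance optional numeric matrix with `n_volumes` rows.
#' @param spike_frames integer frame indices (1-based) to censor.
#' @param oversample temporal oversampling factor for the convolution grid.
#' @return list with `X` (design matrix), `legend` (data.frame naming every
#'   column and its class) and `censored_frames`.
#' @export
build_design_matrix <- function(events, config = glm_config(), nuisance = NULL,
                                spike_frames = integer(0), oversample = 16L) {
  nvol <- config$n_volumes
  tr <- config$tr
  run_dur <- nvol * tr
  if (is.null(events)) events <- data.frame(onset = numeric(0),
                                            duration = numeric(0),
                                            label = character(0))
  stop_if_not(all(c("onset", "duration", "label") %in% names(events)),
              "events needs onset, duration, label columns")
  stop_if_not(all(events$onset >= 0 & events$onset < run_dur),
              "event onsets must lie within the run")
  stop_if_not(all(events$duration > 0), "event durations must be positive")
  # overlapping identical-label events are a specification error
  for (lab in unique(events$label)) {
    e <- events[events$label == lab, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1 &&
        any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
      stop("overlapping events with identical label '", lab, "'", call. = FALSE)
  }

  dt <- tr / oversample
  fine_t <- seq(0, run_dur - dt / 2, by = dt)
  hrf_fine <- hrf_continuous(fine_t[fine_t <= config$hrf_length], config)
  hrf_fine <- hrf_fine / max(hrf_fine)
  frame_idx <- 1L + round((seq_len(nvol) - 1L) * tr / dt)

  labs <- unique(events$label)
  task <- matrix(0, nvol, length(labs))
  colnames(task) <- labs
  for (li in seq_along(labs)) {
    box <- numeric(length(fine_t))
    e <- events[events$label == labs[li], ]
    for (r in seq_len(nrow(e)))
      box[fine_t >= e$onset[r] & fine_t < e$onset[r] + e$duration[r]] <- 1
    conv <- stats::convolve(box, rev(hrf_fine), type = "open")[seq_along(fine_t)]
    task[, li] <- conv[frame_idx] * dt  # Riemann scaling of the convolution
  }

  drift <- cosine_drift_basis(nvol, tr, config$drift_cutoff)
  const <- matrix(1, nvol, 1, dimnames = list(NULL, "constant"))

  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stop_if_not(nrow(nuisance) == nvol,
                "nuisance block must have %d rows", nvol)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance_%02d", seq_len(ncol(nuisance)))
  } else nuisance <- matrix(0, nvol, 0)

  censored <- sort(unique(c(seq_len(config$n_censor_lead),
                            as.integer(spike_frames))))
  stop_if_not(all(censored >= 1 & censored <= nvol),
              "censored frames must be within the run")
  cens <- matrix(0, nvol, length(censored))
  if (length(censored)) {
    cens[cbind(censored, seq_along(censored))] <- 1
    colnames(cens) <- sprintf("censor_%03d", censored)
  }

  X <- cbind(task, const, drift, nuisance, cens)
  legend <- data.frame(
    column = colnames(X),
    class = c(rep("task", ncol(task)), "constant",
              rep("drift", ncol(drift)), rep("nuisance", ncol(nuisance)),
              rep("censor", ncol(cens))),
    stringsAsFactors = FALSE
  )
  list(X = X, legend = legend, censored_frames = censored)
}

#' Detect spike frames from the global signal
#'
#' Documented substitute for the study's unpublished in-house detector:
#' frames whose robust z score of the global mean signal
#' (|x - median| / (1.4826 MAD)) exceeds the threshold are flagged.
#'
#' @param data numeric matrix, voxels x time.
#' @param z_threshold robust z threshold (default 3.5).
#' @return integer vector of flagged frame indices (possibly empty).
#' @export
detect_spikes <- function(data, z_threshold = 3.5) {
  stop_if_not(is.matrix(data) && ncol(data) >= 10,
              "data must be a voxels x time matrix with >= 10 frames")
  g <- colMeans(data)
  s <- stats::mad(g)
  if (s == 0) {
    warning("constant global signal (MAD = 0); no spikes flagged")
    return(integer(0))
  }
  z <- abs(g - stats::median(g)) / s
  which(z > z_threshold)
}

#' Fit the per-voxel GLM by ordinary least squares
#'
#' @param data numeric matrix, voxels x time.
#' @param design a design list from [build_design_matrix()] or a plain matrix.
#' @return list with `beta` (voxels x columns), `sigma2` (residual variance
#'   per voxel, censored frames excluded from the df), `df_residual`, and the
#'   column `legend` when available.
#' @export
fit_glm <- function(data, design) {
  X <- if (is.list(design)) design$X else design
  legend <- if (is.list(design)) design$legend else NULL
  stop_if_not(is.matrix(data) && ncol(data) == nrow(X),
              "data must be voxels x time with %d frames", nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- t(qr.coef(qrX, t(data)))
  fitted <- beta %*% t(X)
  resid <- data - fitted
  df <- nrow(X) - ncol(X)
  sigma2 <- rowSums(resid^2) / df
  colnames(beta) <- colnames(X)
  list(beta = beta, sigma2 = sigma2, df_residual = df, legend = legend)
}
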