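#' Volumetric map container
#'
#' A masked 3-D voxel array with a 4x4 voxel-to-world affine, the common
#' currency for contrast maps and weight volumes.
#'
#' @param values numeric 3-D array.
#' @param affine 4x4 voxel-to-world matrix (defaults to 2 mm isotropic).
#' @param mask logical 3-D array; defaults to all-TRUE.
#' @return object of class `volume_map`.
#' @export
volume_map <- function(values, affine = diag(c(2, 2, 2, 1)), mask = NULL) {
  stop_if_not(is.array(values) && length(dim(values)) == 3,
              "values must be a 3-D array")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  stop_if_not(identical(dim(mask), dim(values)), "mask must match values' grid")
  stop_if_not(any(mask), "mask must be nonempty")
  stop_if_not(all(is.finite(values[mask])), "values must be finite inside the mask")
  stop_if_not(is.matrix(affine) && all(dim(affine) == 4), "affine must be 4x4")
  structure(list(values = values, affine = affine, mask = mask),
            class = "volume_map")
}

#' Signature (neuromarker weight) map container
#'
#' A weight volume plus an integer-labelled subregion atlas with a declared
#' sign per label (+1: more activity predicts more pain; -1: the weights are
#' negative, so a *positive* local pattern response corresponds to
#' *deactivation*).
#'
#' @param weights numeric 3-D array of pattern weights.
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask logical 3-D array; defaults to `weights != 0`.
#' @param subregions integer 3-D array of labels (0 = unlabelled).
#' @param legend data.frame with columns `label`, `sign` (one row per label).
#' @return object of class `signature_map`.
#' @export
signature_map <- function(weights, affine = diag(c(2, 2, 2, 1)), mask = NULL,
                          subregions = NULL, legend = NULL) {
  if (is.null(mask)) mask <- weights != 0
  vm <- volume_map(weights, affine, mask)
  if (is.null(subregions)) subregions <- array(0L, dim(weights))
  stop_if_not(identical(dim(subregions), dim(weights)),
              "subregions must match the weight grid")
  labs <- sort(unique(subregions[subregions > 0]))
  if (is.null(legend) && length(labs)) {
    sgn <- vapply(labs, function(l) {
      w <- weights[subregions == l]
      if (all(w >= 0)) 1L else if (all(w <= 0)) -1L else
        stop("subregion ", l, " mixes weight signs; declare a legend",
             call. = FALSE)
    }, integer(1))
    legend <- data.frame(label = labs, sign = sgn)
  }
  stop_if_not(all(subregions[!mask] == 0), "subregions must lie inside the mask")
  for (i in seq_len(NROW(legend))) {
    w <- weights[subregions == legend$label[i]]
    stop_if_not(all(sign(w[w != 0]) == legend$sign[i]),
                "weights in subregion %d do not carry the declared sign",
                legend$label[i])
  }
  structure(list(weights = weights, affine = affine, mask = mask,
                 subregions = subregions, legend = legend),
            class = "signature_map")
}

check_same_grid <- function(a, b, tol = 1e-4) {
  va <- if (inherits(a, "signature_map")) a$weights else a$values
  vb <- if (inherits(b, "signature_map")) b$weights else b$values
  stop_if_not(identical(dim(va), dim(vb)),
              "grid shape mismatch (%s vs %s); no silent resampling is done",
              paste(dim(va), collapse = "x"), paste(dim(vb), collapse = "x"))
  stop_if_not(max(abs(a$affine - b$affine)) <= tol,
              "affine mismatch beyond %g; no silent resampling is done", tol)
  invisible(TRUE)
}

#' Signature (dot-product) score of a contrast map
#'
#' Sum over joint-mask voxels of map value times signature weight — the
#' standard pattern-expression score of a neuromarker.  Map and signature
#' must share grid and affine; the joint mask is the intersection of the two
#' masks (its voxel count is attached as an attribute).
#'
#' @param map a [volume_map()].
#' @param sig a [signature_map()].
#' @return scalar score with attribute `n_voxels`.
#' @export
signature_score <- function(map, sig) {
  stop_if_not(inherits(map, "volume_map"), "map must be a volume_map")
  stop_if_not(inherits(sig, "signature_map"), "sig must be a signature_map")
  check_same_grid(map, sig)
  joint <- map$mask & sig$mask
  stop_if_not(any(joint), "joint mask is empty")
  s <- sum(map$values[joint] * sig$weights[joint])
  attr(s, "n_voxels") <- sum(joint)
  s
}

#' Mean contrast value inside a region of interest
#'
#' @param map a [volume_map()].
#' @param roi_mask logical 3-D array on the same grid.
#' @return scalar mean with attribute `n_voxels`.
#' @export
roi_mean <- function(map, roi_mask) {
  stop_if_not(inherits(map, "volume_map"), "map must be a volume_map")
  stop_if_not(identical(dim(roi_mask), dim(map$values)),
              "roi_mask must match the map grid")
  joint <- map$mask & roi_mask
  stop_if_not(any(joint), "ROI does not intersect the map mask")
  m <- mean(map$values[joint])
  attr(m, "n_voxels") <- sum(joint)
  m
}

#' Local pattern response within one signature subregion
#'
#' Dot product of the map with the signature weights restricted to a labelled
#' subregion.  Interpretation contract: for negative-weight subregions a more
#' positive response corresponds to deactivation (and predicts more pain);
#' the subregion's declared sign is attached to the result.
#'
#' @param map a [volume_map()].
#' @param sig a [signature_map()] with labelled subregions.
#' @param label integer subregion label.
#' @return scalar response with attributes `sign` and `n_voxels`.
#' @export
local_pattern_response <- function(map, sig, label) {
  stop_if_not(inherits(sig, "signature_map"), "sig must be a signature_map")
  stop_if_not(label %in% sig$legend$label, "unknown subregion label: %s",
              as.character(label))
  check_same_grid(map, sig)
  sel <- (sig$subregions == label) & map$mask & sig$mask
  r <- sum(map$values[sel] * sig$weights[sel])
  attr(r, "sign") <- sig$legend$sign[match(label, sig$legend$label)]
  attr(r, "n_voxels") <- sum(sel)
  r
}

#' Z-score values within groups
#'
#' Standardizes `value_col` to mean 0 and sample SD 1 (n - 1 denominator)
#' within each combination of `group_keys`.
#'
#' @param records data.frame.
#' @param group_keys character vector of grouping column names.
#' @param value_col name of the column to standardize.
#' @param suffix appended to the output column name ("" replaces in place).
#' @return the data.frame with the standardized column.
#' @export
zscore_within <- function(records, group_keys, value_col = "score",
                          suffix = "") {
  stop_if_not(all(group_keys %in% names(records)), "missing grouping columns")
  stop_if_not(value_col %in% names(records), "missing value column %s", value_col)
  key <- interaction(records[group_keys], drop = TRUE, sep = "/")
  out <- records[[value_col]]
  for (lev in levels(key)) {
    i <- key == lev
    v <- records[[value_col]][i]
    stop_if_not(sum(i) >= 2, "group %s has fewer than 2 values", lev)
    s <- stats::sd(v)
    stop_if_not(s > 0, "group %s is constant; cannot z-score", lev)
    out[i] <- (v - mean(v)) / s
  }
  records[[paste0(value_col, suffix)]] <- out
  records
}

#' Explicit nearest/linear regridding of a volume (user-invoked only)
#'
#' Resampling changes dot products, so it is never applied implicitly by the
#' scoring functions; call this utility deliberately when grids differ.
#' Nearest-neighbour or trilinear interpolation in world coordinates.
#'
#' @param map a [volume_map()].
#' @param target_dims integer length-3 grid.
#' @param target_affine 4x4 voxel-to-world matrix of the target grid.
#' @param method "nearest" or "linear".
#' @return a [volume_map()] on the target grid.
#' @export
regrid <- function(map, target_dims, target_affine, method = c("nearest", "linear")) {
  method <- match.arg(method)
  stop_if_not(inherits(map, "volume_map"), "map must be a volume_map")
  dims <- dim(map$values)
  g <- as.matrix(expand.grid(i = seq_len(target_dims[1]) - 1,
                             j = seq_len(target_dims[2]) - 1,
                             k = seq_len(target_dims[3]) - 1))
  world <- target_affine %*% rbind(t(g), 1)
  src <- solve(map$affine) %*% world  # 0-based source voxel coordinates
  vals <- numeric(ncol(src)); msk <- logical(ncol(src))
  getv <- function(i, j, k) {
    ok <- i >= 0 & i < dims[1] & j >= 0 & j < dims[2] & k >= 0 & k < dims[3]
    v <- rep(NA_real_, length(i)); inm <- rep(FALSE, length(i))
    if (any(ok)) {
      lin <- 1 + i[ok] + dims[1] * (j[ok] + dims[2] * k[ok])
      v[ok] <- map$values[lin]; inm[ok] <- map$mask[lin]
    }
    list(v = v, m = inm)
  }
  if (method == "nearest") {
    r <- getv(round(src[1, ]), round(src[2, ]), round(src[3, ]))
    vals <- ifelse(is.na(r$v), 0, r$v); msk <- r$m & !is.na(r$v)
  } else {
    f <- floor(src[1:3, , drop = FALSE])
    w <- src[1:3, , drop = FALSE] - f
    acc <- numeric(ncol(src)); wm <- rep(TRUE, ncol(src))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      r <- getv(f[1, ] + di, f[2, ] + dj, f[3, ] + dk)
      ww <- (ifelse(di == 1, w[1, ], 1 - w[1, ]) *
             ifelse(dj == 1, w[2, ], 1 - w[2, ]) *
             ifelse(dk == 1, w[3, ], 1 - w[3, ]))
      acc <- acc + ww * ifelse(is.na(r$v), 0, r$v)
      wm <- wm & (r$m | ww < 1e-12)
    }
    vals <- acc; msk <- wm
  }
  volume_map(array(vals, target_dims), target_affine, array(msk, target_dims))
}
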