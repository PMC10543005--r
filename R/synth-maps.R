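#' Build a synthetic signature (weight) volume
#'
#' Stand-in for external neuromarker weight maps: disjoint cuboid subregions
#' on a lattice, each carrying all-positive or all-negative weights.  The
#' default 2 positive / 6 negative split mirrors the pre-registered
#' higher-level signature subregion structure.
#'
#' @param grid_dims integer length-3, each at least 8.
#' @param n_pos_subregions,n_neg_subregions subregion counts.
#' @param seed integer seed (same seed, same volume).
#' @param subregion_size edge length of each cuboid subregion (voxels).
#' @return a [signature_map()] with labelled subregions and a sign legend;
#'   positive labels come first.
#' @export
make_synthetic_signature <- function(grid_dims = c(16L, 16L, 16L),
                                     n_pos_subregions = 2L,
                                     n_neg_subregions = 6L,
                                     seed = 1L, subregion_size = 3L) {
  stop_if_not(length(grid_dims) == 3 && all(grid_dims >= 8),
              "grid_dims must be length 3 with every dimension >= 8")
  n_sub <- n_pos_subregions + n_neg_subregions
  stop_if_not(n_sub >= 1, "at least one subregion is required")
  pitch <- subregion_size + 1L  # one-voxel gap guarantees disjointness
  slots <- lapply(grid_dims, function(d) seq(1L, d - subregion_size + 1L, by = pitch))
  capacity <- prod(lengths(slots))
  stop_if_not(n_sub <= capacity,
              "requested %d disjoint subregions but the grid holds only %d",
              n_sub, capacity)
  anchors <- as.matrix(expand.grid(slots[[1]], slots[[2]], slots[[3]]))

  weights <- array(0, grid_dims)
  subregions <- array(0L, grid_dims)
  with_seed(seed, {
    pick <- sample(nrow(anchors), n_sub)
    for (s in seq_len(n_sub)) {
      a <- anchors[pick[s], ]
      ii <- a[1]:(a[1] + subregion_size - 1L)
      jj <- a[2]:(a[2] + subregion_size - 1L)
      kk <- a[3]:(a[3] + subregion_size - 1L)
      sgn <- if (s <= n_pos_subregions) 1 else -1
      w <- sgn * (abs(stats::rnorm(subregion_size^3)) + 0.2)
      weights[ii, jj, kk] <- array(w, rep(subregion_size, 3))
      subregions[ii, jj, kk] <- s
    }
  })
  legend <- data.frame(label = seq_len(n_sub),
                       sign = rep(c(1L, -1L),
                                  c(n_pos_subregions, n_neg_subregions)))
  signature_map(weights, subregions = subregions, legend = legend)
}

#' Simulate contrast maps with planted signature scores
#'
#' Each map is `signature * target / ||w||^2` plus spatially independent
#' Gaussian noise, so the masked dot product with the signature recovers the
#' planted target score in expectation (exactly when `noise_sd = 0`).
#'
#' @param targets data.frame with one row per map; must contain a `target`
#'   column (any id columns are carried into the result names).
#' @param signature a [signature_map()].
#' @param noise_sd voxelwise noise SD.
#' @param seed root seed; one child stream per map.
#' @return named list of [volume_map()]s, one per row of `targets`, in row
#'   order; names are the row ids (or `map<k>`).
#' @export
simulate_contrast_maps <- function(targets, signature, noise_sd = 0, seed = 1L) {
  stop_if_not(inherits(signature, "signature_map"),
              "signature must be a signature_map")
  if (is.numeric(targets)) targets <- data.frame(target = targets)
  stop_if_not("target" %in% names(targets), "targets must have a target column")
  wsq <- sum(signature$weights[signature$mask]^2)
  stop_if_not(wsq > 0, "signature weights are all zero")
  base <- signature$weights / wsq
  ids <- if (!is.null(rownames(targets)) &&
             !identical(rownames(targets), as.character(seq_len(nrow(targets)))))
    rownames(targets) else {
      idc <- setdiff(names(targets), "target")
      if (length(idc)) do.call(paste, c(targets[idc], sep = "_"))
      else sprintf("map%d", seq_len(nrow(targets)))
    }
  maps <- vector("list", nrow(targets))
  for (r in seq_len(nrow(targets))) {
    vals <- base * targets$target[r]
    if (noise_sd > 0) {
      with_seed(child_seed(seed, 6000001L, r), {
        vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim(vals))
      })
    }
    maps[[r]] <- volume_map(vals, signature$affine, signature$mask)
  }
  names(maps) <- ids
  maps
}
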