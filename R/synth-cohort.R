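#' Specify a synthetic twin cohort
#'
#' Defaults mirror the study cohort: 142 monozygotic (MZ) twin individuals,
#' 160 dizygotic (DZ) twin individuals and 93 singletons (395 participants in
#' 244 families).
#'
#' @param n_mz_individuals number of MZ twin individuals (must be even).
#' @param n_dz_individuals number of DZ twin individuals (must be even).
#' @param n_singletons number of participants without a co-twin in the sample.
#' @param seed integer root seed recorded with the cohort.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_individuals = 142L, n_dz_individuals = 160L,
                        n_singletons = 93L, seed = 1L) {
  stop_if_not(is_count(n_mz_individuals) && is_count(n_dz_individuals) &&
              is_count(n_singletons), "cohort counts must be nonnegative integers")
  stop_if_not(n_mz_individuals %% 2 == 0, "n_mz_individuals must be even (twins come in pairs)")
  stop_if_not(n_dz_individuals %% 2 == 0, "n_dz_individuals must be even (twins come in pairs)")
  structure(list(n_mz_individuals = as.integer(n_mz_individuals),
                 n_dz_individuals = as.integer(n_dz_individuals),
                 n_singletons = as.integer(n_singletons),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a participant table for a twin cohort
#'
#' MZ and DZ individuals are grouped into two-member families; singletons form
#' one-member families.  Identifiers are deterministic given the spec.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with columns `participant_id`, `family_id`,
#'   `zygosity` (one of "MZ", "DZ", "singleton").
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stop_if_not(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n_mz_fam <- spec$n_mz_individuals %/% 2L
  n_dz_fam <- spec$n_dz_individuals %/% 2L
  zyg <- c(rep("MZ", spec$n_mz_individuals), rep("DZ", spec$n_dz_individuals),
           rep("singleton", spec$n_singletons))
  fam_idx <- c(if (n_mz_fam) rep(seq_len(n_mz_fam), each = 2L),
               if (n_dz_fam) n_mz_fam + rep(seq_len(n_dz_fam), each = 2L),
               if (spec$n_singletons)
                 n_mz_fam + n_dz_fam + seq_len(spec$n_singletons))
  n <- length(zyg)
  out <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    family_id = sprintf("F%04d", fam_idx),
    zygosity = zyg,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- spec$seed
  out
}
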