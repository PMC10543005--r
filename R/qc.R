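#' Exclude trials by rating reaction time
#'
#' Drops trials whose pain-intensity rating reaction time is strictly above
#' 5.01 s (no response within the allotted window) or strictly below 0.02 s
#' (too fast to be a deliberate rating).  Boundary values are retained.
#' Missing reaction times are treated as non-responses and dropped.
#'
#' @param table trial table with an `rt_intensity` column (seconds).
#' @return list with elements `table` (retained trials) and `log` (an
#'   `exclusion_log`: counts in, dropped, out).
#' @export
exclude_trials_by_rt <- function(table) {
  stop_if_not("rt_intensity" %in% names(table), "rt_intensity column required")
  rt <- table$rt_intensity
  bad <- is.na(rt) | rt > 5.01 | rt < 0.02
  log <- structure(list(
    rule = "rt_intensity outside [0.02, 5.01] s (strict) or missing",
    n_trials_in = nrow(table),
    n_trials_dropped_rt = sum(bad),
    n_out = sum(!bad),
    dropped_fraction = if (nrow(table)) sum(bad) / nrow(table) else 0
  ), class = "exclusion_log")
  list(table = table[!bad, , drop = FALSE], log = log)
}

#' Exclude participants with incomplete condition sets
#'
#' After trial-level exclusions, a participant is retained only if, in each
#' of the four modality-by-condition cells, they still have at least one
#' trial at two or more of the three stimulus levels.  (Missing one level in
#' a single cell is tolerated; lacking two levels in any cell drops the
#' participant.)
#'
#' @param table trial table (trial exclusions already applied).
#' @return list with `table` (retained trials) and `log` (ids and per-cell
#'   reasons for every dropped participant).
#' @export
exclude_incomplete_participants <- function(table) {
  need <- c("participant_id", "modality", "condition", "stimulus_level")
  stop_if_not(all(need %in% names(table)), "trial table lacks design columns")
  cells <- expand.grid(modality = c("thermal", "mechanical"),
                       condition = c("placebo", "control"),
                       stringsAsFactors = FALSE)
  pids <- unique(table$participant_id)
  dropped <- character(0); reasons <- character(0)
  for (p in pids) {
    tp <- table[table$participant_id == p, ]
    for (ci in seq_len(nrow(cells))) {
      sel <- tp$modality == cells$modality[ci] & tp$condition == cells$condition[ci]
      n_levels <- length(unique(tp$stimulus_level[sel]))
      if (n_levels < 2) {
        dropped <- c(dropped, p)
        reasons <- c(reasons, sprintf(
          "%s/%s cell has trials at %d stimulus level(s); >= 2 required",
          cells$modality[ci], cells$condition[ci], n_levels))
        break
      }
    }
  }
  keep <- !(table$participant_id %in% dropped)
  log <- structure(list(
    rule = "complete sets: >= 2 stimulus levels in every modality x condition cell",
    n_trials_in = nrow(table),
    participants_in = length(pids),
    participants_dropped = data.frame(participant_id = dropped, reason = reasons,
                                      stringsAsFactors = FALSE),
    n_out = sum(keep)
  ), class = "exclusion_log")
  list(table = table[keep, , drop = FALSE], log = log)
}

#' Apply the full trial-then-participant exclusion protocol
#'
#' Fixed order: reaction-time trial exclusions first, then the participant
#' completeness rule on the surviving trials.  Both filters are idempotent.
#'
#' @param table trial table.
#' @return list with `table` and `logs` (one `exclusion_log` per stage).
#' @export
apply_qc <- function(table) {
  s1 <- exclude_trials_by_rt(table)
  s2 <- exclude_incomplete_participants(s1$table)
  list(table = s2$table, logs = list(rt = s1$log, completeness = s2$log))
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("exclusion rule:", x$rule, "\n")
  cat("  trials in: ", x$n_trials_in, "\n", sep = "")
  if (!is.null(x$n_trials_dropped_rt))
    cat(sprintf("  trials dropped: %d (%.2f%%)\n", x$n_trials_dropped_rt,
                100 * x$dropped_fraction))
  if (!is.null(x$participants_dropped) && nrow(x$participants_dropped)) {
    cat("  participants dropped:\n")
    for (i in seq_len(nrow(x$participants_dropped)))
      cat("    ", x$participants_dropped$participant_id[i], ": ",
          x$participants_dropped$reason[i], "\n", sep = "")
  }
  cat("  rows out: ", x$n_out, "\n", sep = "")
  invisible(x)
}
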