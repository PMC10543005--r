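#' @keywords internal
"_PACKAGE"

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child RNG seed from a root seed
#'
#' One root seed drives every simulation; independent child streams (per
#' family, per participant-run, per map) are derived by hashing the root seed
#' together with small integer indices.  The rule is a fixed multiplicative
#' hash modulo 2^31 - 1, so child seeds are reproducible, documented, and stay
#' inside R's 32-bit integer range.
#'
#' @param root integer root seed.
#' @param ... integer indices identifying the stream (e.g. participant index,
#'   run number).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, ...) {
  idx <- c(...)
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.numeric(root) %% m
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.numeric(idx[k]) * 16807 + k * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# run code under a child RNG stream without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
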