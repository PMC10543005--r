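#' Control parameters for the REML optimizer
#'
#' @param rel_tol relative convergence tolerance passed to the quasi-Newton
#'   optimizer (parameter/objective change criterion).
#' @param iter_max maximum number of iterations per start.
#' @param n_starts number of optimizer starts (one nominal start plus
#'   deterministic perturbations); the best converged solution is kept.
#' @param grad_tol gradient-norm threshold recorded in the convergence
#'   diagnostics.
#' @param boundary_tol a variance whose standard deviation falls below
#'   `boundary_tol * sd(y)` is flagged as a boundary (zero-variance) fit.
#' @return a list of class `reml_control`.
#' @export
reml_control <- function(rel_tol = 1e-12, iter_max = 1000L, n_starts = 3L,
                         grad_tol = 1e-6, boundary_tol = 1e-3) {
  structure(list(rel_tol = rel_tol, iter_max = as.integer(iter_max),
                 n_starts = as.integer(n_starts), grad_tol = grad_tol,
                 boundary_tol = boundary_tol),
            class = "reml_control")
}

# ---- parameter packing -----------------------------------------------------
# Each random block with k correlated terms carries an unstructured k x k
# covariance, parameterized by the log-Cholesky factor (diagonal on the log
# scale) so every iterate is positive definite.  The residual variance (or one
# variance per stratum) is parameterized as a log-variance.

n_chol_par <- function(k) k * (k + 1L) / 2L

chol_from_par <- function(par, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  L
}

par_from_cov <- function(G) {
  L <- t(chol(G))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# ---- design pre-compilation ------------------------------------------------
# Observations are independent across clusters (families); within a cluster
# the random part is U G U' with U the horizontal concatenation of the active
# random-effect units (one per grouping level with any nonzero design row).
# Clusters with bit-identical design cross-products are pooled so each
# likelihood evaluation costs O(#distinct designs), which makes balanced
# simulated cohorts (three distinct family types) essentially free.

compile_reml_design <- function(y, X, blocks, cluster, resid_strata = NULL) {
  n <- length(y)
  stop_if_not(is.matrix(X) && nrow(X) == n, "X must be a matrix with %d rows", n)
  stop_if_not(all(is.finite(y)), "y must be finite")
  cluster <- as.factor(cluster)
  stop_if_not(length(cluster) == n, "cluster must have length %d", n)
  if (!is.null(resid_strata)) {
    resid_strata <- as.factor(resid_strata)
    stop_if_not(length(resid_strata) == n, "resid_strata must have length %d", n)
  }
  for (b in blocks) {
    stop_if_not(is.matrix(b$Z) && nrow(b$Z) == n,
                "each block Z must be a matrix with %d rows", n)
    stop_if_not(length(b$group) == n, "each block group must have length %d", n)
  }
  p <- ncol(X)
  ks <- vapply(blocks, function(b) ncol(b$Z), integer(1))

  clusters <- split(seq_len(n), cluster, drop = TRUE)
  cl_info <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    idx <- clusters[[ci]]
    Ucols <- list(); ub <- integer(0)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      g <- droplevels(as.factor(b$group[idx]))
      for (lev in levels(g)) {
        rows <- which(g == lev)
        Zu <- matrix(0, length(idx), ks[bi])
        Zu[rows, ] <- b$Z[idx[rows], , drop = FALSE]
        if (any(Zu != 0)) {  # all-zero units (off-zygosity copies) are dropped
          Ucols[[length(Ucols) + 1L]] <- Zu
          ub <- c(ub, bi)
        }
      }
    }
    U <- if (length(Ucols)) do.call(cbind, Ucols) else matrix(0, length(idx), 0)
    Xc <- X[idx, , drop = FALSE]
    yc <- y[idx]
    # canonical row order: clusters with the same design (up to row
    # permutation) then yield bitwise-identical cross-products and pool
    ord <- do.call(order, c(asplit(cbind(Xc, U), 2), list(seq_along(idx))))
    idx <- idx[ord]; U <- U[ord, , drop = FALSE]
    Xc <- Xc[ord, , drop = FALSE]; yc <- yc[ord]
    info <- list(idx = idx, n = length(idx), unit_block = ub,
                 U = U, Xc = Xc, yc = yc,
                 UtU = crossprod(U), UtX = crossprod(U, Xc),
                 XtX = crossprod(Xc), Uty = drop(crossprod(U, yc)),
                 Xty = drop(crossprod(Xc, yc)), yty = sum(yc^2),
                 strata = if (is.null(resid_strata)) NULL else
                   as.integer(resid_strata[idx]))
    info$key <- paste(c(length(idx), ub,
                        sprintf("%.17g", c(info$UtU, info$UtX, info$XtX))),
                      collapse = "|")
    cl_info[[ci]] <- info
  }

  # pool clusters sharing a design (fast path: homoskedastic residual only)
  groups <- NULL
  if (is.null(resid_strata)) {
    keys <- vapply(cl_info, `[[`, character(1), "key")
    groups <- lapply(split(seq_along(cl_info), keys), function(ii) {
      rep_i <- cl_info[[ii[1]]]
      q <- ncol(rep_i$U)
      S_Uy <- matrix(0, q, 1); S_UyyU <- matrix(0, q, q)
      S_Xy <- numeric(p); S_yy <- 0
      for (j in ii) {
        uy <- cl_info[[j]]$Uty
        S_Uy <- S_Uy + uy
        if (q > 0) S_UyyU <- S_UyyU + tcrossprod(uy)
        S_Xy <- S_Xy + cl_info[[j]]$Xty
        S_yy <- S_yy + cl_info[[j]]$yty
      }
      list(m = length(ii), n_c = rep_i$n, q = q, unit_block = rep_i$unit_block,
           UtU = rep_i$UtU, UtX = rep_i$UtX, XtX = rep_i$XtX,
           S_Uy = S_Uy, S_UyyU = S_UyyU, S_Xy = S_Xy, S_yy = S_yy)
    })
  }

  n_strata <- if (is.null(resid_strata)) 1L else nlevels(resid_strata)
  list(y = y, X = X, n = n, p = p, ks = ks, block_names = names(blocks),
       n_blocks = length(blocks), clusters = cl_info, groups = groups,
       n_strata = n_strata,
       strata_levels = if (is.null(resid_strata)) NULL else levels(resid_strata),
       n_clusters = length(cl_info))
}

split_theta <- function(theta, ks, n_strata) {
  out <- list(blocks = vector("list", length(ks)))
  pos <- 0L
  for (bi in seq_along(ks)) {
    np <- n_chol_par(ks[bi])
    out$blocks[[bi]] <- theta[pos + seq_len(np)]
    pos <- pos + np
  }
  out$log_sig2 <- theta[pos + seq_len(n_strata)]
  out
}

# -2 * restricted log-likelihood; also returns the GLS pieces when asked.
neg2_reml <- function(theta, des, want_fit = FALSE) {
  BIG <- 1e10
  th <- split_theta(theta, des$ks, des$n_strata)
  covs <- vector("list", des$n_blocks)
  for (bi in seq_len(des$n_blocks)) {
    L <- chol_from_par(th$blocks[[bi]], des$ks[bi])
    if (any(!is.finite(L))) return(BIG)
    covs[[bi]] <- list(L = L, G = tcrossprod(L))
  }
  sig2 <- exp(th$log_sig2)
  if (any(!is.finite(sig2)) || any(sig2 <= 0)) return(BIG)

  p <- des$p
  A <- matrix(0, p, p); bvec <- numeric(p); quad <- 0; ld <- 0

  if (!is.null(des$groups) && des$n_strata == 1L) {
    s2 <- sig2[1]
    for (g in des$groups) {
      q <- g$q
      if (q == 0L) {
        A <- A + g$m * g$XtX / s2
        bvec <- bvec + g$S_Xy / s2
        quad <- quad + g$S_yy / s2
        ld <- ld + g$m * g$n_c * log(s2)
        next
      }
      # congruence form: with G = L L', the Woodbury core
      # (s2 G^{-1} + U'U)^{-1} equals L (s2 I + L'U'U L)^{-1} L', and
      # |V| = s2^(n-q) |s2 I + L'U'U L| — G is never inverted, so boundary
      # (near-zero variance) blocks cannot overflow
      Lg <- matrix(0, q, q)
      pos <- 0L
      for (bi in g$unit_block) {
        k <- des$ks[bi]; ii <- pos + seq_len(k)
        Lg[ii, ii] <- covs[[bi]]$L
        pos <- pos + k
      }
      Wt <- crossprod(Lg, g$UtU %*% Lg)
      diag(Wt) <- diag(Wt) + s2
      R <- tryCatch(chol(Wt), error = function(e) NULL)
      if (is.null(R)) return(BIG)
      M <- Lg %*% chol2inv(R) %*% t(Lg)
      ldW <- 2 * sum(log(diag(R)))
      MUX <- M %*% g$UtX
      A <- A + g$m * (g$XtX - crossprod(g$UtX, MUX)) / s2
      bvec <- bvec + (g$S_Xy - drop(crossprod(MUX, g$S_Uy))) / s2
      quad <- quad + (g$S_yy - sum(M * g$S_UyyU)) / s2
      ld <- ld + g$m * ((g$n_c - q) * log(s2) + ldW)
    }
  } else {
    # general path: dense per-cluster covariance (heteroskedastic strata)
    for (cl in des$clusters) {
      dvar <- if (is.null(cl$strata)) rep(sig2[1], cl$n) else sig2[cl$strata]
      V <- diag(dvar, cl$n)
      q <- ncol(cl$U)
      if (q > 0L) {
        Gi <- matrix(0, q, q); pos <- 0L
        for (bi in cl$unit_block) {
          k <- des$ks[bi]; ii <- pos + seq_len(k)
          Gi[ii, ii] <- covs[[bi]]$G
          pos <- pos + k
        }
        V <- V + cl$U %*% Gi %*% t(cl$U)
      }
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(R)) return(BIG)
      Zx <- backsolve(R, cl$Xc, transpose = TRUE)
      zy <- backsolve(R, cl$yc, transpose = TRUE)
      A <- A + crossprod(Zx)
      bvec <- bvec + drop(crossprod(Zx, zy))
      quad <- quad + sum(zy^2)
      ld <- ld + 2 * sum(log(diag(R)))
    }
  }

  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(BIG)
  ab <- backsolve(cA, bvec, transpose = TRUE)
  crit <- ld + 2 * sum(log(diag(cA))) + (quad - sum(ab^2)) +
    (des$n - p) * log(2 * pi)
  if (!is.finite(crit)) return(BIG)
  if (!want_fit) return(crit)
  Sigma_beta <- chol2inv(cA)
  beta <- drop(Sigma_beta %*% bvec)
  list(crit = crit, beta = beta, Sigma_beta = Sigma_beta)
}

# Analytic gradient of the -2 restricted log-likelihood (fast path only:
# homoskedastic residual, pooled design groups).  Uses the standard identity
#   d(-2 llR)/dtheta = tr(P dV) - u' dV u,   u = V^{-1}(y - X betahat),
# with every trace reduced to q x q group-level quantities via the Woodbury
# representation V^{-1} = (I - U M U')/sigma^2, M = (sigma^2 G^{-1} + U'U)^{-1}.
neg2_reml_with_grad <- function(theta, des) {
  BIG <- 1e10
  th <- split_theta(theta, des$ks, des$n_strata)
  Ls <- vector("list", des$n_blocks)
  for (bi in seq_len(des$n_blocks)) {
    L <- chol_from_par(th$blocks[[bi]], des$ks[bi])
    if (any(!is.finite(L))) return(list(value = BIG, grad = NULL))
    Ls[[bi]] <- L
  }
  s2 <- exp(th$log_sig2[1])
  if (!is.finite(s2) || s2 <= 0) return(list(value = BIG, grad = NULL))

  p <- des$p
  A <- matrix(0, p, p); bvec <- numeric(p); quad <- 0; ld <- 0
  gk <- vector("list", length(des$groups))  # per-group pieces for the gradient
  for (gi in seq_along(des$groups)) {
    g <- des$groups[[gi]]
    q <- g$q
    if (q == 0L) {
      A <- A + g$m * g$XtX / s2
      bvec <- bvec + g$S_Xy / s2
      quad <- quad + g$S_yy / s2
      ld <- ld + g$m * g$n_c * log(s2)
      gk[[gi]] <- list(q = 0L)
      next
    }
    # congruence form (see neg2_reml): never inverts G
    Lg <- matrix(0, q, q)
    pos <- 0L
    slot <- vector("list", length(g$unit_block))
    for (si in seq_along(g$unit_block)) {
      bi <- g$unit_block[si]
      k <- des$ks[bi]; ii <- pos + seq_len(k)
      Lg[ii, ii] <- Ls[[bi]]
      slot[[si]] <- ii
      pos <- pos + k
    }
    Wt <- crossprod(Lg, g$UtU %*% Lg)
    diag(Wt) <- diag(Wt) + s2
    R <- tryCatch(chol(Wt), error = function(e) NULL)
    if (is.null(R)) return(list(value = BIG, grad = NULL))
    M <- Lg %*% chol2inv(R) %*% t(Lg)
    K <- (diag(q) - M %*% g$UtU) / s2
    Ag <- (g$XtX - crossprod(g$UtX, M %*% g$UtX)) / s2
    A <- A + g$m * Ag
    bvec <- bvec + (g$S_Xy - drop(crossprod(M %*% g$UtX, g$S_Uy))) / s2
    quad <- quad + (g$S_yy - sum(M * g$S_UyyU)) / s2
    ld <- ld + g$m * ((g$n_c - q) * log(s2) + 2 * sum(log(diag(R))))
    gk[[gi]] <- list(q = q, M = M, K = K, Ag = Ag, slot = slot)
  }
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(list(value = BIG, grad = NULL))
  Ainv <- chol2inv(cA)
  beta <- drop(Ainv %*% bvec)
  crit <- ld + 2 * sum(log(diag(cA))) + (quad - sum(bvec * beta)) +
    (des$n - p) * log(2 * pi)
  if (!is.finite(crit)) return(list(value = BIG, grad = NULL))

  # gradient accumulation
  Qb <- lapply(des$ks, function(k) matrix(0, k, k))
  grad_s <- 0
  for (gi in seq_along(des$groups)) {
    g <- des$groups[[gi]]; pk <- gk[[gi]]
    if (pk$q == 0L) {
      rr <- g$S_yy - 2 * sum(beta * g$S_Xy) +
        g$m * drop(crossprod(beta, g$XtX %*% beta))
      trV <- g$m * g$n_c / s2
      XV2X <- g$m * g$XtX / s2^2
      grad_s <- grad_s + s2 * (trV - sum(Ainv * XV2X) - rr / s2^2)
      next
    }
    M <- pk$M; K <- pk$K
    UtXb <- drop(g$UtX %*% beta)
    C <- g$S_UyyU - tcrossprod(g$S_Uy, UtXb) - tcrossprod(UtXb, g$S_Uy) +
      g$m * tcrossprod(UtXb)
    B <- crossprod(K, g$UtX)            # U'V^{-1}X  (q x p)
    Q1 <- g$UtU %*% K                   # U'V^{-1}U
    Q2 <- B %*% Ainv %*% t(B)
    Q3 <- crossprod(K, C %*% K)
    Qtot <- g$m * (Q1 - Q2) - Q3
    for (si in seq_along(pk$slot)) {
      ii <- pk$slot[[si]]
      bi <- g$unit_block[si]
      Qb[[bi]] <- Qb[[bi]] + Qtot[ii, ii, drop = FALSE]
    }
    # residual-variance derivative pieces
    rr <- g$S_yy - 2 * sum(beta * g$S_Xy) +
      g$m * drop(crossprod(beta, g$XtX %*% beta))
    MC <- M %*% C
    uu <- (rr - 2 * sum(diag(MC)) + sum((M %*% g$UtU) * t(MC))) / s2^2
    trV <- g$m * (g$n_c - sum(M * g$UtU)) / s2
    XV2X <- g$m * (pk$Ag - crossprod(B, M %*% g$UtX)) / s2
    grad_s <- grad_s + s2 * (trV - sum(Ainv * XV2X) - uu)
  }

  grad <- numeric(length(theta))
  pos <- 0L
  for (bi in seq_len(des$n_blocks)) {
    k <- des$ks[bi]
    D <- (Qb[[bi]] + t(Qb[[bi]])) %*% Ls[[bi]]
    lt <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    gb <- D[lt]
    dg <- lt[, 1] == lt[, 2]
    gb[dg] <- gb[dg] * diag(Ls[[bi]])[lt[dg, 1]]
    grad[pos + seq_len(n_chol_par(k))] <- gb
    pos <- pos + n_chol_par(k)
  }
  grad[pos + 1L] <- grad_s
  list(value = crit, grad = grad)
}

numeric_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

numeric_hessian <- function(fn, x, h = 1e-5) {
  m <- length(x)
  H <- matrix(0, m, m)
  f0 <- fn(x)
  for (i in seq_len(m)) {
    ei <- numeric(m); ei[i] <- h
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < m) for (j in seq((i + 1), m)) {
      ej <- numeric(m); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Fit a variance-components linear mixed model by REML
#'
#' The engine behind the twin repeated-measures model.  Observations are
#' independent across `cluster` units (families); each random `block`
#' contributes, per level of its grouping factor, a vector of correlated
#' random coefficients with an unstructured covariance shared across levels.
#' Grouping levels whose design columns are identically zero inside a cluster
#' (the off-zygosity copies of the zygosity-split participant terms, and
#' singletons' individual terms) drop out of that cluster automatically, which
#' is what keeps the zygosity-specific covariance blocks identifiable.
#'
#' The REML criterion is maximized over a log-Cholesky parameterization (every
#' iterate positive definite) with a quasi-Newton optimizer and deterministic
#' restarts.  An optional `resid_strata` factor gives each stratum its own
#' residual variance (used e.g. for Welch-type heteroskedastic comparisons).
#'
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (with column names).
#' @param blocks named list of random blocks, each `list(Z = <n x k matrix>,
#'   group = <factor>)`.
#' @param cluster factor of independent sampling units (families).
#' @param resid_strata optional factor: one residual variance per level.
#' @param control a [reml_control()] list.
#' @return an object of class `reml_fit` with elements `beta`, `se`,
#'   `Sigma_beta`, `theta`, `vc` (variance components on the natural scale),
#'   `reml_loglik`, `objective` (the -2 restricted log-likelihood function of
#'   theta, used for Satterthwaite), `sigma_beta_fun`, and `convergence`.
#' @export
reml_fit <- function(y, X, blocks = list(), cluster,
                     resid_strata = NULL, control = reml_control()) {
  des <- compile_reml_design(y, X, blocks, cluster, resid_strata)
  stop_if_not(des$n_clusters >= 2 || des$n_blocks == 0,
              "at least 2 clusters are required to estimate random effects")
  n_par <- sum(vapply(des$ks, n_chol_par, numeric(1))) + des$n_strata

  # nominal start: split the OLS residual variance between strata and blocks
  ols <- stats::lm.fit(des$X, des$y)
  v0 <- max(sum(ols$residuals^2) / max(des$n - des$p, 1), 1e-8)
  start <- numeric(n_par)
  pos <- 0L
  for (bi in seq_len(des$n_blocks)) {
    k <- des$ks[bi]
    L0 <- diag(x = rep(0.5 * log(v0 / 2), k), nrow = k)
    start[pos + seq_len(n_chol_par(k))] <- L0[lower.tri(L0, diag = TRUE)]
    pos <- pos + n_chol_par(k)
  }
  start[pos + seq_len(des$n_strata)] <- log(v0 * 0.7)

  # box constraints on the unconstrained scale keep boundary (zero-variance)
  # fits numerically representable: log-sd floors at -20 (sd ~ 2e-9) and the
  # log residual variance at -40, far below any practical variance yet safe
  # against overflow of the block precision matrices
  lower <- numeric(n_par); upper <- rep(20, n_par)
  pos <- 0L
  for (bi in seq_len(des$n_blocks)) {
    k <- des$ks[bi]
    lw <- matrix(-30, k, k); diag(lw) <- -20
    lower[pos + seq_len(n_chol_par(k))] <- lw[lower.tri(lw, diag = TRUE)]
    upper[pos + seq_len(n_chol_par(k))] <- 30
    pos <- pos + n_chol_par(k)
  }
  lower[pos + seq_len(des$n_strata)] <- -40

  fn <- function(th) neg2_reml(th, des)
  fast <- !is.null(des$groups) && des$n_strata == 1L
  gr <- NULL
  if (fast) {
    # memoize the joint value/gradient computation: nlminb asks for both at
    # the same iterate
    memo <- new.env(parent = emptyenv())
    joint <- function(th) {
      if (!is.null(memo$th) && identical(th, memo$th)) return(memo$vg)
      vg <- neg2_reml_with_grad(th, des)
      memo$th <- th; memo$vg <- vg
      vg
    }
    fn <- function(th) joint(th)$value
    gr <- function(th) {
      vg <- joint(th)
      vg$grad %||% rep(0, length(th))
    }
  }
  starts <- list(start)
  if (control$n_starts >= 2L)
    for (s in seq(2L, control$n_starts)) {
      # deterministic perturbations (alternating +/-), not random draws,
      # so identical inputs give identical fits
      delta <- 0.6 * (-1)^(s + seq_len(n_par))
      starts[[s]] <- start + delta
    }

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, fn, gradient = gr, lower = lower, upper = upper,
                    control = list(rel.tol = control$rel_tol,
                                   iter.max = control$iter_max,
                                   eval.max = 10 * control$iter_max)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= 1e10) next
    if (is.null(best) || opt$objective < best$objective - 1e-10) best <- opt
  }
  if (is.null(best))
    stop("REML optimization failed to converge from any start; ",
         "check the design for rank deficiency or degenerate variance structure",
         call. = FALSE)

  theta <- best$par
  if (fast) {
    # Newton polish: the quasi-Newton stop rule leaves parameters ~1e-5 from
    # the optimum (objective-change criterion); a couple of damped Newton
    # steps on the analytic gradient tighten this to ~1e-9, which the
    # closed-form oracles require
    obj_cur <- best$objective
    for (it in 1:3) {
      g0 <- gr(theta)
      if (!all(is.finite(g0)) || sqrt(sum(g0^2)) < 1e-9) break
      mth <- length(theta)
      J <- matrix(NA_real_, mth, mth)
      for (i in seq_len(mth)) {
        e <- numeric(mth); e[i] <- 1e-4
        gp <- gr(theta + e); gm2 <- gr(theta - e)
        if (!all(is.finite(c(gp, gm2)))) break
        J[i, ] <- (gp - gm2) / 2e-4
      }
      if (anyNA(J)) break
      step <- tryCatch(solve((J + t(J)) / 2, g0), error = function(e) NULL)
      if (is.null(step)) break
      moved <- FALSE
      for (s in c(1, 0.5, 0.1)) {
        cand <- pmin(pmax(theta - s * step, lower), upper)
        fc <- fn(cand)
        if (is.finite(fc) && fc <= obj_cur) {
          theta <- cand; obj_cur <- fc; moved <- TRUE; break
        }
      }
      if (!moved) break
    }
    best$objective <- obj_cur
  }
  gnorm <- if (fast) sqrt(sum(gr(theta)^2)) else
    sqrt(sum(numeric_grad(fn, theta)^2))
  fit0 <- neg2_reml(theta, des, want_fit = TRUE)

  th <- split_theta(theta, des$ks, des$n_strata)
  vc <- list()
  for (bi in seq_len(des$n_blocks)) {
    L <- chol_from_par(th$blocks[[bi]], des$ks[bi])
    G <- tcrossprod(L)
    dimnames(G) <- list(colnames(blocks[[bi]]$Z), colnames(blocks[[bi]]$Z))
    vc[[des$block_names[bi] %||% paste0("block", bi)]] <- G
  }
  sig2 <- exp(th$log_sig2)
  names(sig2) <- des$strata_levels %||% "residual"
  vc$residual_var <- sig2

  sdy <- stats::sd(y)
  boundary <- any(unlist(lapply(vc[seq_len(des$n_blocks)], function(G)
    sqrt(diag(G)) < control$boundary_tol * sdy)))

  se <- sqrt(diag(fit0$Sigma_beta))
  names(fit0$beta) <- names(se) <- colnames(X)

  structure(list(
    beta = fit0$beta, se = se, Sigma_beta = fit0$Sigma_beta,
    theta = theta, vc = vc, reml_loglik = -0.5 * best$objective,
    objective = fn,
    gradient = if (fast) function(th) neg2_reml_with_grad(th, des)$grad else NULL,
    sigma_beta_fun = function(th) {
      r <- neg2_reml(th, des, want_fit = TRUE)
      if (is.list(r)) r$Sigma_beta else matrix(NA_real_, des$p, des$p)
    },
    convergence = list(code = best$convergence, message = best$message,
                       grad_norm = gnorm, boundary = boundary,
                       n_starts_used = length(starts)),
    n_obs = des$n, n_clusters = des$n_clusters, p = des$p,
    terms = colnames(X), cache = new.env(parent = emptyenv())
  ), class = "reml_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Satterthwaite degrees of freedom for a contrast
#'
#' Approximates the degrees of freedom of the Wald t statistic for
#' `c' beta` by the delta method: with `f(theta) = c' Sigma_beta(theta) c`,
#' `df = 2 f^2 / (g' A g)` where `g` is the gradient of `f` in the variance
#' parameters (central differences) and `A` the inverse of the observed REML
#' information (Hessian of the negative restricted log-likelihood by central
#' differences, step 1e-4 on the unconstrained scale; smaller steps are
#' dominated by floating-point roundoff in the second differences).
#'
#' @param fit a [reml_fit()] object.
#' @param contrast numeric contrast vector of length `fit$p`.
#' @return degrees of freedom (scalar); `Inf` with a warning if the
#'   information matrix is singular.
#' @export
satterthwaite_df <- function(fit, contrast) {
  stop_if_not(inherits(fit, "reml_fit"), "fit must be a reml_fit object")
  stop_if_not(length(contrast) == fit$p, "contrast must have length %d", fit$p)
  fvar <- function(th) drop(crossprod(contrast, fit$sigma_beta_fun(th) %*% contrast))
  f0 <- fvar(fit$theta)
  # component-wise central differences with adaptive fallback: near variance
  # boundaries a perturbed evaluation can fail, in which case a smaller step
  # or a one-sided difference anchored at the optimum is used
  g <- vapply(seq_along(fit$theta), function(i) {
    for (h in c(1e-4, 1e-5)) {
      e <- numeric(length(fit$theta)); e[i] <- h
      fp <- fvar(fit$theta + e); fm <- fvar(fit$theta - e)
      if (!anyNA(c(fp, fm))) return((fp - fm) / (2 * h))
      if (!is.na(fp)) return((fp - f0) / h)
      if (!is.na(fm)) return((f0 - fm) / h)
    }
    NA_real_
  }, numeric(1))
  # the observed-information inverse is contrast-free: cache it on the fit.
  # Boundary (zero-variance) parameters leave flat, numerically indefinite
  # directions in the observed information; those directions are dropped by a
  # positive-part pseudo-inverse (they carry no information about the
  # variance of the contrast variance).
  A <- fit$cache$info_inv
  if (is.null(A)) {
    H <- NULL
    if (!is.null(fit$gradient)) {
      # Jacobian of the analytic gradient: one central difference per
      # parameter, more accurate than second differences of the criterion
      m <- length(fit$theta)
      J <- matrix(NA_real_, m, m)
      for (i in seq_len(m)) {
        e <- numeric(m); e[i] <- 1e-4
        gp <- fit$gradient(fit$theta + e)
        gm <- fit$gradient(fit$theta - e)
        if (is.null(gp) || is.null(gm)) break
        J[i, ] <- (gp - gm) / 2e-4
      }
      if (!anyNA(J)) H <- 0.5 * (J + t(J)) / 2
    }
    if (is.null(H)) {  # fallback when a perturbed gradient is not evaluable
      H <- numeric_hessian(function(th) 0.5 * fit$objective(th), fit$theta,
                           h = 1e-4)
      # failed evaluations poison the criterion differences; treat as singular
      if (any(!is.finite(H)) || max(abs(H)) > 1e12) H <- matrix(0, 1, 1)
    }
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    keep <- e$values > 1e-6 * max(e$values, 0)
    if (!any(keep)) {
      warning("singular REML information matrix; reporting df = Inf")
      fit$cache$info_inv <- NA
      return(Inf)
    }
    A <- e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
    fit$cache$info_inv <- A
  } else if (!is.matrix(A)) {
    warning("singular REML information matrix; reporting df = Inf")
    return(Inf)
  }
  v <- drop(crossprod(g, A %*% g))
  if (anyNA(c(v, f0))) {
    warning("contrast variance not evaluable near the optimum; df = Inf")
    return(Inf)
  }
  if (v <= 0 || !is.finite(v)) {
    warning("non-positive variance of the contrast variance; df = Inf")
    return(Inf)
  }
  2 * f0^2 / v
}
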