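## Sparse mixed-model-equation REML engine.
##
## The residual log-likelihood is evaluated exactly through the sparse MME:
##   -2 logL = (n-p) log 2pi + log|C| + log|R| + sum_k log|G_k| + y'Py
## with C the full coefficient matrix (unpenalised fixed + group equations,
## penalised random blocks), using the determinant identity
## |C| = |X'V^-1 X| |V| / (|R| |G|).  For univariate models the residual
## variance is profiled out.  Variance parameters are estimated by
## safeguarded quasi-Newton (nlminb) on log-transformed ratios; sampling
## covariances come from the observed information (central-difference
## Hessian of -logL) at the optimum.

## ---- rank detection ---------------------------------------------------

## Sequential (order-respecting) detection of linearly dependent columns of
## M via incremental Cholesky of M'M; returns indices of dependent columns
## ("trailing" ones are dropped first in the sense that earlier columns win).
dependent_columns <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  G <- crossprod(M)
  k <- ncol(G)
  if (!k) return(integer(0))
  scale <- pmax(diag(G), 1)
  keep <- logical(k)
  L <- matrix(0, k, k)
  for (j in seq_len(k)) {
    idx <- which(keep[seq_len(j - 1L)])
    lj <- if (length(idx)) {
      forwardsolve(L[idx, idx, drop = FALSE], G[idx, j])
    } else numeric(0)
    d <- G[j, j] - sum(lj^2)
    if (d > tol * scale[j]) {
      keep[j] <- TRUE
      if (length(idx)) L[j, idx] <- lj
      L[j, j] <- sqrt(d)
    }
  }
  which(!keep)
}

## ---- univariate MME ---------------------------------------------------

## Build the univariate MME structure.
## X: dense fixed design (before rank reduction)
## ran: list of random terms, each list(name, Z (sparse nrec x q), Binv
##   (sparse prior precision at unit variance), qlog (count entering
##   q_k log gamma_k), logdetG0 (log|G_k| at unit variance), groups
##   (equation indices within the term that are unpenalised group equations))
## group_cols: dense matrix of explicit group covariates (records x groups)
##   used only for estimability detection (the Q-matrix view of the groups).
mme_build <- function(y, X, ran, weights = NULL, group_term = NULL,
                      group_cols = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  det_M <- if (!is.null(group_cols) && ncol(group_cols)) {
    cbind(X, group_cols)
  } else X
  dep <- dependent_columns(det_M)
  x_drop <- dep[dep <= ncol(X)]
  g_pin <- dep[dep > ncol(X)] - ncol(X)   # indices into group equations
  Xk <- X[, setdiff(seq_len(ncol(X)), x_drop), drop = FALSE]
  ## remove pinned group equations from the relevant random term
  if (length(g_pin) && !is.null(group_term)) {
    tr <- ran[[group_term]]
    pin_eq <- tr$groups[g_pin]
    keep_eq <- setdiff(seq_len(ncol(tr$Z)), pin_eq)
    tr$Z <- tr$Z[, keep_eq, drop = FALSE]
    tr$Binv <- tr$Binv[keep_eq, keep_eq, drop = FALSE]
    tr$groups <- match(setdiff(tr$groups, pin_eq), keep_eq)
    if (!is.null(tr$labels)) {
      tr$pinned_labels <- tr$labels[pin_eq]
      tr$labels <- tr$labels[keep_eq]
    }
    tr$pinned <- pin_eq
    ran[[group_term]] <- tr
  }
  ngroups_kept <- if (!is.null(group_term))
    length(ran[[group_term]]$groups) else 0L
  p <- ncol(Xk) + ngroups_kept
  ## error-contrast normalisation log|X*'X*| over the full unpenalised design
  ## (fixed columns plus explicit group-ancestry regressions): subtracting it
  ## from -2 logL makes the REML objective invariant to any full-rank
  ## reparameterisation of the unpenalised part, so values are comparable
  ## across the population-structure variants
  Xstar <- if (!is.null(group_cols) && ncol(group_cols)) {
    keep_g <- setdiff(seq_len(ncol(group_cols)), g_pin)
    cbind(Xk, group_cols[, keep_g, drop = FALSE])
  } else Xk
  ldetXX <- as.numeric(determinant(crossprod(Xstar),
                                   logarithm = TRUE)$modulus)
  W <- do.call(cbind, c(list(Matrix::Matrix(Xk, sparse = TRUE)),
                        lapply(ran, `[[`, "Z")))
  qs <- vapply(ran, function(t) ncol(t$Z), integer(1))
  offs <- ncol(Xk) + cumsum(c(0L, utils::head(qs, -1L)))
  names(offs) <- names(ran)
  sw <- sqrt(weights)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W * sw))
  Bs <- vector("list", length(ran))
  nc <- ncol(W)
  for (k in seq_along(ran)) {
    Bk <- methods::as(methods::as(ran[[k]]$Binv, "CsparseMatrix"),
                      "generalMatrix")
    Bs[[k]] <- Matrix::sparseMatrix(
      i = Bk@i + 1L + offs[k],
      j = rep(seq_len(ncol(Bk)), diff(Bk@p)) + offs[k],
      x = Bk@x, dims = c(nc, nc))
  }
  list(y = y, w = weights, Xk = Xk, W = W, WtW = WtW, Bs = Bs,
       ran = ran, offs = offs, qs = qs, n = n, p = p,
       rhs = Matrix::crossprod(W, weights * y),
       yy = sum(weights * y^2),
       logdetR0 = -sum(log(weights)),
       ldetXX = ldetXX,
       logdetG0 = sum(vapply(ran, `[[`, numeric(1), "logdetG0")),
       qlog = vapply(ran, `[[`, numeric(1), "qlog"),
       x_drop = x_drop, g_pin = g_pin)
}

mme_C <- function(m, gamma) {
  C <- m$WtW
  for (k in seq_along(m$Bs)) C <- C + m$Bs[[k]] * (1 / gamma[k])
  Matrix::forceSymmetric(C)
}

## One shared Cholesky symbolic factorisation per MME, updated numerically.
mme_factor <- function(m, C, cache) {
  if (is.null(cache$chol)) {
    cache$chol <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  } else {
    cache$chol <- Matrix::update(cache$chol, C)
  }
  cache$chol
}

## Profiled (residual variance concentrated out) -2 residual logL.
## gamma: variance ratios sigma2_k / sigma2_e, one per random term.
mme_nll2_prof <- function(m, gamma, cache) {
  C <- mme_C(m, gamma)
  ch <- tryCatch(mme_factor(m, C, cache), error = function(e) NULL)
  if (is.null(ch)) return(list(nll2 = 1e10))
  ldetC <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                              sqrt = TRUE)$modulus)
  sol <- Matrix::solve(ch, m$rhs, system = "A")
  ypy0 <- m$yy - sum(sol * m$rhs)
  if (ypy0 <= 0) return(list(nll2 = 1e10))
  np <- m$n - m$p
  s2e <- ypy0 / np
  nll2 <- np * (log(2 * pi) + 1) + np * log(s2e) + ldetC - m$ldetXX +
    sum(m$qlog * log(gamma)) + m$logdetG0 + m$logdetR0
  list(nll2 = nll2, s2e = s2e, sol = sol, chol = ch, ldetC = ldetC)
}

## Unprofiled -2 residual logL at absolute variances (ratios recomputed);
## used for the observed-information Hessian.
mme_nll2_abs <- function(m, vars, s2e, cache) {
  gamma <- vars / s2e
  C <- mme_C(m, gamma)
  ch <- tryCatch(mme_factor(m, C, cache), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ldetC <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                              sqrt = TRUE)$modulus)
  sol <- Matrix::solve(ch, m$rhs, system = "A")
  ypy0 <- m$yy - sum(sol * m$rhs)
  np <- m$n - m$p
  np * log(2 * pi) + np * log(s2e) + ldetC - m$ldetXX +
    sum(m$qlog * log(gamma)) + m$logdetG0 + m$logdetR0 + ypy0 / s2e
}

#' REML fitting control parameters
#'
#' @param rel_tol Relative convergence tolerance on the objective.
#' @param par_tol Relative parameter-change tolerance.
#' @param max_iter Iteration cap for the variance-parameter search.
#' @param gamma_floor Lower bound for a variance ratio; a parameter resting
#'   on it is reported as boundary-constrained (estimate effectively 0).
#' @param pql_max_iter,pql_tol Outer-loop controls for the binary
#'   (penalised quasi-likelihood) fit.
#' @param polish_dim Equation-count threshold below which the optimum is
#'   refined with analytic gradients (dense inverse of the coefficient
#'   matrix; high precision for small systems).
#' @return List of control values.
#' @export
reml_control <- function(rel_tol = 1e-10, par_tol = 1e-8, max_iter = 200,
                         gamma_floor = 1e-8, pql_max_iter = 50,
                         pql_tol = 1e-7, polish_dim = 800) {
  list(rel_tol = rel_tol, par_tol = par_tol, max_iter = max_iter,
       gamma_floor = gamma_floor, pql_max_iter = pql_max_iter,
       pql_tol = pql_tol, polish_dim = polish_dim)
}

## Analytic gradient of the profiled -2logL in log-ratio coordinates;
## uses the dense inverse of C, so it is reserved for systems small enough
## (<= polish_dim equations) to refine the quasi-Newton optimum to high
## precision.
mme_grad_prof <- function(m, lg) {
  gamma <- exp(lg)
  C <- as.matrix(mme_C(m, gamma))
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci)) return(rep(0, length(gamma)))
  rhs <- as.numeric(m$rhs)
  sol <- Ci %*% rhs
  ypy0 <- m$yy - sum(sol * rhs)
  np <- m$n - m$p
  vapply(seq_along(gamma), function(k) {
    Bk <- as.matrix(m$Bs[[k]])
    trk <- sum(Ci * Bk)
    sBs <- as.numeric(t(sol) %*% Bk %*% sol)
    (np * (-sBs / gamma[k]^2) / ypy0 - trk / gamma[k]^2 +
       m$qlog[k] / gamma[k]) * gamma[k]
  }, numeric(1))
}

## Maximise the profiled residual likelihood over log-ratios.
mme_reml <- function(m, start_gamma = NULL, control = reml_control()) {
  if (is.null(start_gamma)) {
    start_gamma <- vapply(m$ran, function(t)
      if (isTRUE(t$is_additive)) 0.5 else 0.1, numeric(1))
  }
  lo <- log(control$gamma_floor); hi <- log(1e8)
  cache <- new.env(parent = emptyenv())
  obj <- function(lg) mme_nll2_prof(m, exp(lg), cache)$nll2
  op <- stats::nlminb(log(pmin(pmax(start_gamma, exp(lo) * 2), exp(hi) / 2)),
                      obj, lower = lo, upper = hi,
                      control = list(rel.tol = control$rel_tol,
                                     x.tol = control$par_tol,
                                     iter.max = control$max_iter,
                                     eval.max = 10 * control$max_iter))
  ## analytic-gradient refinement (small systems): finite-difference
  ## gradients limit the attainable parameter precision of the first pass,
  ## so interior coordinates get a few Newton sweeps on the exact gradient
  if (ncol(m$W) <= control$polish_dim) {
    x <- op$par
    for (sweep in 1:6) {
      g <- mme_grad_prof(m, x)
      moved <- 0
      for (k in seq_along(x)) {
        if (x[k] <= lo + 1e-6 && g[k] > 0) next  # resting on the floor
        h <- 1e-4
        gp <- mme_grad_prof(m, replace(x, k, x[k] + h))[k]
        gm <- mme_grad_prof(m, replace(x, k, x[k] - h))[k]
        curv <- (gp - gm) / (2 * h)
        if (!is.finite(curv) || curv <= 0) next
        step <- max(min(g[k] / curv, 0.5), -0.5)
        x[k] <- min(max(x[k] - step, lo), hi)
        moved <- max(moved, abs(step))
      }
      if (moved < 1e-11) break
    }
    fx <- obj(x)
    if (is.finite(fx) && fx <= op$objective + 1e-9) {
      op$par <- x
      op$objective <- fx
    }
  }
  gamma <- exp(op$par)
  fin <- mme_nll2_prof(m, gamma, cache)
  boundary <- op$par <= lo + 1e-6
  converged <- op$convergence == 0 ||
    grepl("false convergence|singular convergence", op$message %||% "")
  list(m = m, gamma = gamma, s2e = fin$s2e, sol = fin$sol,
       chol = fin$chol, cache = cache,
       logLik = -fin$nll2 / 2, converged = converged,
       iterations = op$iterations, boundary = boundary,
       message = op$message)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## REML over absolute variances with the residual variance held fixed (the
## binary working-variate fit: binomial variance scale, dispersion handled
## outside the likelihood).
mme_reml_fixed <- function(m, s2e_fixed = 1, start_vars = NULL,
                           control = reml_control()) {
  if (is.null(start_vars)) {
    start_vars <- vapply(m$ran, function(t)
      if (isTRUE(t$is_additive)) 0.5 else 0.1, numeric(1)) * s2e_fixed
  }
  lo <- log(control$gamma_floor * s2e_fixed); hi <- log(1e8 * s2e_fixed)
  cache <- new.env(parent = emptyenv())
  obj <- function(lv) mme_nll2_abs(m, exp(lv), s2e_fixed, cache)
  op <- stats::nlminb(log(pmin(pmax(start_vars, exp(lo) * 2), exp(hi) / 2)),
                      obj, lower = lo, upper = hi,
                      control = list(rel.tol = control$rel_tol,
                                     x.tol = control$par_tol,
                                     iter.max = control$max_iter,
                                     eval.max = 10 * control$max_iter))
  vars <- exp(op$par)
  gamma <- vars / s2e_fixed
  C <- mme_C(m, gamma)
  ch <- mme_factor(m, C, cache)
  sol <- Matrix::solve(ch, m$rhs, system = "A")
  list(m = m, gamma = gamma, s2e = s2e_fixed, sol = sol, chol = ch,
       cache = cache, logLik = -obj(log(vars)) / 2,
       converged = op$convergence == 0 ||
         grepl("false convergence|singular convergence", op$message %||% ""),
       iterations = op$iterations,
       boundary = op$par <= lo + 1e-6, message = op$message,
       s2e_fixed = TRUE)
}

## Observed information of the variance parameters (vars..., s2e) by a
## central-difference Hessian of -logL; returns the sampling covariance.
mme_vcov_varcomp <- function(m, vars, s2e, cache = new.env()) {
  th <- c(vars, s2e)
  k <- length(th)
  f <- function(x) {
    if (any(x <= 0)) return(1e10)
    0.5 * mme_nll2_abs(m, x[-k], x[k], cache)
  }
  H <- num_hessian(f, th)
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  ## near-boundary / non-PD information: keep NA rather than nonsense
  if (!anyNA(cov) && any(diag(cov) < 0)) {
    ev <- eigen(H, symmetric = TRUE)
    pos <- pmax(ev$values, 1e-10 * max(abs(ev$values)))
    cov <- ev$vectors %*% diag(1 / pos, k) %*% t(ev$vectors)
  }
  cov
}

## Symmetric central-difference Hessian with relative steps.
num_hessian <- function(f, x, rel_step = 1e-3) {
  k <- length(x)
  h <- pmax(abs(x) * rel_step, 1e-10)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

## Prediction error variances: diagonal of the inverse coefficient matrix
## (absolute scale) at the requested equation indices, by chunked solves.
mme_pev <- function(m, chol, s2e, eq_idx, chunk = 256L) {
  nc <- ncol(m$W)
  out <- numeric(length(eq_idx))
  for (start in seq(1L, length(eq_idx), by = chunk)) {
    idx <- eq_idx[start:min(start + chunk - 1L, length(eq_idx))]
    E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx),
                              x = 1, dims = c(nc, length(idx)))
    S <- Matrix::solve(chol, E, system = "A")
    out[start:(start + length(idx) - 1L)] <-
      Matrix::colSums(E * S)
  }
  out * s2e
}
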