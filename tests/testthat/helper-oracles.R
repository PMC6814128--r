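## Shared fixtures and independent oracles (dense-matrix REML likelihoods,
## explicit group-regression fits) used across test files.

small_trial <- function(seed = 1, ...) {
  defaults <- list(n_provenances = 4, mothers_per_provenance = 6,
                   offspring_per_mother = 6, replicates = 4,
                   sets_per_replicate = 2)
  args <- utils::modifyList(defaults, list(...))
  simulate_trial(do.call(sim_config, args), seed = seed)
}

## random valid pedigree with OP structure and optional extra generation
random_pedigree <- function(n_founders, n_offspring, seed,
                            provenances = c("A", "B")) {
  set.seed(seed)
  founders <- sprintf("f%02d", seq_len(n_founders))
  ped <- data.frame(individual = founders, dam = NA_character_,
                    sire = NA_character_,
                    provenance = sample(provenances, n_founders, TRUE),
                    stringsAsFactors = FALSE)
  if (n_offspring) {
    off <- sprintf("o%02d", seq_len(n_offspring))
    dams <- sample(founders, n_offspring, TRUE)
    ped <- rbind(ped, data.frame(individual = off, dam = dams,
                                 sire = NA_character_,
                                 provenance = ped$provenance[match(dams, ped$individual)],
                                 stringsAsFactors = FALSE))
  }
  ped
}

## Dense-matrix REML -2logL for the univariate animal model, evaluated from
## first principles (V built explicitly; error-contrast normalised).
dense_nll2_uni <- function(vars, des, aug) {
  A <- build_A_tabular(aug)
  n <- length(des$y)
  Z <- matrix(0, n, nrow(A)); Z[cbind(seq_len(n), des$ind_idx)] <- 1
  Zr <- as.matrix(des$ran$replicate$Z); Zs <- as.matrix(des$ran$set$Z)
  V <- vars[["g"]] * Z %*% A %*% t(Z) +
    vars[["r"]] * tcrossprod(Zr) + vars[["s"]] * tcrossprod(Zs) +
    diag(vars[["e"]], n)
  if (!is.null(vars[["p"]]) && !is.na(vars[["p"]])) {
    Zp <- as.matrix(des$ran$provenance$Z)
    V <- V + vars[["p"]] * tcrossprod(Zp)
  }
  X <- des$X
  gc <- des$group_cols
  if (!is.null(gc) && ncol(gc)) X <- cbind(X, gc)
  X <- X[, setdiff(seq_len(ncol(X)), provblup:::dependent_columns(X)),
         drop = FALSE]
  p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric((n - p) * log(2 * pi) +
             determinant(V)$modulus + determinant(XVX)$modulus -
             determinant(crossprod(X))$modulus +
             t(des$y) %*% P %*% des$y)
}

## Explicit fixed-group fit at fixed variance ratios: groups as unpenalised
## columns built from the expected ancestry fractions, additive effect with
## A from the tabular method (unknown parents as founders).  Returns the
## profiled logL and the group-inclusive breeding values Q ghat + ahat.
explicit_group_fit <- function(des, aug, aug_none, gamma) {
  A <- build_A_tabular(aug_none)
  Q <- build_group_fractions(aug)
  ind <- match(des$tree, aug_none$ped$individual)
  n <- length(des$y)
  keep_info <- provblup:::dependent_columns(cbind(des$X, Q[ind, , drop = FALSE]))
  xd <- keep_info[keep_info <= ncol(des$X)]
  gp <- keep_info[keep_info > ncol(des$X)] - ncol(des$X)
  keptg <- setdiff(seq_len(ncol(Q)), gp)
  Xstar <- cbind(des$X[, setdiff(seq_len(ncol(des$X)), xd), drop = FALSE],
                 Q[ind, keptg, drop = FALSE])
  Zi <- Matrix::sparseMatrix(i = seq_len(n), j = ind, x = 1,
                             dims = c(n, nrow(A)))
  rn <- list(additive = list(name = "additive", Z = Zi,
                             Binv = Matrix::Matrix(solve(A), sparse = TRUE),
                             qlog = nrow(A),
                             logdetG0 = as.numeric(determinant(A)$modulus),
                             groups = integer(0),
                             labels = rownames(A), is_additive = TRUE),
             replicate = des$ran$replicate, set = des$ran$set)
  m <- provblup:::mme_build(des$y, Xstar, rn)
  cache <- new.env()
  r <- provblup:::mme_nll2_prof(m, gamma, cache)
  px <- ncol(m$Xk)
  ngk <- length(keptg)
  ghat <- as.numeric(r$sol[(px - ngk + 1):px])
  ahat <- as.numeric(r$sol[px + seq_len(nrow(A))])
  list(logLik = -r$nll2 / 2,
       ebv = as.numeric(Q[, keptg, drop = FALSE] %*% ghat) + ahat,
       labels = rownames(A))
}

## Group-augmented MME solutions at the same fixed ratios.
augmented_group_fit <- function(des, gamma) {
  m <- provblup:::mme_build(des$y, des$X, des$ran,
                            group_term = des$group_term,
                            group_cols = des$group_cols)
  cache <- new.env()
  r <- provblup:::mme_nll2_prof(m, gamma, cache)
  add <- m$ran$additive
  aidx <- m$offs[["additive"]] + seq_len(ncol(add$Z))
  sol_add <- stats::setNames(as.numeric(r$sol[aidx]), add$labels)
  list(logLik = -r$nll2 / 2,
       ebv = sol_add[setdiff(seq_along(sol_add), add$groups)])
}

## Dense-matrix REML -2logL for the stacked bivariate model.
dense_nll2_biv <- function(th, des1, des2, aug, couple_resid = TRUE) {
  A <- build_A_tabular(aug)
  n1 <- length(des1$y); n2 <- length(des2$y); n <- n1 + n2
  y <- c(des1$y, des2$y)
  Z1 <- matrix(0, n1, nrow(A)); Z1[cbind(seq_len(n1), des1$ind_idx)] <- 1
  Z2 <- matrix(0, n2, nrow(A)); Z2[cbind(seq_len(n2), des2$ind_idx)] <- 1
  V <- rbind(cbind(th[["g1"]] * Z1 %*% A %*% t(Z1),
                   th[["cg"]] * Z1 %*% A %*% t(Z2)),
             cbind(th[["cg"]] * Z2 %*% A %*% t(Z1),
                   th[["g2"]] * Z2 %*% A %*% t(Z2)))
  add_env <- function(V, idx, des, r, s, e) {
    Zr <- as.matrix(des$ran$replicate$Z); Zs <- as.matrix(des$ran$set$Z)
    V[idx, idx] <- V[idx, idx] + r * tcrossprod(Zr) + s * tcrossprod(Zs) +
      diag(e, length(idx))
    V
  }
  V <- add_env(V, seq_len(n1), des1, th[["r1"]], th[["s1"]], th[["e1"]])
  V <- add_env(V, n1 + seq_len(n2), des2, th[["r2"]], th[["s2"]], th[["e2"]])
  if (couple_resid) {
    common <- intersect(des1$tree, des2$tree)
    i1 <- match(common, des1$tree); i2 <- n1 + match(common, des2$tree)
    V[cbind(i1, i2)] <- V[cbind(i1, i2)] + th[["ce"]]
    V[cbind(i2, i1)] <- V[cbind(i2, i1)] + th[["ce"]]
  }
  xstar <- function(des) {
    X <- des$X
    if (!is.null(des$group_cols) && ncol(des$group_cols))
      X <- cbind(X, des$group_cols)
    X[, setdiff(seq_len(ncol(X)), provblup:::dependent_columns(X)),
      drop = FALSE]
  }
  X <- as.matrix(Matrix::bdiag(xstar(des1), xstar(des2)))
  p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric((n - p) * log(2 * pi) +
             determinant(V)$modulus + determinant(XVX)$modulus -
             determinant(crossprod(X))$modulus + t(y) %*% P %*% y)
}

## all set partitions of 1..n (for the exhaustive modularity oracle)
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

partition_membership <- function(p, n) {
  m <- integer(n)
  for (b in seq_along(p)) m[p[[b]]] <- b
  m
}
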