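## Bivariate animal-model REML: genetic covariances between two traits
## within a site, or one trait across two sites (GxE), with Kronecker
## (co)variance structures: unstructured 2x2 additive (x A), diagonal
## replicate and set-within-replicate blocks, and a residual 2x2 that is
## unstructured within site (trees carrying both traits) and diagonal across
## sites (no tree yields two records).

#' Bivariate animal model for two traits within one site
#'
#' Stacks the two traits' records and maximises the residual likelihood over
#' the additive (co)variance matrix G1 (Kronecker with the pedigree A),
#' trait-specific replicate and set-within-replicate variances, and the
#' residual (co)variance (covariance identified through trees measured for
#' both traits).  Records missing one trait are retained for the other.
#'
#' @param trait_i,trait_j Trait column names.
#' @param data Phenotype table (see [ablup()]).
#' @param pedigree Pedigree data frame or prebuilt [augment_pedigree()]
#'   result.
#' @param variant \code{"F"}, \code{"GC1"} or \code{"GC2"} (provenance fixed
#'   or contemporary genetic groups; the random-provenance variant is
#'   univariate-only).
#' @param site Optional site filter.
#' @param se Compute the observed-information covariance of all (co)variance
#'   parameters (needed for the SE of the genetic correlation).
#' @param start Optional named list with starting values \code{g}, \code{r},
#'   \code{s}, \code{e} (each length 2, e.g. from univariate fits).
#' @param control A [reml_control()] list.
#' @return An object of class \code{"ablup_biv"} with the genetic correlation
#'   in \code{$rg} (delta-method SE from the inverse information).
#' @export
ablup_pair <- function(trait_i, trait_j, data, pedigree,
                       variant = c("F", "GC1", "GC2"), site = NULL,
                       se = TRUE, start = NULL, control = reml_control()) {
  variant <- match.arg(variant)
  aug <- ablup_pedigree(pedigree, variant)
  des1 <- ablup_design(trait_i, data, aug, variant, site = site)
  des2 <- ablup_design(trait_j, data, aug, variant, site = site)
  biv_reml(des1, des2, aug, variant, c(trait_i, trait_j),
           couple_resid = TRUE, se = se, start = start, control = control)
}

#' Bivariate animal model for one trait across two sites
#'
#' Treats the trait's expression at each site as a separate trait.  The
#' residual covariance is fixed at zero (no tree grows on both sites); the
#' cross-site genetic covariance is identified through pedigree links
#' (families represented on both sites).
#'
#' @param trait Trait column name (present for both sites).
#' @param sites Length-2 character vector naming the sites.
#' @inheritParams ablup_pair
#' @export
ablup_xsite <- function(trait, data, pedigree, sites,
                        variant = c("F", "GC1", "GC2"),
                        se = TRUE, start = NULL, control = reml_control()) {
  variant <- match.arg(variant)
  stopifnot(length(sites) == 2L)
  aug <- ablup_pedigree(pedigree, variant)
  des1 <- ablup_design(trait, data, aug, variant, site = sites[1])
  des2 <- ablup_design(trait, data, aug, variant, site = sites[2])
  if (length(intersect(des1$tree, des2$tree)))
    stop("tree(s) appear on both sites; cross-site fit assumes disjoint trees")
  ## genetic connectedness: phenotyped trees on the two sites must share
  ## pedigree ancestors, otherwise the genetic covariance is unidentified
  anc <- function(des) {
    idx <- unique(des$ind_idx)
    out <- logical(nrow(aug$ped))
    while (length(idx)) {
      out[idx] <- TRUE
      idx <- unique(c(aug$dam_i[idx], aug$sire_i[idx]))
      idx <- idx[idx > 0]
      idx <- idx[!out[idx]]
    }
    which(out)
  }
  if (!length(intersect(anc(des1), anc(des2))))
    stop("no cross-site genetic connectedness (no shared families between sites)")
  biv_reml(des1, des2, aug, variant, paste(trait, sites, sep = "@"),
           couple_resid = FALSE, se = se, start = start, control = control)
}

## Shared bivariate REML machinery.
biv_reml <- function(des1, des2, aug, variant, trait_names, couple_resid,
                     se, start, control) {
  n1 <- length(des1$y); n2 <- length(des2$y)
  y <- c(des1$y, des2$y)
  n <- n1 + n2
  ng <- length(aug$groups)
  m_eq <- ng + nrow(aug$ped)

  ## per-trait estimability: drop dependent fixed columns, pin dependent
  ## group equations (deterministic, order-respecting)
  prep <- function(des) {
    gc <- if (!is.null(des$group_cols)) des$group_cols else
      matrix(0, length(des$y), 0)
    dep <- dependent_columns(cbind(des$X, gc))
    xd <- dep[dep <= ncol(des$X)]
    gp <- dep[dep > ncol(des$X)] - ncol(des$X)
    Xk <- des$X[, setdiff(seq_len(ncol(des$X)), xd), drop = FALSE]
    keep_g <- setdiff(seq_len(ng), gp)
    Xstar <- cbind(Xk, gc[, keep_g, drop = FALSE])
    list(Xk = Xk, g_pin = gp, keep_eq = setdiff(seq_len(m_eq), gp),
         p = ncol(Xk) + length(keep_g),
         ldetXX = as.numeric(determinant(crossprod(Xstar),
                                         logarithm = TRUE)$modulus))
  }
  p1 <- prep(des1); p2 <- prep(des2)
  Ainv <- build_Ainv_groups(aug)
  A1 <- Ainv[p1$keep_eq, p1$keep_eq, drop = FALSE]
  A2 <- Ainv[p2$keep_eq, p2$keep_eq, drop = FALSE]
  A12 <- Ainv[p1$keep_eq, p2$keep_eq, drop = FALSE]
  m1 <- length(p1$keep_eq); m2 <- length(p2$keep_eq)

  X <- Matrix::bdiag(Matrix::Matrix(p1$Xk, sparse = TRUE),
                     Matrix::Matrix(p2$Xk, sparse = TRUE))
  px <- ncol(X)
  Za1 <- Matrix::sparseMatrix(i = seq_len(n1),
                              j = match(ng + des1$ind_idx, p1$keep_eq),
                              x = 1, dims = c(n1, m1))
  Za2 <- Matrix::sparseMatrix(i = seq_len(n2),
                              j = match(ng + des2$ind_idx, p2$keep_eq),
                              x = 1, dims = c(n2, m2))
  Za <- Matrix::bdiag(Za1, Za2)
  Zr <- Matrix::bdiag(des1$ran$replicate$Z, des2$ran$replicate$Z)
  Zs <- Matrix::bdiag(des1$ran$set$Z, des2$ran$set$Z)
  qr1 <- ncol(des1$ran$replicate$Z); qr2 <- ncol(des2$ran$replicate$Z)
  qs1 <- ncol(des1$ran$set$Z); qs2 <- ncol(des2$ran$set$Z)
  W <- cbind(X, Za, Zr, Zs)
  nc <- ncol(W)
  off_a <- px; off_r <- px + m1 + m2; off_s <- off_r + qr1 + qr2

  ## residual pairing (within-site): records of the same tree
  pair1 <- pair2 <- integer(0)
  if (couple_resid) {
    common <- intersect(des1$tree, des2$tree)
    pair1 <- match(common, des1$tree)
    pair2 <- n1 + match(common, des2$tree)
  }
  npair <- length(pair1)
  single1 <- setdiff(seq_len(n1), pair1)
  single2 <- setdiff(n1 + seq_len(n2), pair2)
  t_of <- rep(1:2, c(n1, n2))

  ## -2 logL at natural parameters
  nind <- nrow(aug$ped)
  ldA <- logdet_A(aug)
  p <- p1$p + p2$p
  consts <- (n - p) * log(2 * pi) - p1$ldetXX - p2$ldetXX + 2 * ldA
  nll2 <- function(th) {
    g1 <- th[["g1"]]; g2 <- th[["g2"]]; cg <- th[["cg"]]
    e1 <- th[["e1"]]; e2 <- th[["e2"]]
    ce <- if (couple_resid) th[["ce"]] else 0
    detG <- g1 * g2 - cg^2
    detR <- e1 * e2 - ce^2
    if (detG <= 0 || detR <= 0 || g1 <= 0 || g2 <= 0 || e1 <= 0 || e2 <= 0)
      return(1e10)
    Gi <- matrix(c(g2, -cg, -cg, g1), 2) / detG
    ## residual precision
    rd <- c(rep(1 / e1, n1), rep(1 / e2, n2))
    ro <- numeric(0)
    if (npair) {
      rd[pair1] <- e2 / detR
      rd[pair2] <- e1 / detR
      ro <- rep(-ce / detR, npair)
    }
    Rinv <- Matrix::sparseMatrix(
      i = c(seq_len(n), pair1, pair2),
      j = c(seq_len(n), pair2, pair1),
      x = c(rd, ro, ro), dims = c(n, n))
    B <- rbind(cbind(Gi[1, 1] * A1, Gi[1, 2] * A12),
               cbind(Gi[2, 1] * Matrix::t(A12), Gi[2, 2] * A2))
    Bfull <- Matrix::bdiag(
      Matrix::Diagonal(px, 0), B,
      Matrix::Diagonal(qr1, 1 / th[["r1"]]),
      Matrix::Diagonal(qr2, 1 / th[["r2"]]),
      Matrix::Diagonal(qs1, 1 / th[["s1"]]),
      Matrix::Diagonal(qs2, 1 / th[["s2"]]))
    RW <- Rinv %*% W
    C <- Matrix::forceSymmetric(Matrix::crossprod(W, RW) + Bfull)
    ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldetC <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                sqrt = TRUE)$modulus)
    rhs <- Matrix::crossprod(RW, y)
    sol <- Matrix::solve(ch, rhs, system = "A")
    ypy <- sum(y * (Rinv %*% y)) - sum(sol * rhs)
    ldetR <- npair * log(detR) + sum(log(c(e1, e2)[t_of[c(single1, single2)]]))
    ldetGfull <- nind * log(detG) +
      qr1 * log(th[["r1"]]) + qr2 * log(th[["r2"]]) +
      qs1 * log(th[["s1"]]) + qs2 * log(th[["s2"]])
    val <- consts + ldetC + ldetR + ldetGfull + ypy
    attr(val, "sol") <- sol
    val
  }

  ## transformed parameterisation: log variances, atanh correlations
  par_names <- c("g1", "g2", "cg", "r1", "r2", "s1", "s2", "e1", "e2",
                 if (couple_resid) "ce")
  to_nat <- function(tp) {
    v <- exp(tp[1:2]); rg <- tanh(tp[3])
    out <- c(g1 = v[1], g2 = v[2], cg = rg * sqrt(v[1] * v[2]),
             r1 = exp(tp[4]), r2 = exp(tp[5]),
             s1 = exp(tp[6]), s2 = exp(tp[7]),
             e1 = exp(tp[8]), e2 = exp(tp[9]))
    if (couple_resid)
      out <- c(out, ce = tanh(tp[10]) * sqrt(out[["e1"]] * out[["e2"]]))
    out
  }
  vy1 <- stats::var(des1$y); vy2 <- stats::var(des2$y)
  st <- if (is.null(start)) {
    list(g = c(0.3 * vy1, 0.3 * vy2), r = c(0.05 * vy1, 0.05 * vy2),
         s = c(0.05 * vy1, 0.05 * vy2), e = c(0.6 * vy1, 0.6 * vy2))
  } else start
  tp0 <- c(log(st$g), 0, log(st$r), log(st$s), log(st$e),
           if (couple_resid) 0)
  zmax <- atanh(0.999)
  lo <- c(rep(log(1e-8 * max(vy1, vy2)), 2), -zmax, rep(log(1e-8 * max(vy1, vy2)), 6),
          if (couple_resid) -zmax)
  hi <- c(rep(log(1e8), 2), zmax, rep(log(1e8), 6), if (couple_resid) zmax)
  op <- stats::nlminb(tp0, function(tp) as.numeric(nll2(to_nat(tp))),
                      lower = lo, upper = hi,
                      control = list(rel.tol = control$rel_tol,
                                     iter.max = control$max_iter,
                                     eval.max = 10 * control$max_iter))
  th <- to_nat(op$par)
  fin <- nll2(th)
  logLik <- -as.numeric(fin) / 2
  t_free <- length(par_names)
  bent <- abs(th[["cg"]]) / sqrt(th[["g1"]] * th[["g2"]]) > 0.99 ||
    (couple_resid && abs(th[["ce"]]) / sqrt(th[["e1"]] * th[["e2"]]) > 0.99)
  vcov_th <- NULL
  if (se) {
    f <- function(x) {
      names(x) <- par_names
      0.5 * as.numeric(nll2(x))
    }
    H <- num_hessian(f, stats::setNames(as.numeric(th[par_names]), par_names))
    vcov_th <- tryCatch(solve(H), error = function(e)
      matrix(NA_real_, t_free, t_free))
    dimnames(vcov_th) <- list(par_names, par_names)
  }
  rg <- genetic_correlation(th[["cg"]], th[["g1"]], th[["g2"]],
                            cov = if (!is.null(vcov_th))
                              vcov_th[c("cg", "g1", "g2"), c("cg", "g1", "g2")])
  structure(list(traits = trait_names, variant = variant,
                 couple_resid = couple_resid,
                 G1 = matrix(c(th[["g1"]], th[["cg"]], th[["cg"]], th[["g2"]]), 2,
                             dimnames = list(trait_names, trait_names)),
                 components = th, vcov = vcov_th, rg = rg,
                 logLik = logLik, t_free = t_free,
                 aic = -2 * logLik + 2 * t_free,
                 n = n, p = p,
                 converged = op$convergence == 0 ||
                   grepl("false convergence|singular convergence",
                         op$message %||% ""),
                 iterations = op$iterations, bent = bent,
                 message = op$message),
            class = "ablup_biv")
}

#' @export
print.ablup_biv <- function(x, ...) {
  cat("Bivariate animal-model REML (ABLUP-", x$variant, "): ",
      paste(x$traits, collapse = " / "),
      if (!x$couple_resid) " [cross-site, residual covariance fixed 0]",
      "\n", sep = "")
  cat(sprintf("  r_G = %.3f (SE %s)\n", x$rg$value,
              ifelse(is.na(x$rg$se), "NA", sprintf("%.3f", x$rg$se))))
  cat("  logLik =", format(x$logLik, digits = 8), " n =", x$n, "\n")
  if (x$bent) cat("  note: correlation at boundary (bent)\n")
  invisible(x)
}

#' @export
summary.ablup_biv <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, object$t_free)
  out <- data.frame(estimate = as.numeric(object$components),
                    se = as.numeric(se),
                    row.names = names(object$components))
  cat("Bivariate components (", paste(object$traits, collapse = " / "),
      "):\n", sep = "")
  print(round(out, 4))
  cat(sprintf("r_G = %.3f (SE %s)\n", object$rg$value,
              ifelse(is.na(object$rg$se), "NA", sprintf("%.3f", object$rg$se))))
  invisible(out)
}

#' @export
logLik.ablup_biv <- function(object, ...) {
  structure(object$logLik, df = object$t_free, nobs = object$n,
            class = "logLik")
}
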