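## The animal-model fit: univariate REML / PQL under the four population
## structure treatments.

#' Fit a univariate animal model to a provenance/progeny trial
#'
#' Fits the individual-tree mixed model
#' \deqn{y = X\beta + Z g + Z r + Z r(s) + e}
#' with random additive genetic effects (covariance proportional to the
#' pedigree numerator relationship matrix A), random replicate and
#' set-within-replicate effects, and fixed intercept and control terms, by
#' REML on sparse mixed-model equations.  The population structure enters in
#' one of four ways:
#' \describe{
#'   \item{\code{"F"}}{provenance as a fixed term (reference-level coding);}
#'   \item{\code{"R"}}{provenance as an i.i.d. random term (enables Q_ST);}
#'   \item{\code{"GC1"}}{contemporary genetic groups in the pedigree with a
#'     common phantom paternal pollen group — the maternal unknown-parent slot
#'     points to the provenance group, the paternal slot to the pollen group;}
#'   \item{\code{"GC2"}}{contemporary genetic groups with both unknown slots
#'     pointing to the provenance group.}
#' }
#' Under the group variants breeding values are group-inclusive (the group
#' solution is absorbed into each individual's prediction).
#'
#' @param trait Name of the trait column in \code{data}.
#' @param data Phenotype data frame with columns \code{tree},
#'   \code{replicate}, \code{set}, \code{provenance}, optional \code{control}
#'   (control-lot label, empty/NA for pedigreed trees), optional \code{site},
#'   and one column per trait.  Records with a missing trait value are
#'   dropped.
#' @param pedigree Pedigree data frame (columns \code{individual, dam, sire,
#'   provenance}) or a prebuilt [augment_pedigree()] result consistent with
#'   \code{variant}.
#' @param variant One of \code{"F"}, \code{"R"}, \code{"GC1"}, \code{"GC2"}.
#' @param site Optional site label; if given and \code{data} has a
#'   \code{site} column, records are filtered to that site.
#' @param link \code{"identity"} for Gaussian traits, \code{"logit"} for a
#'   binary trait fitted by penalised quasi-likelihood with the residual
#'   variance fixed at 1 and an over/under-dispersion coefficient estimated.
#' @param pev Compute per-individual prediction error variances (needed for
#'   breeding-value accuracy); disable in simulation loops for speed.
#' @param se Compute the observed-information sampling covariance of the
#'   variance components (needed for standard errors of genetic parameters).
#' @param start Optional starting variance ratios (relative to the residual).
#' @param control A [reml_control()] list.
#' @return An object of class \code{"ablup"}; see [summary.ablup()].
#' @examples
#' trial <- simulate_trial(sim_config(n_provenances = 4, mothers_per_provenance = 6,
#'   offspring_per_mother = 6, replicates = 4, sets_per_replicate = 2), seed = 1)
#' fit <- ablup("growth", trial$phenotypes, trial$pedigree, variant = "F")
#' summary(fit)
#' @export
ablup <- function(trait, data, pedigree, variant = c("F", "R", "GC1", "GC2"),
                  site = NULL, link = c("identity", "logit"),
                  pev = TRUE, se = TRUE, start = NULL,
                  control = reml_control()) {
  variant <- match.arg(variant)
  link <- match.arg(link)
  cl <- match.call()
  aug <- ablup_pedigree(pedigree, variant)
  des <- ablup_design(trait, data, aug, variant, site = site)
  if (link == "logit") {
    fit <- pql_fit(des, start, control)
  } else {
    m <- mme_build(des$y, des$X, des$ran, group_term = des$group_term,
                   group_cols = des$group_cols)
    fit <- mme_reml(m, start, control)
  }
  finish_ablup(fit, des, aug, trait, variant, link, site, pev, se, cl,
               control)
}

## Resolve the pedigree argument into an augmented pedigree matching variant.
ablup_pedigree <- function(pedigree, variant) {
  if (inherits(pedigree, "augped")) {
    want <- switch(variant, GC1 = "GC1", GC2 = "GC2", "none")
    if (pedigree$scheme$mode != want)
      stop("augmented pedigree scheme '", pedigree$scheme$mode,
           "' does not match variant '", variant, "'")
    return(pedigree)
  }
  ped <- as_pedigree(pedigree)
  scheme <- switch(variant,
    GC1 = group_scheme("GC1", provenances = unique(ped$provenance)),
    GC2 = group_scheme("GC2", provenances = unique(ped$provenance)),
    group_scheme("none"))
  augment_pedigree(ped, scheme, ungrouped = "keep")
}

## Assemble response, fixed design and random-term structures for one trait.
ablup_design <- function(trait, data, aug, variant, site = NULL) {
  stopifnot(inherits(aug, "augped"))
  req <- c("tree", "replicate", "set")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (!trait %in% names(data)) stop("trait '", trait, "' not in data")
  if (!is.null(site)) {
    if (!"site" %in% names(data)) stop("no 'site' column to filter on")
    data <- data[data$site == site, , drop = FALSE]
    if (!nrow(data)) stop("no records for site '", site, "'")
  }
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (!nrow(data)) stop("no non-missing records for trait '", trait, "'")
  y <- as.numeric(data[[trait]])
  n <- nrow(data)
  tree <- as.character(data$tree)
  ind_idx <- match(tree, aug$ped$individual)
  if (anyNA(ind_idx))
    stop("tree(s) absent from pedigree: ",
         paste(utils::head(unique(tree[is.na(ind_idx)]), 5), collapse = ", "))
  ng <- length(aug$groups)

  ## fixed part: intercept, control-lot indicators, provenance dummies (F)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  ctl <- if ("control" %in% names(data)) as.character(data$control)
         else rep(NA_character_, n)
  ctl[!is.na(ctl) & ctl %in% c("", "0")] <- NA_character_
  lots <- sort(unique(ctl[!is.na(ctl)]))
  for (lot in lots)
    X <- cbind(X, `colnames<-`(matrix(as.numeric(!is.na(ctl) & ctl == lot)),
                               paste0("control", lot)))
  prov <- if ("provenance" %in% names(data)) as.character(data$provenance)
          else rep(NA_character_, n)
  prov[!is.na(prov) & prov == ""] <- NA_character_
  if (variant %in% c("F", "R") && all(is.na(prov)) &&
      any(!is.na(aug$ped$provenance)))
    prov <- aug$ped$provenance[ind_idx]
  if (variant == "F") {
    levs <- sort(unique(prov[!is.na(prov)]))
    for (p in levs[-1])
      X <- cbind(X, `colnames<-`(matrix(as.numeric(!is.na(prov) & prov == p)),
                                 paste0("provenance", p)))
  }

  ## random terms
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = ng + ind_idx, x = 1,
                             dims = c(n, ng + nrow(aug$ped)))
  ran <- list(additive = list(
    name = "additive", Z = Za, Binv = build_Ainv_groups(aug),
    qlog = nrow(aug$ped), logdetG0 = logdet_A(aug),
    groups = seq_len(ng), labels = c(aug$groups, aug$ped$individual),
    is_additive = TRUE))
  repf <- factor(as.character(data$replicate))
  ran$replicate <- iid_term("replicate", repf, n)
  setf <- factor(paste(as.character(data$replicate), as.character(data$set),
                       sep = ":"))
  ran$set <- iid_term("set", setf, n)
  if (variant == "R") {
    pf <- factor(prov)
    obs <- !is.na(pf)
    Zp <- Matrix::sparseMatrix(i = which(obs), j = as.integer(pf[obs]), x = 1,
                               dims = c(n, nlevels(pf)))
    ran$provenance <- list(name = "provenance", Z = Zp,
                           Binv = Matrix::Diagonal(nlevels(pf)),
                           qlog = nlevels(pf), logdetG0 = 0,
                           groups = integer(0), labels = levels(pf))
  }
  group_cols <- if (ng) {
    Q <- build_group_fractions(aug)
    Q[ind_idx, , drop = FALSE]
  } else NULL
  list(y = y, X = X, ran = ran, group_term = if (ng) "additive" else NULL,
       group_cols = group_cols, tree = tree, ind_idx = ind_idx,
       control = ctl, prov = prov, ng = ng, variant = variant,
       rep = repf, set = setf)
}

iid_term <- function(name, f, n) {
  list(name = name,
       Z = Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                                dims = c(n, nlevels(f))),
       Binv = Matrix::Diagonal(nlevels(f)), qlog = nlevels(f), logdetG0 = 0,
       groups = integer(0), labels = levels(f))
}

## Penalised quasi-likelihood fit for a binary trait on the logit scale.
## The working-variate REML holds the underlying residual variance fixed at
## the binomial value 1 (one record per tree confounds the Mendelian part of
## the additive variance with a free residual on the working scale); the
## over/under-dispersion coefficient theta is estimated afterwards by the
## quasi-likelihood Pearson moment estimator.
pql_fit <- function(des, start, control) {
  y <- des$y
  if (!all(y %in% c(0, 1))) stop("logit link needs a 0/1 response")
  if (length(unique(y)) < 2L) stop("binary response is constant")
  by_rep <- tapply(y, des$rep, function(v) length(unique(v)))
  if (any(by_rep == 1L))
    warning("complete separation: all-0 or all-1 response in ",
            sum(by_rep == 1L), " replicate stratum/strata")
  mu <- pmin(pmax(mean(y), 0.05), 0.95)
  eta <- rep(stats::qlogis(mu), length(y))
  vars <- start
  fit <- NULL
  for (it in seq_len(control$pql_max_iter)) {
    mu <- stats::plogis(pmin(pmax(eta, -10), 10))
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    m <- mme_build(z, des$X, des$ran, weights = w,
                   group_term = des$group_term, group_cols = des$group_cols)
    fit <- mme_reml_fixed(m, 1, vars, control)
    vars <- fit$gamma
    eta_new <- as.numeric(m$W %*% fit$sol)
    delta <- max(abs(eta_new - eta)) / max(1, max(abs(eta_new)))
    eta <- eta_new
    if (delta < control$pql_tol) break
  }
  mu <- stats::plogis(pmin(pmax(eta, -10), 10))
  fit$theta <- sum((y - mu)^2 / pmax(mu * (1 - mu), 1e-6)) /
    (fit$m$n - fit$m$p)
  fit$pql_iterations <- it
  fit$pql_converged <- delta < control$pql_tol
  fit
}

## Assemble the user-facing fit object from the engine output.
finish_ablup <- function(fit, des, aug, trait, variant, link, site,
                         pev, se, call, control) {
  m <- fit$m
  if (!fit$converged)
    warning("REML did not report convergence: ", fit$message)
  vars <- fit$gamma * fit$s2e
  vnames <- paste0("sigma2_", vapply(m$ran, `[[`, character(1), "name"))
  vnames[vnames == "sigma2_additive"] <- "sigma2_g"
  vnames[vnames == "sigma2_replicate"] <- "sigma2_r"
  vnames[vnames == "sigma2_set"] <- "sigma2_rs"
  vnames[vnames == "sigma2_provenance"] <- "sigma2_p"
  resname <- if (link == "logit") "theta" else "sigma2_e"
  res_val <- if (link == "logit") fit$theta else fit$s2e
  vc <- stats::setNames(c(vars, res_val), c(vnames, resname))
  t_free <- length(vc)
  vcov_vc <- NULL
  if (se) {
    if (isTRUE(fit$s2e_fixed)) {
      ## residual fixed at the binomial value: information over the
      ## variance components only; the moment dispersion gets no SE
      f <- function(x) {
        if (any(x <= 0)) return(1e10)
        0.5 * mme_nll2_abs(m, x, fit$s2e, fit$cache)
      }
      H <- num_hessian(f, vars)
      cv <- tryCatch(solve(H), error = function(e)
        matrix(NA_real_, length(vars), length(vars)))
      vcov_vc <- matrix(0, t_free, t_free)
      vcov_vc[seq_along(vars), seq_along(vars)] <- cv
      vcov_vc[t_free, ] <- vcov_vc[, t_free] <- 0
    } else {
      vcov_vc <- mme_vcov_varcomp(m, vars, fit$s2e, fit$cache)
    }
    dimnames(vcov_vc) <- list(names(vc), names(vc))
  }
  px <- ncol(m$Xk)
  beta <- stats::setNames(as.numeric(fit$sol[seq_len(px)]), colnames(m$Xk))
  add <- m$ran$additive
  aidx <- m$offs["additive"] + seq_len(ncol(add$Z))
  sol_add <- stats::setNames(as.numeric(fit$sol[aidx]), add$labels)
  ngk <- length(add$groups)
  group_effects <- if (ngk) sol_add[add$groups] else numeric(0)
  ebv <- sol_add[setdiff(seq_along(sol_add), add$groups)]
  other <- lapply(setdiff(names(m$ran), "additive"), function(nm) {
    idx <- m$offs[nm] + seq_len(m$qs[nm])
    stats::setNames(as.numeric(fit$sol[idx]), m$ran[[nm]]$labels)
  })
  names(other) <- setdiff(names(m$ran), "additive")
  pev_v <- NULL
  if (pev) {
    ph <- unique(des$ind_idx[is.na(des$control)])
    lab <- aug$ped$individual[ph]
    pos <- match(lab, add$labels)
    eq <- m$offs["additive"] + pos
    pev_v <- stats::setNames(mme_pev(m, fit$chol, fit$s2e, eq), lab)
  }
  structure(list(
    call = call, trait = trait, variant = variant, link = link, site = site,
    vc = vc, vcov_vc = vcov_vc, logLik = fit$logLik, t_free = t_free,
    aic = -2 * fit$logLik + 2 * t_free,
    n = m$n, p = m$p, beta = beta,
    dropped_fixed = colnames(des$X)[m$x_drop],
    pinned_groups = add$pinned_labels,
    group_effects = group_effects, ebv = ebv, ranef = other,
    pev = pev_v, gamma = fit$gamma, s2e = fit$s2e,
    boundary = stats::setNames(fit$boundary, vnames),
    converged = fit$converged, iterations = fit$iterations,
    pql_iterations = fit$pql_iterations,
    aug = aug, fitted = as.numeric(m$W %*% fit$sol),
    y = des$y, tree = des$tree, control_lot = des$control,
    mme = m, chol = fit$chol),
    class = "ablup")
}

#' @export
print.ablup <- function(x, ...) {
  cat("Animal-model REML fit (ABLUP-", x$variant, ", ", x$link,
      " link): trait ", x$trait,
      if (!is.null(x$site)) paste0(" at ", x$site), "\n", sep = "")
  cat("  n =", x$n, " records, logLik =", format(x$logLik, digits = 8),
      ", AIC =", format(x$aic, digits = 8), "\n")
  print(round(x$vc, 4))
  invisible(x)
}

#' Summarise an animal-model fit
#'
#' Reports the variance components with their standard errors, heritability
#' (by the formula matching the variant and link), mean breeding-value
#' accuracy over phenotyped non-control trees, Q_ST (variant \code{"R"}), and
#' AIC.
#'
#' @param object An \code{"ablup"} fit.
#' @param ... Unused.
#' @export
summary.ablup <- function(object, ...) {
  vc_se <- if (!is.null(object$vcov_vc)) sqrt(pmax(diag(object$vcov_vc), 0))
           else rep(NA_real_, length(object$vc))
  h2 <- tryCatch(heritability(object), error = function(e) NULL)
  qst <- if (object$variant == "R")
    tryCatch(qst(object), error = function(e) NULL) else NULL
  acc <- if (!is.null(object$pev))
    tryCatch(accuracy(object), error = function(e) NULL) else NULL
  structure(list(fit = object,
                 components = data.frame(estimate = unname(object$vc),
                                         se = unname(vc_se),
                                         boundary = c(object$boundary, FALSE),
                                         row.names = names(object$vc)),
                 h2 = h2, qst = qst, accuracy = acc),
            class = "summary.ablup")
}

#' @export
print.summary.ablup <- function(x, ...) {
  print(x$fit)
  cat("\nVariance components:\n")
  print(round(x$components[c("estimate", "se")], 4))
  if (any(x$components$boundary))
    cat("  (boundary-constrained: ",
        paste(rownames(x$components)[x$components$boundary], collapse = ", "),
        ")\n", sep = "")
  if (!is.null(x$h2))
    cat(sprintf("\nh2 = %.3f (SE %.3f)\n", x$h2$value, x$h2$se))
  if (!is.null(x$qst))
    cat(sprintf("Q_ST = %.3f (SE %.3f)%s\n", x$qst$value, x$qst$se,
                if (isTRUE(x$qst$significant)) " *" else ""))
  if (!is.null(x$accuracy))
    cat(sprintf("mean breeding-value accuracy r = %.3f\n", x$accuracy$value))
  invisible(x)
}

#' @export
coef.ablup <- function(object, ...) object$beta

#' @export
logLik.ablup <- function(object, ...) {
  structure(object$logLik, df = object$t_free, nobs = object$n,
            class = "logLik")
}

#' Akaike information criterion of a REML fit
#'
#' \code{-2 logL + 2 t} with t the number of free variance parameters.
#' Comparable across population-structure variants fitted to the same
#' records; the absolute value depends on the REML likelihood-constant
#' convention.
#'
#' @param object An \code{"ablup"} fit.
#' @param ... Unused.
#' @param k Penalty per parameter (2 = AIC).
#' @export
AIC.ablup <- function(object, ..., k = 2) -2 * object$logLik + k * object$t_free

#' @export
fitted.ablup <- function(object, ...) object$fitted

#' @export
residuals.ablup <- function(object, ...) {
  if (object$link == "logit") object$y - stats::plogis(object$fitted)
  else object$y - object$fitted
}

#' Extract estimated breeding values
#'
#' Under genetic-group variants the values are group-inclusive predictions
#' (the individual solution from the group-augmented equations).
#'
#' @param object An \code{"ablup"} fit.
#' @param ids Optional individual ids to extract.
#' @return Named numeric vector of EBVs.
#' @export
breeding_values <- function(object, ids = NULL) {
  stopifnot(inherits(object, "ablup"))
  if (is.null(ids)) object$ebv else object$ebv[ids]
}

#' @export
predict.ablup <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(breeding_values(object))
  breeding_values(object, as.character(newdata$tree))
}

#' Sampling covariance of the variance-component estimates
#'
#' Observed-information covariance matrix of the variance parameters
#' (the basis of all Taylor-series standard errors reported by the package).
#'
#' @param object An \code{"ablup"} fit.
#' @param ... Unused.
#' @export
vcov.ablup <- function(object, ...) {
  if (is.null(object$vcov_vc))
    stop("fit was run with se = FALSE; refit with se = TRUE")
  object$vcov_vc
}
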