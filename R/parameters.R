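## Genetic parameters derived from fitted variance components, with
## first-order Taylor-series (delta-method) standard errors propagated from
## the observed-information covariance of the components.

param_estimate <- function(value, se, tag, significant = NULL) {
  structure(list(value = value, se = se, tag = tag,
                 significant = significant), class = "param_estimate")
}

#' @export
print.param_estimate <- function(x, ...) {
  cat(x$tag, ": ", format(x$value, digits = 4),
      if (!is.na(x$se)) paste0(" (SE ", format(x$se, digits = 3), ")"),
      if (isTRUE(x$significant)) " *", "\n", sep = "")
  invisible(x)
}

## se of f(theta) given gradient and covariance (NULL -> NA)
delta_se <- function(grad, cov) {
  if (is.null(cov) || anyNA(cov)) return(NA_real_)
  sqrt(max(0, as.numeric(t(grad) %*% cov %*% grad)))
}

vc_cov <- function(vcov_vc, names) {
  if (is.null(vcov_vc)) return(NULL)
  vcov_vc[names, names, drop = FALSE]
}

#' Narrow-sense heritability
#'
#' Dispatches on the fit: for a Gaussian fit without a random provenance
#' term, \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} (replicate and
#' set variances excluded from the denominator); with a random provenance
#' term, \eqn{\sigma^2_g / (\sigma^2_p + \sigma^2_g + \sigma^2_e)}; for a
#' binary (logit) fit, \eqn{\sigma^2_g / (\sigma^2_g + \theta \pi^2/3)}.
#'
#' @param object An \code{"ablup"} fit.
#' @param ... Unused.
#' @return A parameter estimate (value, delta-method SE, formula tag).
#' @export
heritability <- function(object, ...) {
  stopifnot(inherits(object, "ablup"))
  vc <- object$vc
  if (object$link == "logit")
    return(heritability_binary(vc["sigma2_g"], vc["theta"],
                               vc_cov(object$vcov_vc, c("sigma2_g", "theta"))))
  if ("sigma2_p" %in% names(vc))
    return(heritability_with_provenance(
      vc["sigma2_p"], vc["sigma2_g"], vc["sigma2_e"],
      vc_cov(object$vcov_vc, c("sigma2_p", "sigma2_g", "sigma2_e"))))
  heritability_normal(vc["sigma2_g"], vc["sigma2_e"],
                      vc_cov(object$vcov_vc, c("sigma2_g", "sigma2_e")))
}

#' @rdname heritability
#' @param sigma2_g Additive genetic variance.
#' @param sigma2_e Residual variance.
#' @param cov Optional 2x2 (or 3x3) sampling covariance of the components in
#'   the order of the formula arguments; \code{NULL} gives an NA standard
#'   error.
#' @export
heritability_normal <- function(sigma2_g, sigma2_e, cov = NULL) {
  D <- sigma2_g + sigma2_e
  if (D <= 0) stop("heritability undefined: sigma2_g + sigma2_e = 0")
  grad <- c(sigma2_e, -sigma2_g) / D^2
  param_estimate(unname(sigma2_g / D), delta_se(grad, cov), "h2_normal")
}

#' @rdname heritability
#' @param sigma2_p Provenance (among-population) variance.
#' @export
heritability_with_provenance <- function(sigma2_p, sigma2_g, sigma2_e,
                                         cov = NULL) {
  D <- sigma2_p + sigma2_g + sigma2_e
  if (D <= 0) stop("heritability undefined: zero total variance")
  grad <- c(-sigma2_g, sigma2_p + sigma2_e, -sigma2_g) / D^2
  param_estimate(unname(sigma2_g / D), delta_se(grad, cov), "h2_with_prov")
}

#' @rdname heritability
#' @param theta Over/under-dispersion coefficient of the logit fit.
#' @export
heritability_binary <- function(sigma2_g, theta, cov = NULL) {
  if (theta <= 0) stop("dispersion theta must be positive")
  cc <- pi^2 / 3
  D <- sigma2_g + theta * cc
  grad <- c(theta * cc, -sigma2_g * cc) / D^2
  param_estimate(unname(sigma2_g / D), delta_se(grad, cov), "h2_binary")
}

#' Quantitative-trait population divergence Q_ST
#'
#' \eqn{Q_{ST} = \sigma^2_p / (\sigma^2_p + 2\sigma^2_g)} from a fit with a
#' random provenance term; flagged statistically significant when the value
#' exceeds twice its standard error.
#'
#' @param object An \code{"ablup"} fit with variant \code{"R"}, or a numeric
#'   provenance variance (then \code{sigma2_g} must be given).
#' @param sigma2_g Additive genetic variance (component interface).
#' @param cov Optional sampling covariance of (sigma2_p, sigma2_g).
#' @param ... Unused.
#' @export
qst <- function(object, sigma2_g = NULL, cov = NULL, ...) {
  if (inherits(object, "ablup")) {
    if (!"sigma2_p" %in% names(object$vc))
      stop("Q_ST needs a fit with a random provenance term (variant \"R\")")
    cov <- vc_cov(object$vcov_vc, c("sigma2_p", "sigma2_g"))
    sigma2_p <- object$vc["sigma2_p"]
    sigma2_g <- object$vc["sigma2_g"]
  } else sigma2_p <- object
  D <- sigma2_p + 2 * sigma2_g
  if (D <= 0) stop("Q_ST undefined: both components zero")
  grad <- c(2 * sigma2_g, -2 * sigma2_p) / D^2
  se <- delta_se(grad, cov)
  val <- unname(sigma2_p / D)
  param_estimate(val, se, "qst",
                 significant = if (!is.na(se)) val > 2 * se else NA)
}

#' Breeding-value accuracy
#'
#' Per-individual accuracy \eqn{r = \sqrt{1 - PEV/\sigma^2_g}} and its mean
#' over phenotyped non-control genotypes (the per-trait summary reported).
#' A PEV exceeding the additive variance is clamped to accuracy 0 with a
#' warning.
#'
#' @param object An \code{"ablup"} fit with prediction error variances, or a
#'   numeric vector of PEVs (then \code{sigma2_g} must be given).
#' @param sigma2_g Additive genetic variance (vector interface).
#' @param ... Unused.
#' @return A parameter estimate whose \code{value} is the mean accuracy, with
#'   the per-individual accuracies in \code{$per_individual}.
#' @export
accuracy <- function(object, sigma2_g = NULL, ...) {
  if (inherits(object, "ablup")) {
    if (is.null(object$pev))
      stop("fit was run with pev = FALSE; refit with pev = TRUE")
    pev <- object$pev
    sigma2_g <- object$vc[["sigma2_g"]]
  } else pev <- object
  if (sigma2_g <= 0) stop("accuracy undefined for sigma2_g <= 0")
  ratio <- pev / sigma2_g
  if (any(ratio > 1 + 1e-8))
    warning(sum(ratio > 1 + 1e-8),
            " PEV value(s) exceed sigma2_g; accuracy clamped to 0")
  r <- sqrt(pmax(0, 1 - ratio))
  out <- param_estimate(mean(r), NA_real_, "accuracy")
  out$per_individual <- r
  out
}

#' Genetic correlation from (co)variance components
#'
#' \eqn{r_G = \sigma_{g_ig_j} / \sqrt{\sigma^2_{g_i}\sigma^2_{g_j}}} with a
#' delta-method SE from the sampling covariance of the three components.
#'
#' @param cov_ij Additive genetic covariance between the traits.
#' @param var_i,var_j Additive genetic variances.
#' @param cov Optional 3x3 sampling covariance of (cov_ij, var_i, var_j).
#' @export
genetic_correlation <- function(cov_ij, var_i, var_j, cov = NULL) {
  if (var_i <= 0 || var_j <= 0)
    stop("genetic correlation undefined for non-positive variances")
  r <- cov_ij / sqrt(var_i * var_j)
  grad <- c(1 / sqrt(var_i * var_j), -r / (2 * var_i), -r / (2 * var_j))
  param_estimate(unname(r), delta_se(grad, cov), "rg")
}

#' Correlation of breeding values with latitude of origin
#'
#' Pearson correlation of individual EBVs with the latitude of their
#' provenance of origin, over pedigreed non-control individuals.
#'
#' @param ebv Named numeric vector of breeding values.
#' @param latitude Numeric vector of origin latitudes, aligned with
#'   \code{ebv}.
#' @export
latitude_ebv_correlation <- function(ebv, latitude) {
  ok <- !is.na(ebv) & !is.na(latitude)
  if (sum(ok) < 3L) stop("need at least 3 individuals")
  if (stats::sd(ebv[ok]) == 0 || stats::sd(latitude[ok]) == 0)
    stop("zero variance in EBVs or latitudes")
  stats::cor(ebv[ok], latitude[ok])
}
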