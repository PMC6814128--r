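## Orchestration: univariate and correlation suites over sites, traits and
## population-structure variants, plus ingestion of externally exported
## study tables.

#' Run the univariate analysis suite
#'
#' For every site x trait x variant combination: transforms ordinal traits to
#' normal scores (per site), fits the animal model, and collects variance
#' components with standard errors, heritability, breeding-value accuracy,
#' Q_ST (random-provenance variant) and AIC.  Individual fit failures are
#' recorded and the run continues.
#'
#' @param phenotypes Phenotype table (see [ablup()]).
#' @param pedigree Pedigree data frame.
#' @param traits Trait column names to analyse.
#' @param variants Subset of \code{c("F", "R", "GC1", "GC2")}.
#' @param sites Site labels to analyse separately; default all sites present
#'   (or a single unnamed site).
#' @param trait_types Optional named character vector
#'   (\code{"continuous"}, \code{"ordinal"}, \code{"binary"}) per trait;
#'   unnamed traits are treated as continuous.  Ordinal traits are
#'   normal-scored per site; binary traits use the logit link.
#' @param pev,se Passed to [ablup()].
#' @param out_dir Optional directory: writes one CSV per site plus a run
#'   manifest.
#' @param control A [reml_control()] list.
#' @return Data frame with one row per fit (component estimates and SEs,
#'   h2, accuracy, Q_ST, AIC, convergence status), with the run manifest in
#'   \code{attr(, "manifest")}.
#' @export
run_univariate_suite <- function(phenotypes, pedigree, traits,
                                 variants = c("F", "R", "GC1", "GC2"),
                                 sites = NULL, trait_types = NULL,
                                 pev = TRUE, se = TRUE, out_dir = NULL,
                                 control = reml_control()) {
  variants <- match.arg(variants, several.ok = TRUE)
  sites <- resolve_sites(phenotypes, sites)
  augs <- lapply(stats::setNames(nm = unique(variants)), function(v)
    ablup_pedigree(pedigree, v))
  rows <- list()
  for (site in sites) {
    dat <- site_data(phenotypes, site, traits, trait_types)
    for (trait in traits) {
      if (all(is.na(dat[[trait]]))) next
      type <- trait_type(trait, trait_types)
      link <- if (type == "binary") "logit" else "identity"
      for (v in variants) {
        fit <- tryCatch(
          ablup(trait, dat, augs[[v]], variant = v, link = link,
                pev = pev, se = se, control = control),
          error = function(e) e)
        rows[[length(rows) + 1L]] <-
          suite_row(fit, site, trait, v, link)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  manifest <- run_manifest(list(traits = traits, variants = variants,
                                sites = sites, trait_types = trait_types),
                           phenotypes, pedigree,
                           status = out[c("site", "trait", "variant",
                                          "converged")])
  attr(out, "manifest") <- manifest
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (site in sites) {
      f <- file.path(out_dir, paste0("univariate_",
                                     gsub("[^A-Za-z0-9]", "_", site), ".csv"))
      utils::write.csv(out[out$site == site, , drop = FALSE], f,
                       row.names = FALSE)
    }
    write_manifest(manifest, file.path(out_dir, "manifest.txt"))
  }
  out
}

resolve_sites <- function(phenotypes, sites) {
  if (!is.null(sites)) return(sites)
  if ("site" %in% names(phenotypes)) unique(phenotypes$site) else NA_character_
}

trait_type <- function(trait, trait_types) {
  if (!is.null(trait_types) && trait %in% names(trait_types))
    trait_types[[trait]] else "continuous"
}

## site subset with per-site normal scores for ordinal traits
site_data <- function(phenotypes, site, traits, trait_types) {
  dat <- if (is.na(site) || !"site" %in% names(phenotypes)) phenotypes
         else phenotypes[phenotypes$site == site, , drop = FALSE]
  for (trait in traits) {
    if (trait_type(trait, trait_types) == "ordinal" && trait %in% names(dat) &&
        !all(is.na(dat[[trait]])))
      dat[[trait]] <- normal_score(dat[[trait]])
  }
  dat
}

suite_row <- function(fit, site, trait, variant, link) {
  base <- data.frame(site = site, trait = trait, variant = variant,
                     link = link, stringsAsFactors = FALSE)
  comp_names <- c("sigma2_p", "sigma2_g", "sigma2_r", "sigma2_rs",
                  "sigma2_e", "theta")
  for (cn in comp_names) { base[[cn]] <- NA_real_; base[[paste0(cn, "_se")]] <- NA_real_ }
  base$h2 <- base$h2_se <- base$qst <- base$qst_se <- base$accuracy <-
    base$logLik <- base$aic <- NA_real_
  base$qst_significant <- NA
  if (inherits(fit, "error")) {
    base$converged <- FALSE
    base$error <- conditionMessage(fit)
    return(base)
  }
  se_v <- if (!is.null(fit$vcov_vc)) sqrt(pmax(diag(fit$vcov_vc), 0))
  for (cn in intersect(comp_names, names(fit$vc))) {
    base[[cn]] <- unname(fit$vc[cn])
    if (!is.null(se_v)) base[[paste0(cn, "_se")]] <- unname(se_v[cn])
  }
  h2 <- tryCatch(heritability(fit), error = function(e) NULL)
  if (!is.null(h2)) { base$h2 <- h2$value; base$h2_se <- h2$se }
  if (fit$variant == "R") {
    q <- tryCatch(qst(fit), error = function(e) NULL)
    if (!is.null(q)) {
      base$qst <- q$value; base$qst_se <- q$se
      base$qst_significant <- isTRUE(q$significant)
    }
  }
  if (!is.null(fit$pev)) {
    a <- tryCatch(accuracy(fit), error = function(e) NULL)
    if (!is.null(a)) base$accuracy <- a$value
  }
  base$logLik <- fit$logLik
  base$aic <- fit$aic
  base$converged <- fit$converged
  base$error <- NA_character_
  base
}

#' Run the correlation analysis suite
#'
#' Fits bivariate models for every within-site trait pair under each variant,
#' optionally fits the cross-site bivariate model per trait, compares the
#' variants' correlation matrices per site by a Mantel test, and detects
#' trait modules in each matrix.  Univariate fits supply starting values.
#'
#' @inheritParams run_univariate_suite
#' @param variants Subset of \code{c("F", "GC1", "GC2")} (two are compared in
#'   the Mantel step).
#' @param cross_site Fit the cross-site model per trait (needs exactly two
#'   sites).
#' @param n_perm,seed Mantel permutation settings.
#' @return List with \code{within} (pairwise r_G table), \code{matrices}
#'   (site -> variant -> correlation matrix), \code{cross_site} (per-trait
#'   r_G between sites), \code{mantel} (per-site comparison of the first two
#'   variants) and \code{modules}.
#' @export
run_correlation_suite <- function(phenotypes, pedigree, traits,
                                  variants = c("F", "GC1"), sites = NULL,
                                  trait_types = NULL, cross_site = TRUE,
                                  n_perm = 999, seed = 1L, se = TRUE,
                                  out_dir = NULL, control = reml_control()) {
  variants <- match.arg(variants, c("F", "GC1", "GC2"), several.ok = TRUE)
  sites <- resolve_sites(phenotypes, sites)
  augs <- lapply(stats::setNames(nm = unique(variants)), function(v)
    ablup_pedigree(pedigree, v))
  within <- list(); matrices <- list(); mantel_rows <- list()
  modules <- list()
  for (site in sites) {
    dat <- site_data(phenotypes, site, traits, trait_types)
    have <- traits[vapply(traits, function(tr)
      tr %in% names(dat) && !all(is.na(dat[[tr]])), logical(1))]
    matrices[[site]] <- list()
    for (v in variants) {
      ## univariate starts
      ustart <- lapply(stats::setNames(nm = have), function(tr)
        tryCatch(ablup(tr, dat, augs[[v]], variant = v, pev = FALSE,
                       se = FALSE, control = control),
                 error = function(e) NULL))
      Mt <- diag(length(have))
      dimnames(Mt) <- list(have, have)
      if (length(have) >= 2) {
        for (i in seq_len(length(have) - 1L)) for (j in (i + 1L):length(have)) {
          ti <- have[i]; tj <- have[j]
          st <- biv_start(ustart[[ti]], ustart[[tj]])
          bf <- tryCatch(
            ablup_pair(ti, tj, dat, augs[[v]], variant = v, se = se,
                       start = st, control = control),
            error = function(e) e)
          row <- data.frame(site = site, variant = v, trait_i = ti,
                            trait_j = tj, rg = NA_real_, rg_se = NA_real_,
                            converged = FALSE, error = NA_character_,
                            stringsAsFactors = FALSE)
          if (inherits(bf, "error")) {
            row$error <- conditionMessage(bf)
          } else {
            row$rg <- bf$rg$value; row$rg_se <- bf$rg$se
            row$converged <- bf$converged
            Mt[ti, tj] <- Mt[tj, ti] <- bf$rg$value
          }
          within[[length(within) + 1L]] <- row
        }
      }
      matrices[[site]][[v]] <- Mt
      md <- tryCatch(detect_modules(Mt), error = function(e) NULL)
      if (!is.null(md))
        modules[[length(modules) + 1L]] <-
          data.frame(site = site, variant = v, trait = names(md$membership),
                     module = md$membership, q_mod = md$q_mod,
                     stringsAsFactors = FALSE)
    }
    if (length(variants) >= 2) {
      mt <- mantel_test(matrices[[site]][[variants[1]]],
                        matrices[[site]][[variants[2]]],
                        n_perm = n_perm, seed = seed)
      mantel_rows[[length(mantel_rows) + 1L]] <-
        data.frame(site = site, variant_a = variants[1],
                   variant_b = variants[2], statistic = mt$statistic,
                   p_value = mt$p_value, stringsAsFactors = FALSE)
    }
  }
  xrows <- list()
  if (cross_site && length(sites) == 2L) {
    ## normal scores stay per site for the stacked cross-site table
    xdat <- do.call(rbind, lapply(sites, function(s)
      site_data(phenotypes, s, traits, trait_types)))
    for (v in variants) for (tr in traits) {
      bf <- tryCatch(
        ablup_xsite(tr, xdat, augs[[v]], sites = sites, variant = v, se = se,
                    control = control),
        error = function(e) e)
      row <- data.frame(trait = tr, variant = v, rg = NA_real_,
                        rg_se = NA_real_, converged = FALSE,
                        error = NA_character_, stringsAsFactors = FALSE)
      if (inherits(bf, "error")) row$error <- conditionMessage(bf)
      else {
        row$rg <- bf$rg$value; row$rg_se <- bf$rg$se
        row$converged <- bf$converged
      }
      xrows[[length(xrows) + 1L]] <- row
    }
  }
  res <- list(within = do.call(rbind, within),
              matrices = matrices,
              cross_site = if (length(xrows)) do.call(rbind, xrows),
              mantel = if (length(mantel_rows)) do.call(rbind, mantel_rows),
              modules = if (length(modules)) do.call(rbind, modules))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in c("within", "cross_site", "mantel", "modules"))
      if (!is.null(res[[nm]]))
        utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
  }
  res
}

biv_start <- function(f1, f2) {
  if (is.null(f1) || is.null(f2)) return(NULL)
  list(g = c(f1$vc[["sigma2_g"]], f2$vc[["sigma2_g"]]),
       r = c(f1$vc[["sigma2_r"]], f2$vc[["sigma2_r"]]),
       s = c(f1$vc[["sigma2_rs"]], f2$vc[["sigma2_rs"]]),
       e = c(f1$vc[["sigma2_e"]], f2$vc[["sigma2_e"]]))
}

#' Ingest externally exported study tables
#'
#' Reads a pedigree CSV and one phenotype CSV per site (e.g. sheets of a
#' study workbook exported to CSV), renaming columns according to an explicit
#' mapping so no external layout is hard-coded.
#'
#' @param pedigree_path CSV with the maternal pedigree.
#' @param phenotype_paths Named character vector of CSV paths, one per site
#'   (names are the site labels).
#' @param mapping Named list: standard column name (\code{individual},
#'   \code{dam}, \code{sire}, \code{provenance}, \code{tree},
#'   \code{replicate}, \code{set}, \code{control}, and one entry per trait)
#'   -> column name in the files.  Unmapped required columns raise an error
#'   listing the candidate columns found.
#' @return List with \code{pedigree} and \code{phenotypes} (the per-site
#'   tables row-bound with a \code{site} column).
#' @export
ingest_study_tables <- function(pedigree_path, phenotype_paths, mapping) {
  remap <- function(df, wanted, where) {
    for (std in wanted) {
      src <- mapping[[std]]
      if (is.null(src) || !src %in% names(df))
        stop("no mapping for required column '", std, "' in ", where,
             "; candidates: ", paste(names(df), collapse = ", "))
      names(df)[names(df) == src] <- std
    }
    df
  }
  ped <- utils::read.csv(pedigree_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  ped <- as_pedigree(remap(ped, c("individual", "dam", "sire", "provenance"),
                           "pedigree"))
  phen <- lapply(names(phenotype_paths), function(site) {
    df <- utils::read.csv(phenotype_paths[[site]], stringsAsFactors = FALSE)
    required <- c("tree", "replicate", "set")
    optional <- setdiff(names(mapping), c("individual", "dam", "sire",
                                          required))
    optional <- optional[vapply(optional, function(w)
      !is.null(mapping[[w]]) && mapping[[w]] %in% names(df), logical(1))]
    df <- remap(df, c(required, optional), site)
    df$site <- site
    df
  })
  common <- Reduce(intersect, lapply(phen, names))
  phen <- do.call(rbind, lapply(phen, function(df) {
    for (nm in setdiff(unique(unlist(lapply(phen, names))), names(df)))
      df[[nm]] <- NA
    df[union(common, setdiff(names(df), common))]
  }))
  list(pedigree = ped, phenotypes = phen)
}

## run manifest: digests of inputs + per-fit status (no timestamps, so
## identical inputs reproduce the manifest bit for bit)
run_manifest <- function(config, phenotypes, pedigree, status) {
  dig <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
  }
  list(package_version = tryCatch(
         as.character(utils::packageVersion("provblup")),
         error = function(e) "dev"),
       config_digest = dig(config),
       phenotype_digest = dig(phenotypes),
       pedigree_digest = dig(pedigree),
       fits = status)
}

write_manifest <- function(manifest, path) {
  lines <- c(paste0("package_version=", manifest$package_version),
             paste0("config_digest=", manifest$config_digest),
             paste0("phenotype_digest=", manifest$phenotype_digest),
             paste0("pedigree_digest=", manifest$pedigree_digest),
             "fits:",
             apply(manifest$fits, 1, function(r)
               paste0("  ", paste(r, collapse = "\t"))))
  writeLines(lines, path)
  invisible(path)
}
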