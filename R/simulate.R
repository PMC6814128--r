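## Synthetic open-pollinated provenance/progeny trial generator: the
## generative counterpart of the analysis model, with known truth stored for
## recovery tests.

#' Configuration for a synthetic provenance/progeny trial
#'
#' Defaults emulate the study design this package targets: a provenance test
#' with 30 replications of 7 sets, each set holding open-pollinated families
#' plus 2 control lots, provenances represented equally within each set, and
#' provenance origins spanning 36-48 degrees N.
#'
#' @param n_provenances Number of provenances.
#' @param mothers_per_provenance Open-pollinated families per provenance.
#' @param offspring_per_mother Offspring per family per site.
#' @param replicates Replications per site.
#' @param sets_per_replicate Sets nested within each replication; families
#'   are assigned to sets round-robin within provenance so each provenance is
#'   represented in every set.
#' @param n_controls Number of control lots (clonally repeated checks without
#'   pedigree, one ramet per set per replicate).
#' @param mu Trait mean.
#' @param sigma2_g Additive genetic variance within provenances.
#' @param sigma2_p Among-provenance variance; if \code{NULL}, derived from
#'   \code{qst}.
#' @param qst Target \eqn{Q_{ST} = \sigma^2_p/(\sigma^2_p + 2\sigma^2_g)}
#'   used when \code{sigma2_p} is \code{NULL} (default 0.2).
#' @param h2 Target single-site narrow-sense heritability
#'   \eqn{\sigma^2_g/(\sigma^2_g+\sigma^2_e)} used when \code{sigma2_e} is
#'   \code{NULL} (default 0.3).
#' @param sigma2_e Residual variance; if \code{NULL}, derived from \code{h2}.
#' @param sigma2_r,sigma2_rs Replicate and set-within-replicate variances.
#' @param pollen \code{"local"}: pollen parents are random males of the
#'   mother's provenance; \code{"common"}: every offspring draws its pollen
#'   parent from one common pool shared by all provenances (the long-distance
#'   pollen-flow situation the GC1 scheme models).
#' @param delta_pollen Mean breeding value of the common pollen pool relative
#'   to the local populations (only with \code{pollen = "common"}).
#' @param sigma2_pollen Additive variance of the common pollen pool.
#' @param latitude_range Range of provenance origin latitudes (degrees N).
#' @param cline_slope Deterministic linear latitude cline in the provenance
#'   effects (trait units per degree); the random among-provenance deviation
#'   keeps variance \code{sigma2_p}.
#' @param cross_site_rg Cross-site additive genetic correlation; \code{NULL}
#'   simulates a single site, a value in [-1, 1] simulates two sites.
#' @param traits Named list of trait definitions, each
#'   \code{list(type = "continuous")}, \code{list(type = "ordinal", k = 9)}
#'   or \code{list(type = "binary", prevalence = 0.5)}.
#' @param trait_cor Genetic correlation matrix among the traits' latent
#'   values (default: independent).
#' @return A \code{"sim_config"} list.
#' @export
sim_config <- function(n_provenances = 14, mothers_per_provenance = 17,
                       offspring_per_mother = 30, replicates = 30,
                       sets_per_replicate = 7, n_controls = 2,
                       mu = 10,
                       sigma2_g = 1, sigma2_p = NULL, qst = 0.2,
                       h2 = 0.3, sigma2_e = NULL,
                       sigma2_r = 0.10, sigma2_rs = 0.05,
                       pollen = c("local", "common"), delta_pollen = 0,
                       sigma2_pollen = sigma2_g,
                       latitude_range = c(36, 48), cline_slope = 0,
                       cross_site_rg = NULL,
                       traits = list(growth = list(type = "continuous")),
                       trait_cor = NULL) {
  pollen <- match.arg(pollen)
  if (is.null(sigma2_p)) {
    stopifnot(qst >= 0, qst < 1)
    sigma2_p <- 2 * sigma2_g * qst / (1 - qst)
  }
  if (is.null(sigma2_e)) {
    stopifnot(h2 > 0, h2 <= 1)
    sigma2_e <- sigma2_g * (1 - h2) / h2
  }
  stopifnot(sigma2_g >= 0, sigma2_p >= 0, sigma2_e >= 0, sigma2_r >= 0,
            sigma2_rs >= 0, offspring_per_mother >= 1)
  if (!is.null(cross_site_rg)) stopifnot(abs(cross_site_rg) <= 1)
  nt <- length(traits)
  if (!nt || is.null(names(traits)) || any(names(traits) == ""))
    stop("traits must be a named list")
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    if (!tr$type %in% c("continuous", "ordinal", "binary"))
      stop("unknown trait type for '", tn, "'")
    if (tr$type == "ordinal" && (is.null(tr$k) || tr$k < 2L))
      stop("ordinal trait '", tn, "' needs k >= 2 classes")
    if (tr$type == "binary" && is.null(tr$prevalence))
      traits[[tn]]$prevalence <- 0.5
  }
  if (is.null(trait_cor)) trait_cor <- diag(nt)
  stopifnot(nrow(trait_cor) == nt, isSymmetric(unname(trait_cor)))
  structure(list(n_provenances = n_provenances,
                 mothers_per_provenance = mothers_per_provenance,
                 offspring_per_mother = offspring_per_mother,
                 replicates = replicates,
                 sets_per_replicate = sets_per_replicate,
                 n_controls = n_controls, mu = mu,
                 sigma2_g = sigma2_g, sigma2_p = sigma2_p,
                 sigma2_e = sigma2_e, sigma2_r = sigma2_r,
                 sigma2_rs = sigma2_rs,
                 pollen = pollen, delta_pollen = delta_pollen,
                 sigma2_pollen = sigma2_pollen,
                 latitude_range = latitude_range, cline_slope = cline_slope,
                 cross_site_rg = cross_site_rg,
                 traits = traits, trait_cor = as.matrix(trait_cor)),
            class = "sim_config")
}

## correlated genetic draws: n rows, columns = trait x site combinations
## (site fastest), unit marginal variance
genetic_draw <- function(n, cfg, nsite) {
  Rs <- if (nsite == 2L)
    matrix(c(1, cfg$cross_site_rg, cfg$cross_site_rg, 1), 2) else matrix(1)
  R <- kronecker(cfg$trait_cor, Rs)
  ## tolerate PSD boundary (|r| = 1)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
  matrix(stats::rnorm(n * nrow(R)), n) %*% t(L)
}

#' Simulate an open-pollinated provenance/progeny trial
#'
#' Generates pedigree, phenotypes and ground truth under the generative
#' counterpart of the analysis model: provenance effects (optionally a linear
#' latitude cline) with variance \eqn{\sigma^2_p}; maternal within-provenance
#' breeding values with variance \eqn{\sigma^2_g}; each offspring's additive
#' value is half its mother's plus half an independently drawn pollen
#' parent's plus a Mendelian-sampling deviate of variance \eqn{\sigma^2_g/2};
#' replicate, set-within-replicate and residual effects of the configured
#' variances; ordinal traits by thresholding the latent value into k classes
#' at equal quantiles, binary traits at the prevalence quantile.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; equal seeds give identical trials.
#' @return A list of class \code{"sim_trial"} with elements \code{pedigree},
#'   \code{phenotypes}, \code{truth} (generating parameters, per-provenance
#'   effects and latitudes, per-tree true breeding values) and \code{config}.
#' @export
simulate_trial <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(seed)
  nsite <- if (is.null(cfg$cross_site_rg)) 1L else 2L
  sites <- paste0("S", seq_len(nsite))
  tnames <- names(cfg$traits)
  nt <- length(tnames)
  P <- cfg$n_provenances; M <- cfg$mothers_per_provenance
  O <- cfg$offspring_per_mother; R <- cfg$replicates
  S <- cfg$sets_per_replicate
  provs <- sprintf("P%02d", seq_len(P))
  lat <- seq(cfg$latitude_range[1], cfg$latitude_range[2], length.out = max(P, 2))[seq_len(P)]

  ## provenance effects: cline + random deviation, shared across sites,
  ## correlated across traits
  prov_dev <- genetic_draw(P, cfg, 1L) * sqrt(cfg$sigma2_p)  # P x nt
  cline <- cfg$cline_slope * (lat - mean(lat))
  prov_eff <- sweep(prov_dev, 1, -cline)                     # add cline to every trait
  dimnames(prov_eff) <- list(provs, tnames)

  ## mothers
  mid <- as.vector(t(outer(provs, sprintf("M%03d", seq_len(M)), paste, sep = "_")))
  mother_prov <- rep(provs, each = M)
  bw_m <- genetic_draw(P * M, cfg, nsite) * sqrt(cfg$sigma2_g)  # trait x site cols

  ## offspring are generated independently per site (each site's trees are
  ## distinct individuals; the cross-site genetic link runs through the
  ## mothers, whose site-specific breeding values are correlated)
  noff <- P * M * O
  mother_of <- rep(seq_len(P * M), each = O)
  pidx <- match(mother_prov[mother_of], provs)
  colsel <- function(t) (t - 1L) * nsite + seq_len(nsite)   # site cols of trait t
  offspring_genetic <- function(s) {
    bw_f <- if (cfg$pollen == "common") {
      cfg$delta_pollen + genetic_draw(noff, cfg, 1L) * sqrt(cfg$sigma2_pollen)
    } else {
      genetic_draw(noff, cfg, 1L) * sqrt(cfg$sigma2_g)
    }
    mend <- genetic_draw(noff, cfg, 1L) * sqrt(cfg$sigma2_g / 2)
    bm <- bw_m[mother_of, vapply(seq_len(nt), function(t) colsel(t)[s],
                                 integer(1)), drop = FALSE]
    g <- 0.5 * bm + 0.5 * bw_f + mend
    for (t in seq_len(nt)) {
      pe <- prov_eff[pidx, t]
      g[, t] <- g[, t] + if (cfg$pollen == "common") 0.5 * pe else pe
    }
    colnames(g) <- tnames
    g
  }

  ## field layout: family -> set (round-robin within provenance),
  ## offspring j of a family -> replicate ((j-1) mod R) + 1, per site
  fam_set <- rep(((seq_len(M) - 1L) %% S) + 1L, times = P)
  off_rep <- ((seq_len(O) - 1L) %% R) + 1L

  ped <- data.frame(individual = c(mid), dam = NA_character_,
                    sire = NA_character_, provenance = mother_prov,
                    stringsAsFactors = FALSE)
  phen_list <- list()
  truth_bv <- list()
  control_eff <- stats::rnorm(cfg$n_controls, 0,
                              sqrt(cfg$sigma2_g + cfg$sigma2_p))
  lots <- if (cfg$n_controls) paste0("C", seq_len(cfg$n_controls)) else character(0)

  for (s in seq_len(nsite)) {
    site <- sites[s]
    ## environmental effects are drawn independently per trait (the bivariate
    ## analysis model's replicate and set structures are diagonal)
    rep_eff_t <- matrix(stats::rnorm(R * nt, 0, sqrt(cfg$sigma2_r)), R, nt)
    set_eff_t <- array(stats::rnorm(R * S * nt, 0, sqrt(cfg$sigma2_rs)),
                       c(R, S, nt))
    oid <- paste0(site, "_", mid[mother_of], "_O", sprintf("%02d", rep(seq_len(O), P * M)))
    orep <- rep(off_rep, P * M)
    oset <- fam_set[mother_of]
    ped <- rbind(ped, data.frame(individual = oid, dam = mid[mother_of],
                                 sire = NA_character_,
                                 provenance = mother_prov[mother_of],
                                 stringsAsFactors = FALSE))
    g_o <- offspring_genetic(s)
    latent <- matrix(NA_real_, noff, nt, dimnames = list(NULL, tnames))
    for (t in seq_len(nt)) {
      env <- rep_eff_t[orep, t] + set_eff_t[cbind(orep, oset, t)]
      latent[, t] <- cfg$mu + g_o[, t] + env +
        stats::rnorm(noff, 0, sqrt(cfg$sigma2_e))
    }
    df <- data.frame(tree = oid, site = site, replicate = orep, set = oset,
                     provenance = mother_prov[mother_of],
                     control = NA_character_, stringsAsFactors = FALSE)
    ## controls: one ramet per lot per set per replicate
    if (cfg$n_controls) {
      grid <- expand.grid(lot = seq_len(cfg$n_controls), rep = seq_len(R),
                          set = seq_len(S))
      cid <- paste0(site, "_", lots[grid$lot], "_x",
                    sprintf("%04d", seq_len(nrow(grid))))
      ped <- rbind(ped, data.frame(individual = cid, dam = NA_character_,
                                   sire = NA_character_,
                                   provenance = NA_character_,
                                   stringsAsFactors = FALSE))
      clat <- matrix(NA_real_, nrow(grid), nt, dimnames = list(NULL, tnames))
      for (t in seq_len(nt)) {
        cenv <- rep_eff_t[grid$rep, t] + set_eff_t[cbind(grid$rep, grid$set, t)]
        clat[, t] <- cfg$mu + control_eff[grid$lot] + cenv +
          stats::rnorm(nrow(grid), 0, sqrt(cfg$sigma2_e))
      }
      cdf <- data.frame(tree = cid, site = site, replicate = grid$rep,
                        set = grid$set, provenance = NA_character_,
                        control = lots[grid$lot], stringsAsFactors = FALSE)
      df <- rbind(df, cdf)
      latent <- rbind(latent, clat)
    }
    ## observed scale per trait (thresholding within site)
    for (t in seq_len(nt)) {
      tr <- cfg$traits[[t]]
      x <- latent[, t]
      df[[tnames[t]]] <- switch(tr$type,
        continuous = x,
        ordinal = {
          br <- stats::quantile(x, probs = seq(0, 1, length.out = tr$k + 1),
                                names = FALSE)
          br[1] <- -Inf; br[length(br)] <- Inf
          as.integer(cut(x, breaks = br, labels = FALSE,
                         include.lowest = TRUE))
        },
        binary = as.integer(x > stats::quantile(x, 1 - tr$prevalence,
                                                names = FALSE)))
    }
    phen_list[[s]] <- df
    bvdf <- data.frame(tree = oid, site = site, stringsAsFactors = FALSE)
    for (t in seq_len(nt)) bvdf[[tnames[t]]] <- g_o[, t]
    truth_bv[[s]] <- bvdf
  }
  phen <- do.call(rbind, phen_list)
  rownames(phen) <- NULL
  truth <- list(
    params = list(sigma2_g = cfg$sigma2_g, sigma2_p = cfg$sigma2_p,
                  sigma2_e = cfg$sigma2_e, sigma2_r = cfg$sigma2_r,
                  sigma2_rs = cfg$sigma2_rs,
                  h2 = cfg$sigma2_g / (cfg$sigma2_g + cfg$sigma2_e),
                  qst = cfg$sigma2_p / (cfg$sigma2_p + 2 * cfg$sigma2_g),
                  delta_pollen = cfg$delta_pollen,
                  cross_site_rg = cfg$cross_site_rg, seed = seed),
    provenance_effects = prov_eff,
    latitudes = stats::setNames(lat, provs),
    mother_bv = `rownames<-`(bw_m, mid),
    bv = do.call(rbind, truth_bv))
  structure(list(pedigree = ped, phenotypes = phen, truth = truth,
                 config = cfg, seed = seed), class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("Synthetic provenance/progeny trial:",
      x$config$n_provenances, "provenances x",
      x$config$mothers_per_provenance, "families x",
      x$config$offspring_per_mother, "offspring;",
      length(unique(x$phenotypes$site)), "site(s),",
      nrow(x$phenotypes), "trees\n")
  invisible(x)
}

#' Write a simulated trial to delimited files
#'
#' Emits \code{pedigree.csv}, \code{phenotypes.csv} and
#' \code{truth_bv.csv}/\code{truth_params.csv} in the package's file
#' dialects (unknown fields empty).
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if absent).
#' @export
export_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "sim_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) {
    df[] <- lapply(df, function(col) {
      if (is.character(col)) replace(col, is.na(col), "") else col
    })
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  wr(trial$pedigree, "pedigree.csv")
  wr(trial$phenotypes, "phenotypes.csv")
  wr(trial$truth$bv, "truth_bv.csv")
  pp <- trial$truth$params
  pp$cross_site_rg <- if (is.null(pp$cross_site_rg)) NA_real_ else pp$cross_site_rg
  wr(data.frame(parameter = names(pp), value = unlist(pp)), "truth_params.csv")
  invisible(dir)
}

#' Read a simulated trial back from [export_trial()] files
#'
#' @param dir Directory holding the exported files.
#' @return List with \code{pedigree}, \code{phenotypes}, \code{truth_bv} and
#'   \code{truth_params}.
#' @export
read_trial <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  phen <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(tree = "character",
                                         provenance = "character",
                                         control = "character"))
  phen$control[!is.na(phen$control) & phen$control == ""] <- NA
  phen$provenance[!is.na(phen$provenance) & phen$provenance == ""] <- NA
  bv <- utils::read.csv(file.path(dir, "truth_bv.csv"),
                        stringsAsFactors = FALSE)
  pars <- utils::read.csv(file.path(dir, "truth_params.csv"),
                          stringsAsFactors = FALSE)
  list(pedigree = ped, phenotypes = phen, truth_bv = bv, truth_params = pars)
}
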