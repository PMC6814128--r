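test_that("bivariate likelihood at the optimum matches the dense oracle", {
  cfg <- sim_config(n_provenances = 3, mothers_per_provenance = 4,
                    offspring_per_mother = 4, replicates = 3,
                    sets_per_replicate = 2, n_controls = 1,
                    traits = list(a = list(type = "continuous"),
                                  b = list(type = "continuous")),
                    trait_cor = matrix(c(1, 0.5, 0.5, 1), 2))
  tr <- simulate_trial(cfg, seed = 9)
  fit <- ablup_pair("a", "b", tr$phenotypes, tr$pedigree, variant = "F",
                    se = FALSE)
  aug <- provblup:::ablup_pedigree(tr$pedigree, "F")
  des1 <- provblup:::ablup_design("a", tr$phenotypes, aug, "F")
  des2 <- provblup:::ablup_design("b", tr$phenotypes, aug, "F")
  nll_dense <- dense_nll2_biv(as.list(fit$components), des1, des2, aug)
  expect_equal(-nll_dense / 2, fit$logLik, tolerance = 1e-6)
})

test_that("a trait paired with a near-copy of itself gives rG ~ 1", {
  tr <- small_trial(seed = 5, mothers_per_provenance = 8)
  ph <- tr$phenotypes
  set.seed(1)
  ph$copy <- ph$growth + rnorm(nrow(ph), 0, 0.05)
  fit <- ablup_pair("growth", "copy", ph, tr$pedigree, variant = "F",
                    se = FALSE)
  expect_gt(fit$rg$value, 0.98)
})

test_that("independent genetic effects give rG near zero, with a sane SE", {
  cfg <- sim_config(n_provenances = 5, mothers_per_provenance = 10,
                    offspring_per_mother = 10, replicates = 5,
                    sets_per_replicate = 2,
                    traits = list(a = list(type = "continuous"),
                                  b = list(type = "continuous")))
  tr <- simulate_trial(cfg, seed = 6)
  fit <- ablup_pair("a", "b", tr$phenotypes, tr$pedigree, variant = "F")
  expect_lt(abs(fit$rg$value), 2 * fit$rg$se + 1e-6)
  expect_gt(fit$rg$se, 0)
})

test_that("bivariate marginals agree with univariate fits on complete data", {
  cfg <- sim_config(n_provenances = 5, mothers_per_provenance = 10,
                    offspring_per_mother = 8, replicates = 5,
                    sets_per_replicate = 2,
                    traits = list(a = list(type = "continuous"),
                                  b = list(type = "continuous")),
                    trait_cor = matrix(c(1, 0.4, 0.4, 1), 2))
  tr <- simulate_trial(cfg, seed = 7)
  fit <- ablup_pair("a", "b", tr$phenotypes, tr$pedigree, variant = "F",
                    se = FALSE)
  u1 <- ablup("a", tr$phenotypes, tr$pedigree, variant = "F", pev = FALSE,
              se = FALSE)
  u2 <- ablup("b", tr$phenotypes, tr$pedigree, variant = "F", pev = FALSE,
              se = FALSE)
  expect_equal(fit$components[["g1"]], u1$vc[["sigma2_g"]], tolerance = 0.25)
  expect_equal(fit$components[["g2"]], u2$vc[["sigma2_g"]], tolerance = 0.25)
  expect_equal(fit$components[["e1"]], u1$vc[["sigma2_e"]], tolerance = 0.15)
  expect_equal(fit$components[["e2"]], u2$vc[["sigma2_e"]], tolerance = 0.15)
})

test_that("rG is invariant to linear rescaling of either trait", {
  tr <- small_trial(seed = 8, traits = list(a = list(type = "continuous"),
                                            b = list(type = "continuous")),
                    trait_cor = matrix(c(1, 0.5, 0.5, 1), 2))
  f1 <- ablup_pair("a", "b", tr$phenotypes, tr$pedigree, variant = "F",
                   se = FALSE)
  ph <- tr$phenotypes; ph$b <- 10 * ph$b + 3
  f2 <- ablup_pair("a", "b", ph, tr$pedigree, variant = "F", se = FALSE)
  expect_equal(f1$rg$value, f2$rg$value, tolerance = 5e-3)
})

test_that("cross-site fit recovers the simulated genetic correlation", {
  cfg <- sim_config(n_provenances = 10, mothers_per_provenance = 20,
                    offspring_per_mother = 6, replicates = 6,
                    sets_per_replicate = 2, cross_site_rg = 0.5)
  tr <- simulate_trial(cfg, seed = 11)
  fit <- ablup_xsite("growth", tr$phenotypes, tr$pedigree,
                     sites = c("S1", "S2"), variant = "F")
  expect_lt(abs(fit$rg$value - 0.5), 2 * fit$rg$se)
  ## swapping the site labels leaves rG unchanged
  fit2 <- ablup_xsite("growth", tr$phenotypes, tr$pedigree,
                      sites = c("S2", "S1"), variant = "F", se = FALSE)
  expect_equal(fit$rg$value, fit2$rg$value, tolerance = 5e-3)
})

test_that("identical genetic effects across sites give rG near 1", {
  cfg <- sim_config(n_provenances = 6, mothers_per_provenance = 15,
                    offspring_per_mother = 5, replicates = 5,
                    sets_per_replicate = 2, cross_site_rg = 1)
  tr <- simulate_trial(cfg, seed = 12)
  fit <- ablup_xsite("growth", tr$phenotypes, tr$pedigree,
                     sites = c("S1", "S2"), variant = "F", se = FALSE)
  expect_gt(fit$rg$value, 0.75)
})

test_that("cross-site preconditions are enforced", {
  cfg <- sim_config(n_provenances = 3, mothers_per_provenance = 4,
                    offspring_per_mother = 3, replicates = 2,
                    sets_per_replicate = 2, cross_site_rg = 0.5)
  tr <- simulate_trial(cfg, seed = 13)
  ## a tree with records on both sites
  ph <- rbind(tr$phenotypes, transform(tr$phenotypes[1, ], site = "S2"))
  expect_error(ablup_xsite("growth", ph, tr$pedigree, sites = c("S1", "S2")),
               "both sites")
  ## no shared families between sites -> identifiability error
  tr2 <- simulate_trial(cfg, seed = 14)
  ph2 <- rbind(
    transform(tr$phenotypes[tr$phenotypes$site == "S1", ], site = "S1"),
    transform(tr2$phenotypes[tr2$phenotypes$site == "S2", ],
              site = "S2", tree = paste0("x_", tr2$phenotypes$tree[
                tr2$phenotypes$site == "S2"])))
  ped2 <- tr2$pedigree
  ped2$individual <- paste0("x_", ped2$individual)
  ped2$dam <- ifelse(is.na(ped2$dam), NA, paste0("x_", ped2$dam))
  expect_error(
    ablup_xsite("growth", ph2, rbind(tr$pedigree, ped2),
                sites = c("S1", "S2")),
    "connectedness")
})
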