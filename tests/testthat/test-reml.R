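test_that("REML matches lme4 on identity-relationship data", {
  skip_if_not_installed("lme4")
  set.seed(7)
  n_id <- 50; nrec <- 5
  id <- rep(sprintf("i%02d", seq_len(n_id)), each = nrec)
  repl <- rep(seq_len(nrec), n_id)
  blk <- sample(1:2, n_id * nrec, replace = TRUE)
  y <- rep(rnorm(n_id, 0, 1.1), each = nrec) +
    rnorm(nrec, 0, 0.6)[repl] + rnorm(10, 0, 0.4)[(repl - 1) * 2 + blk] +
    rnorm(n_id * nrec, 0, 0.9)
  ped <- data.frame(individual = sprintf("i%02d", seq_len(n_id)),
                    dam = NA, sire = NA, provenance = "A")
  dat <- data.frame(tree = id, replicate = repl, set = blk,
                    provenance = "A", control = NA, y = y)
  fit <- ablup("y", dat, ped, variant = "F", pev = FALSE, se = FALSE)
  lf <- lme4::lmer(y ~ 1 + (1 | id) + (1 | repl) + (1 | ss), REML = TRUE,
                   data = data.frame(y = y, id = id, repl = factor(repl),
                                     ss = factor(paste(repl, blk))))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$vc[["sigma2_g"]], vc$vcov[vc$grp == "id"],
               tolerance = 1e-5)
  expect_equal(fit$vc[["sigma2_r"]], vc$vcov[vc$grp == "repl"],
               tolerance = 1e-4)
  expect_equal(fit$vc[["sigma2_rs"]], vc$vcov[vc$grp == "ss"],
               tolerance = 1e-4)
  expect_equal(fit$vc[["sigma2_e"]], vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-5)
  ## our logL carries the error-contrast normalisation -log|X'X|/2
  ldxx <- as.numeric(determinant(crossprod(model.matrix(lf)))$modulus)
  expect_equal(fit$logLik - ldxx / 2, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
})

test_that("sparse-MME likelihood equals the dense-matrix formula", {
  tr <- small_trial(seed = 2, n_provenances = 3, mothers_per_provenance = 4,
                    offspring_per_mother = 4, replicates = 3, n_controls = 1)
  for (variant in c("F", "R", "GC1")) {
    aug <- provblup:::ablup_pedigree(tr$pedigree, variant)
    des <- provblup:::ablup_design("growth", tr$phenotypes, aug, variant)
    m <- provblup:::mme_build(des$y, des$X, des$ran,
                              group_term = des$group_term,
                              group_cols = des$group_cols)
    vars <- c(g = 0.8, r = 0.12, s = 0.07, e = 1.4,
              p = if (variant == "R") 0.3 else NA)
    gamma <- c(0.8, 0.12, 0.07, if (variant == "R") 0.3) / 1.4
    nll_sparse <- provblup:::mme_nll2_abs(m, gamma * 1.4, 1.4, new.env())
    nll_dense <- dense_nll2_uni(as.list(vars), des, aug)
    expect_equal(nll_sparse, nll_dense, tolerance = 1e-7)
  }
})

test_that("balanced one-way REML equals the ANOVA closed form", {
  set.seed(11)
  s <- 20; nper <- 8
  fid <- rep(sprintf("f%02d", seq_len(s)), each = nper)
  y <- rep(rnorm(s, 0, 2), each = nper) + rnorm(s * nper, 0, 1.5)
  ped <- data.frame(individual = sprintf("f%02d", seq_len(s)), dam = NA,
                    sire = NA, provenance = "A")
  dat <- data.frame(tree = fid, replicate = 1, set = 1, provenance = "A",
                    control = NA, y = y)
  fit <- ablup("y", dat, ped, variant = "F", pev = FALSE, se = FALSE,
               control = reml_control(rel_tol = 1e-14))
  av <- anova(lm(y ~ fid))
  msb <- av["fid", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  expect_equal(fit$vc[["sigma2_g"]], (msb - msw) / nper, tolerance = 1e-8)
  expect_equal(fit$vc[["sigma2_e"]], msw, tolerance = 1e-8)
})

test_that("REML objective is invariant to equation order and fixed coding", {
  tr <- small_trial(seed = 3)
  f1 <- ablup("growth", tr$phenotypes, tr$pedigree, variant = "F",
              pev = FALSE, se = FALSE)
  ## permute the record order
  set.seed(1); perm <- sample(nrow(tr$phenotypes))
  f2 <- ablup("growth", tr$phenotypes[perm, ], tr$pedigree, variant = "F",
              pev = FALSE, se = FALSE)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-7)
  expect_equal(f1$vc, f2$vc, tolerance = 1e-5)
  ## relabel provenances (changes the reference level / dummy coding)
  ph <- tr$phenotypes; pd <- tr$pedigree
  relab <- function(x) chartr("1234", "4321", x)
  ph$provenance <- relab(ph$provenance); pd$provenance <- relab(pd$provenance)
  f3 <- ablup("growth", ph, pd, variant = "F", pev = FALSE, se = FALSE)
  expect_equal(f1$logLik, f3$logLik, tolerance = 1e-7)
  expect_equal(f1$vc[["sigma2_g"]], f3$vc[["sigma2_g"]], tolerance = 1e-5)
})

test_that("rescaling the response scales components, h2 unchanged", {
  tr <- small_trial(seed = 4)
  f1 <- ablup("growth", tr$phenotypes, tr$pedigree, variant = "F",
              pev = FALSE, se = FALSE)
  ph <- tr$phenotypes; ph$growth <- 2 * ph$growth
  f2 <- ablup("growth", ph, tr$pedigree, variant = "F", pev = FALSE,
              se = FALSE)
  expect_equal(4 * f1$vc, f2$vc, tolerance = 1e-4)
  expect_equal(heritability(f1)$value, heritability(f2)$value,
               tolerance = 1e-5)
})

test_that("AIC counts free variance parameters per variant", {
  tr <- small_trial(seed = 5)
  fF <- ablup("growth", tr$phenotypes, tr$pedigree, variant = "F",
              pev = FALSE, se = FALSE)
  fR <- ablup("growth", tr$phenotypes, tr$pedigree, variant = "R",
              pev = FALSE, se = FALSE)
  expect_equal(fF$t_free, 4L)   # additive, replicate, set(rep), residual
  expect_equal(fR$t_free, 5L)   # + provenance
  expect_equal(AIC(fF), -2 * fF$logLik + 2 * 4)
  expect_equal(fR$aic, -2 * fR$logLik + 2 * 5)
  ## arithmetic of the criterion itself
  expect_equal(-2 * (-100) + 2 * 4, 208)
})

test_that("a null additive variance shrinks to the boundary at large n", {
  tr <- small_trial(seed = 9, sigma2_g = 1e-12, qst = 0, sigma2_e = 2,
                    mothers_per_provenance = 30, offspring_per_mother = 12,
                    replicates = 6)
  fit <- ablup("growth", tr$phenotypes, tr$pedigree, variant = "F",
               pev = FALSE, se = FALSE)
  expect_lt(fit$vc[["sigma2_g"]], 0.03 * fit$vc[["sigma2_e"]])
})

test_that("PEV stays within (0, sigma2_g] so accuracy is real", {
  tr <- small_trial(seed = 6)
  for (variant in c("F", "GC1")) {
    fit <- ablup("growth", tr$phenotypes, tr$pedigree, variant = variant,
                 pev = TRUE, se = FALSE)
    expect_true(all(fit$pev > 0))
    expect_true(all(fit$pev <= fit$vc[["sigma2_g"]] + 1e-8))
    acc <- accuracy(fit)
    expect_true(all(is.finite(acc$per_individual)))
    expect_true(acc$value >= 0 && acc$value <= 1)
  }
})

test_that("missing trait values are dropped listwise and design nests sets", {
  tr <- small_trial(seed = 7)
  ph <- tr$phenotypes
  ph$growth[c(3, 10)] <- NA
  fit <- ablup("growth", ph, tr$pedigree, variant = "F", pev = FALSE,
               se = FALSE)
  expect_equal(fit$n, nrow(ph) - 2L)
  ## set factor has replicate x set levels
  des <- provblup:::ablup_design("growth", ph,
                                 provblup:::ablup_pedigree(tr$pedigree, "F"),
                                 "F")
  expect_equal(nlevels(des$set), 4 * 2)
  ## tree absent from pedigree -> linkage error
  ph2 <- tr$phenotypes; ph2$tree[1] <- "not_in_pedigree"
  expect_error(ablup("growth", ph2, tr$pedigree, variant = "F"),
               "absent from pedigree")
})
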