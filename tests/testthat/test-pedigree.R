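test_that("pedigree files are parsed with unknown-parent conventions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,dam,sire,provenance",
               "a,,,A", "b,0,,B", "c,,,"), f)
  ped <- read_pedigree(f)
  expect_equal(nrow(ped), 3L)
  expect_true(all(is.na(ped$dam)) && all(is.na(ped$sire)))
  expect_equal(ped$provenance, c("A", "B", NA))

  ## open-pollinated convention: mother known, sire empty
  writeLines(c("individual,dam,sire,provenance",
               "m,,,A", "o,m,,A"), f)
  ped <- read_pedigree(f)
  expect_equal(ped$dam[2], "m")
  expect_true(is.na(ped$sire[2]))

  ## tab-delimited autodetection
  writeLines(c("individual\tdam\tsire\tprovenance", "x\t\t\tA"), f)
  expect_equal(read_pedigree(f)$individual, "x")

  writeLines(c("individual,dam,sire,provenance", "X,X,,A"), f)
  expect_error(read_pedigree(f), "own parent")
  writeLines(c("individual,dam,sire,provenance", "a,,,A", "a,,,A"), f)
  expect_error(read_pedigree(f), "duplicate")
  writeLines(c("individual,dam", "a,"), f)
  expect_error(read_pedigree(f), "required column")
  expect_error(as_pedigree(data.frame(individual = "o", dam = "m",
                                      sire = "m")), "selfing")
})

test_that("sorting places parents first, completes founders, detects cycles", {
  ped <- data.frame(individual = c("o1", "m1"), dam = c("m1", NA),
                    sire = NA, provenance = c("A", "A"))
  s <- sort_pedigree(ped)
  expect_equal(s$individual, c("m1", "o1"))

  ## referenced-but-undeclared parent inserted as founder without provenance
  ped2 <- data.frame(individual = "o", dam = "ghost", sire = NA,
                     provenance = "A")
  s2 <- sort_pedigree(ped2)
  expect_equal(s2$individual, c("ghost", "o"))
  expect_true(is.na(s2$provenance[1]))

  ## idempotence on an already valid ordering
  expect_identical(sort_pedigree(s), s)

  cyc <- data.frame(individual = c("A", "B"), dam = c("B", "A"),
                    sire = NA, provenance = NA)
  expect_error(sort_pedigree(cyc), "cycle")
})

test_that("group augmentation follows the GC1/GC2 slot rules", {
  ped <- data.frame(individual = c("m", "o"), dam = c(NA, "m"),
                    sire = NA, provenance = c("p", "p"))
  a1 <- augment_pedigree(ped, group_scheme("GC1", "p"))
  expect_equal(a1$ped$dam, c("G_p", "m"))
  expect_equal(a1$ped$sire, c("G_pollen", "G_pollen"))
  expect_setequal(a1$groups, c("G_p", "G_pollen"))

  a2 <- augment_pedigree(ped, group_scheme("GC2", "p"))
  expect_equal(a2$ped$dam, c("G_p", "m"))
  expect_equal(a2$ped$sire, c("G_p", "G_p"))

  a0 <- augment_pedigree(ped, group_scheme("none"))
  expect_true(all(is.na(a0$ped$sire)))
  expect_length(a0$groups, 0L)

  ## founder without provenance: error by default, kept ungrouped on request
  pedc <- rbind(ped, data.frame(individual = "ctl", dam = NA, sire = NA,
                                provenance = NA))
  expect_error(augment_pedigree(pedc, group_scheme("GC2", "p")),
               "no provenance")
  ak <- augment_pedigree(pedc, group_scheme("GC2", "p"), ungrouped = "keep")
  expect_true(is.na(ak$ped$dam[ak$ped$individual == "ctl"]))

  ## group ids must not collide with individuals
  pedx <- data.frame(individual = "G_p", dam = NA, sire = NA,
                     provenance = "p")
  expect_error(augment_pedigree(pedx, group_scheme("GC2", "p")), "collide")
})

test_that("inbreeding matches classical values, groups act as founders", {
  ped <- data.frame(individual = c("a", "b", "c", "d", "x"),
                    dam = c(NA, NA, "a", "a", "c"),
                    sire = c(NA, NA, "b", "b", "d"),
                    provenance = NA)
  F1 <- inbreeding(augment_pedigree(ped, group_scheme("none")))
  expect_equal(unname(F1[c("a", "b", "c", "d")]), rep(0, 4))
  expect_equal(unname(F1[["x"]]), 0.25)   # offspring of full sibs

  ## offspring of half sibs
  ped2 <- data.frame(individual = c("m", "s1", "s2", "h1", "h2", "y"),
                     dam = c(NA, NA, NA, "m", "m", "h1"),
                     sire = c(NA, NA, NA, "s1", "s2", "h2"),
                     provenance = NA)
  F2 <- inbreeding(augment_pedigree(ped2, group_scheme("none")))
  expect_equal(unname(F2[["y"]]), 0.125)

  ## grouped founders stay non-inbred
  ped3 <- data.frame(individual = c("m", "o"), dam = c(NA, "m"),
                     sire = NA, provenance = "p")
  F3 <- inbreeding(augment_pedigree(ped3, group_scheme("GC2", "p")))
  expect_equal(unname(F3), c(0, 0))
})

test_that("tabular A reproduces textbook relationships and is SPD", {
  ped <- data.frame(individual = c("m1", "m2", "o1", "o2", "o3"),
                    dam = c(NA, NA, "m1", "m1", "m2"), sire = NA,
                    provenance = "A")
  A <- build_A_tabular(augment_pedigree(ped, group_scheme("none")))
  expect_equal(unname(diag(A)), rep(1, 5))
  expect_equal(A["m1", "o1"], 0.5)
  expect_equal(A["o1", "o2"], 0.25)    # OP half sibs, distinct phantom sires
  expect_equal(A["o1", "o3"], 0)

  ## full sibs
  pedf <- data.frame(individual = c("d", "s", "c1", "c2"),
                     dam = c(NA, NA, "d", "d"), sire = c(NA, NA, "s", "s"),
                     provenance = NA)
  Af <- build_A_tabular(augment_pedigree(pedf, group_scheme("none")))
  expect_equal(Af["c1", "c2"], 0.5)

  ## unrelated founders -> identity
  pedu <- data.frame(individual = letters[1:6], dam = NA, sire = NA,
                     provenance = "A")
  expect_equal(unname(build_A_tabular(augment_pedigree(pedu))),
               diag(6))

  ## random pedigrees: symmetric positive definite, diagonal in [1, 2],
  ## group parents treated as unknown founders (A identical across schemes)
  for (seed in 1:3) {
    ped <- random_pedigree(8, 25, seed)
    a_none <- augment_pedigree(ped, group_scheme("none"))
    a_gc1 <- augment_pedigree(ped, group_scheme("GC1", c("A", "B")))
    A1 <- build_A_tabular(a_none); A2 <- build_A_tabular(a_gc1)
    expect_equal(A1, A2)
    expect_true(isSymmetric(A1))
    ev <- eigen(A1, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_true(all(diag(A1) >= 1 & diag(A1) <= 2))
  }
})

test_that("group-augmented A-inverse follows the phantom-parent rules", {
  ## single founder under GC1: both slots unknown -> delta = 1, with the
  ## -delta/2 and delta/4 contributions landing on the two groups
  ped <- data.frame(individual = "f", dam = NA, sire = NA, provenance = "A")
  Ai <- as.matrix(build_Ainv_groups(augment_pedigree(ped,
                                                     group_scheme("GC1", "A"))))
  expect_equal(Ai, matrix(c(0.25, 0.25, -0.5,
                            0.25, 0.25, -0.5,
                            -0.5, -0.5, 1), 3, byrow = TRUE,
                          dimnames = list(c("G_A", "G_pollen", "f"),
                                          c("G_A", "G_pollen", "f"))))
  ## same founder under GC2: single group absorbs both slots
  Ai2 <- as.matrix(build_Ainv_groups(augment_pedigree(ped,
                                                      group_scheme("GC2", "A"))))
  expect_equal(Ai2, matrix(c(1, -1, -1, 1), 2,
                           dimnames = list(c("G_A", "f"), c("G_A", "f"))))

  ## mode none, founders only -> identity
  pedu <- data.frame(individual = letters[1:4], dam = NA, sire = NA,
                     provenance = NA)
  expect_equal(as.matrix(build_Ainv_groups(augment_pedigree(pedu))),
               diag(4), ignore_attr = TRUE)

  ## mode none equals the numeric inverse of tabular A (random pedigrees)
  for (seed in 4:5) {
    ped <- random_pedigree(30, 150, seed)
    aug <- augment_pedigree(ped, group_scheme("none"))
    expect_lt(max(abs(as.matrix(build_Ainv_groups(aug)) -
                      solve(build_A_tabular(aug)))), 1e-10)
  }
})

test_that("group ancestry fractions follow the halving recursion", {
  ped <- data.frame(individual = c("m", "o", "u"),
                    dam = c(NA, "m", NA), sire = NA,
                    provenance = c("p", "p", "p"))
  aug1 <- augment_pedigree(ped, group_scheme("GC1", "p"))
  Q1 <- build_group_fractions(aug1)
  expect_equal(Q1["m", ], c(G_p = 0.5, G_pollen = 0.5))
  ## OP offspring of an unknown mother: slots point straight at the groups
  expect_equal(Q1["u", ], c(G_p = 0.5, G_pollen = 0.5))
  ## OP offspring of a known grouped mother
  expect_equal(Q1["o", ], c(G_p = 0.25, G_pollen = 0.75))
  expect_equal(unname(rowSums(Q1)), rep(1, 3))

  aug2 <- augment_pedigree(ped, group_scheme("GC2", "p"))
  Q2 <- build_group_fractions(aug2)
  expect_equal(unname(Q2[, "G_p"]), rep(1, 3))
})

test_that("augmented pedigree writer emits groups first with a role column", {
  ped <- data.frame(individual = c("m", "o"), dam = c(NA, "m"), sire = NA,
                    provenance = "p")
  aug <- augment_pedigree(ped, group_scheme("GC1", "p"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_augmented_pedigree(aug, f)
  out <- utils::read.csv(f, colClasses = "character")
  expect_equal(names(out), c("individual", "dam", "sire", "provenance",
                             "role"))
  expect_equal(out$role, c("group", "group", "individual", "individual"))
  expect_equal(out$individual[1:2], aug$groups)
})

test_that("group-augmented equations equal the explicit Q-regression oracle", {
  for (seed in 1:4) {
    scheme_mode <- if (seed %% 2) "GC1" else "GC2"
    ped <- random_pedigree(10, 30, seed)
    aug <- augment_pedigree(ped, group_scheme(scheme_mode, c("A", "B")))
    aug_none <- augment_pedigree(ped, group_scheme("none"))
    set.seed(100 + seed)
    off <- aug$ped$individual[grepl("^o", aug$ped$individual)]
    dat <- data.frame(tree = rep(off, 2),
                      replicate = rep(1:2, each = length(off)),
                      set = 1, provenance = NA, control = NA,
                      y = rnorm(2 * length(off)))
    des <- provblup:::ablup_design("y", dat, aug, scheme_mode)
    gamma <- c(0.7, 0.15, 0.1)
    fa <- augmented_group_fit(des, gamma)
    fe <- explicit_group_fit(des, aug, aug_none, gamma)
    expect_equal(fa$logLik, fe$logLik, tolerance = 1e-9)
    expect_lt(max(abs(fa$ebv[fe$labels] - fe$ebv)), 1e-6)
  }
})
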