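---
title: "Modelling population structure in pedigree-based genetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population structure in pedigree-based genetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provblup)
```

## The problem

Wild-collected provenance/progeny trials of wind-pollinated forest trees
confound two levels of genetic variation: divergence *among* source
populations (provenances) and additive variation *within* them.  Getting the
partition right matters: it decides the heritability denominator, the
quantitative divergence statistic $Q_{ST}$, and the ranking of individual
breeding values.  A further complication specific to wind-pollinated species
is that the seed parent is by definition locally adapted (it survived to
reproduce on site), while the pollen parent may have blown in from hundreds
of kilometres away and need not carry the local provenance's genetic
background.

`provblup` fits the individual-tree ("animal") mixed model

$$ y = X\beta + Z g + Z r + Z r(s) + e $$

with $g \sim N(0, A\sigma^2_g)$ (A the pedigree numerator relationship
matrix), $r \sim N(0, I\sigma^2_r)$ replicate effects,
$r(s) \sim N(0, I\sigma^2_{r(s)})$ sets nested within replicates and
$e \sim N(0, I\sigma^2_e)$, under four treatments of population structure:

* **ABLUP-F** — provenance as a fixed term (the conventional default);
* **ABLUP-R** — provenance as an i.i.d. random term, which makes
  $\sigma^2_p$ estimable and yields
  $Q_{ST} = \sigma^2_p / (\sigma^2_p + 2\sigma^2_g)$;
* **ABLUP-GC2** — contemporary genetic groups in the pedigree: both unknown
  parent slots of a grouped individual point to its provenance group;
* **ABLUP-GC1** — genetic groups with an asymmetry reflecting long-distance
  pollen flow: the unknown maternal slot points to the provenance group, the
  unknown paternal slot to a single phantom *pollen* group shared by all
  provenances.

## Pedigree machinery

Group augmentation rewrites unknown parent slots as phantom-group ids; the
augmented pedigree is topologically sorted with groups in the first equation
block.  Inbreeding is computed by recursive relationship evaluation with
phantom groups treated as unrelated, non-inbred founders: groups are
statistical devices, not ancestors.

The sparse A-inverse with group equations uses the Westell–Quaas rules.  For
individual $i$ with parent slots $s, d$, the contributions are $\delta_i$ at
$(i,i)$, $-\delta_i/2$ at $(i,s)$ and $(i,d)$, and $\delta_i/4$ on the
parent-pair block, with $\delta_i = 1/d_i$ and the Mendelian-sampling
coefficient $d_i$ counting **only real known parents**
($d_i = 1$, $0.75 - 0.25F$, or $0.5 - 0.25(F_s + F_d)$).  A group slot
receives the off-diagonal contributions but does not reduce the
within-family variance.  This is the detail that makes the group equations
exactly equivalent to an explicit, unpenalised fixed regression on expected
group-ancestry fractions (the Q matrix produced by
`build_group_fractions()`), which in turn is what produces the observed
ABLUP-F $\equiv$ ABLUP-GC2 collapse.  The alternative convention — counting
a group slot as a known parent, so that a grouped founder gets
$\delta = 2$ — destroys both properties and is not used.  The tests verify
the equivalence against a dense explicit-fit oracle to $10^{-6}$ and the
tabular-method A to machine precision.

Dependent columns of the unpenalised design (including group equations made
inestimable by collinearity, e.g. the GC1 pollen column, which is confounded
with the intercept when every non-control tree carries half pollen ancestry)
are detected by an order-respecting incremental Cholesky of the Gram matrix
and pinned to zero; earlier columns always win, so solutions are
reproducible.

## The REML engine

The residual log-likelihood is evaluated exactly through the sparse
mixed-model equations using the determinant identity
$|C| = |X'V^{-1}X|\,|V| / (|R|\,|G|)$, with one symbolic Cholesky
factorisation per model updated numerically across evaluations.  For
univariate models the residual variance is profiled out analytically.

Two engine conventions deserve explanation:

* **Error-contrast normalisation.**  The textbook REML log-likelihood
  changes by a constant under reparameterisation of the fixed design
  ($X \to XT$ shifts $\log|X'V^{-1}X|$ by $2\log|T|$).  Because the four
  population-structure variants parameterise the same fixed subspace
  differently (provenance dummies vs. scaled group-ancestry columns), we
  subtract $\log|X^{*\prime}X^{*}|$ (over the full unpenalised design,
  groups included).  The objective is then invariant to any full-rank
  reparameterisation, and log-likelihoods and AIC values are comparable
  across variants.  Absolute values remain convention-dependent across
  software; only differences are meaningful.
* **Optimisation and standard errors.**  Variance ratios are estimated by
  safeguarded quasi-Newton iteration (`nlminb`) on the log scale with a
  floor of $10^{-8}$ on each ratio (a parameter resting on it is flagged
  boundary-constrained).  For systems of up to 800 equations the optimum is
  refined by coordinate Newton sweeps on the analytic gradient (which needs
  the dense inverse of the coefficient matrix), reaching machine-precision
  agreement with closed-form solutions on balanced designs.  Sampling
  covariances of the variance parameters come from the observed information
  — a central-difference Hessian of the exact $-\log L$ in the
  absolute-variance parameterisation — and feed every Taylor-series
  standard error downstream.  This replaces the more common
  average-information update-with-EM-fallback scheme: the estimates and the
  information-based SE class are the same, but direct maximisation of the
  exact likelihood is considerably more robust near variance boundaries.

Prediction error variances are the additive-block diagonal of the inverse
coefficient matrix (absolute scale), computed by chunked sparse solves for
the phenotyped individuals only.  Under the group variants the additive
equations solve directly for the group-inclusive prediction
$Q\hat{g} + \hat{a}$, so the reported PEV is the error variance of that
prediction, and reported breeding values include the group contribution.

## Genetic parameters

All estimators take the fitted components and the observed-information
covariance:

* $\hat h^2 = \hat\sigma^2_g / (\hat\sigma^2_g + \hat\sigma^2_e)$ for
  Gaussian traits (replicate and set variances are excluded from the
  denominator by convention);
* $\hat h^2 = \hat\sigma^2_g / (\hat\sigma^2_p + \hat\sigma^2_g +
  \hat\sigma^2_e)$ under ABLUP-R, where the provenance variance joins the
  denominator — this is why the random-provenance variant reports slightly
  lower heritabilities on the same data;
* $\hat h^2 = \hat\sigma^2_g / (\hat\sigma^2_g + \theta\pi^2/3)$ for binary
  traits on the logit scale;
* $Q_{ST} = \hat\sigma^2_p / (\hat\sigma^2_p + 2\hat\sigma^2_g)$, flagged
  significant when the value exceeds twice its standard error;
* accuracy $r = \sqrt{1 - PEV/\hat\sigma^2_g}$ per individual; the per-trait
  summary is the mean over phenotyped non-control genotypes (a convention
  choice — the summary population is not standardised in the field; PEVs
  exceeding $\hat\sigma^2_g$, possible only by numerical accident, clamp the
  accuracy to 0 with a warning);
* $r_G = \hat\sigma_{g_ig_j} / \sqrt{\hat\sigma^2_{g_i}\hat\sigma^2_{g_j}}$
  with a delta-method SE from the $(\sigma_{g_ig_j}, \sigma^2_{g_i},
  \sigma^2_{g_j})$ covariance block.

Delta-method gradients are analytic for every formula.

## Ordinal and binary traits

Ordinal class scores (stem straightness, malformation, branching, needle
retention) are transformed to normal scores
$\Phi^{-1}((r_i - 3/8)/(n + 1/4))$ with mid-ranks for ties — the Blom
version of the rank-based normal score.  The transform is computed per site
over all non-missing trees (sites are analysed separately throughout), not
within replicate; with 30 replications per site the difference is
negligible and the whole-site version keeps scores comparable across
replicates.

Binary traits are fitted by penalised quasi-likelihood on the logit scale.
With a single record per tree, the Mendelian (individual-specific) part of
$\sigma^2_g A$ and a free residual variance are confounded on the working
scale, and letting REML estimate both sends the iteration to a degenerate
ridge.  The working-variate REML therefore holds the underlying residual at
the binomial value 1 — matching the convention of printing the binary
residual as "1 (NA)" — and the over/under-dispersion coefficient $\theta$
is estimated afterwards by the quasi-likelihood Pearson moment estimator.
$\theta$ is close to 1 on simulated data without extra-binomial noise
(slightly below, because BLUP fitted values absorb part of the Pearson
variation).  PQL's well-documented attenuation of variance components in
sparse-information binary designs applies here in full: on simulated
open-pollinated trials the latent heritability is recovered directionally
but not unbiasedly, which is why binary traits should be read
qualitatively.  The cluster-informative case (repeated binary records per
genotype) is recovered well and is verified against an independent PQL
implementation in the tests.

## Bivariate models

Within-site trait pairs stack both traits' records with the Kronecker
structures: unstructured $2\times2$ additive $\otimes A$, diagonal replicate
and set blocks, and an unstructured residual applying only to within-tree
record pairs (records missing one trait are retained for the other).
Cross-site fits treat the two sites' expressions as two traits with the
residual covariance fixed at zero — no tree grows on both sites — so the
genetic covariance is identified purely through pedigree links, and the fit
refuses to run when the two sites share no families.  Covariances are
parameterised through bounded correlations ($\tanh$-transformed,
$|\rho| \le 0.999$), which enforces positive semi-definiteness by
construction; an estimate at the bound is flagged as bent.  Univariate fits
supply starting values in the pipeline.  The stacked likelihood is verified
against a dense-matrix oracle in the tests.

## Comparing correlation structures

Pairwise $r_G$ matrices from two variants are compared by a Mantel test
(Pearson correlation of off-diagonal entries, significance by permuting one
matrix's trait order; 999 permutations by default, seeded).  Trait modules
are detected by weighted Newman modularity maximisation (fast-greedy
agglomeration) on the graph with edge weights $|r_G|$ — absolute values,
because a strong negative genetic correlation is as much of a structural
tie as a positive one; the cited methodology does not pin this down, and
the choice is guarded by an exhaustive-search oracle over all trait
partitions in the tests.  Both steps delegate to the standard
implementations (vegan, igraph) behind the package's interface.

## The synthetic generator

`simulate_trial()` is the generative counterpart of the analysis model.
Defaults emulate the targeted trial series: 30 replications of 7 sets, 34
open-pollinated families plus 2 clonally repeated control lots per set,
provenances represented equally within every set, origins spanning
36–48°N.  The number of provenances is set to 14 (34 families does not
divide into provenances uniquely; 14 provenances of 17 families each is a
realistic mid-size coastal collection and keeps every provenance in every
set).  Provenance effects have variance $\sigma^2_p$ (or a target $Q_{ST}$),
optionally with a deterministic latitude cline; maternal breeding values
have variance $\sigma^2_g$ within provenance; each offspring is half its
mother, half an independently drawn pollen parent, plus a Mendelian deviate
of variance $\sigma^2_g/2$.  The pollen pool is either local (random males
of the same provenance) or common across provenances with a mean shift
$\Delta_{pollen}$ — the biological premise of the GC1 scheme.  Two-site
trials draw site-specific genetic effects with the configured cross-site
correlation; each site's offspring are distinct individuals linked through
their mothers, so the realised cross-site half-sib covariance is exactly
$0.25\,r_G\sigma^2_g$ as the pedigree implies.  Ordinal traits threshold
the latent value at equal empirical quantiles; binary traits at the
prevalence quantile.

The generator does **not** emulate spatial autocorrelation within
replicates, selection or mortality, assortative mating, or marker data.
Passing recovery tests therefore demonstrate correctness of the estimation
machinery under the stated model, not robustness to field realities outside
it.

## An equivalence the model class imposes

One structural result shapes what can and cannot be demonstrated on
synthetic data of this design.  With unpenalised genetic groups under the
Quaas rules, the group model is an explicit fixed regression on the
ancestry-fraction matrix Q.  In a uniform-depth open-pollinated trial —
known founder mothers, all phenotyped trees first-generation offspring —
every phenotyped tree's Q row is $(0.25\,\text{prov}, 0.75\,\text{pollen})$
under GC1 and $1.0\,\text{prov}$ under GC2, so both lie in the span of the
provenance indicators plus intercept.  Consequently ABLUP-F, ABLUP-GC1 and
ABLUP-GC2 are *the same statistical model* on such data: identical REML
likelihoods, components, heritabilities and AIC (the tests verify this to
machine precision, and a common pollen-pool mean shift changes nothing — it
is absorbed by the intercept).  The GC1 scheme becomes distinguishable only
when ancestry fractions vary across phenotyped individuals: mixed
generation depths, records on grouped founders, or partially known
paternity.  Practitioners comparing AIC across these variants on
single-generation OP data with other software should expect any observed
differences to reflect that software's internal group conventions rather
than information in the data.

## Numerical choices and limitations

* Convergence: relative objective tolerance $10^{-10}$, parameter tolerance
  $10^{-8}$, iteration cap 200; PQL outer loop capped at 50 with relative
  linear-predictor tolerance $10^{-7}$.
* Variance-ratio floor $10^{-8}$ (relative to the residual); binary weights
  floored at $10^{-6}$; estimates at a floor are flagged, not fatal.
* Selfing (dam = sire) is rejected; identifiers are opaque strings; group
  ids must not collide with individual ids.
* Controls are founders excluded from group assignment and handled by a
  fixed control-lot term (one level per lot).  GC1 uses one pollen group per
  analysed dataset.
* Observed-information SEs are unreliable for boundary-constrained
  components (the information matrix is then singular; affected entries are
  reported but should not be interpreted).
* Test problem sizes: the parameter-recovery study uses 30 provenances × 30
  mothers × 10 offspring (~9,000 records, 10 replications of 3 sets) with
  50 replicates; structural equivalences are verified on trials of a few
  hundred trees, where dense oracles are exact and cheap.
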