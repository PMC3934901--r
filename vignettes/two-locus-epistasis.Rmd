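---
title: "Modelling two-locus epistasis in familial disease penetrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-locus epistasis in familial disease penetrance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famepi)
```

## The model

`famepi` evaluates statistical epistasis — departure of the joint effect
of two loci from what their marginal effects predict — in family-based
cohorts of a heritable disease such as familial prostate cancer.  The
outcome is not individual disease status but the number of affected
members in a subject's family, $Y$.  Genotypes at two SNPs are collapsed
to dominant carrier codes $G_1, G_2 \in \{0, 1\}$ (carrier = at least one
copy of the declared risk allele).  The penetrance ladder consists of
log-link Poisson models:

$$\log \lambda = \beta_0 \;[\,+\, \beta_1 G_1] \;[\,+\, \beta_2 G_2]
  \;[\,+\, \beta_3 G_1 G_2] \;[\,+\, \beta_a \,\mathrm{age}]$$

fitted by iteratively reweighted least squares (Fisher scoring) with
step-halving.  In the terminology of Fisher's two epistasis scales, the
model with both main effects and no product term is the *additive* model
(effects multiply rates, i.e. add on the log scale), and the model with
the product term is the *multiplicative* model.  The additive-vs-
multiplicative likelihood-ratio test on 1 df, together with AIC, decides
whether the joint effect departs from independence on the log scale;
$\exp(\beta)$ is reported as a rate ratio (the convention in the
motivating literature labels these odds ratios, so output labels keep
that traceable).

Epistasis is scale-dependent, so `classify_epistasis()` labels the sign
on both scales: the multiplicative-scale label is the sign of $\beta_3$,
gated by the LRT at `alpha` (default 0.05, no multiplicity correction by
default, with a Bonferroni option); the additive-scale label is the sign
of the fitted-mean contrast
$\lambda_{11} - \lambda_{10} - \lambda_{01} + \lambda_{00}$.  Note that
with $\beta_3 = 0$ this contrast equals
$\lambda_{00}(e^{\beta_1}-1)(e^{\beta_2}-1) > 0$: rate-multiplicative
effects are already super-additive on the risk scale, so "no
multiplicative interaction" does not mean "no additive interaction".

## Observation units and why both exist

The contingency layout of the motivating study attributes the family's
case count to *every* genotyped member (its column totals equal subject
counts), and `build_design(unit = "subject")` reproduces exactly that:
one row per genotyped subject, the family's count as outcome, the
subject's own carrier codes as covariates.  Because the outcome is then
constant within a family, subject-level rows are not independent, and
model-based (Fisher-information) standard errors and LRTs are
anticonservative roughly in proportion to family size.

`build_design(unit = "family")` is the calibrated alternative: one row
per family, the family's modal carrier status per SNP (ties count as
carrier) and mean age as covariates.  This matches the generative unit
of the simulator, and it is the unit under which the package's
calibration properties hold (coverage, type-I error below).  For
subject-level analyses a cluster-robust sandwich covariance grouped by
family is available (`fam_poisson(..., cluster = )`,
`vcov(fit, robust = TRUE)`), clearly an extension beyond the source
convention.

## Tunable parameters

* `tol` (relative deviance, default `1e-8`) and `max_iter` (100): IRLS
  convergence.  At convergence the score has max-norm below `1e-6` on
  the instances the tests generate.  Initialisation is
  $\beta_0 = \log(\bar y + 0.5)$, other coefficients 0 — robust for
  count data with possible zero means.
* `link`: `"log"` (default, all published-style analyses) or
  `"identity"` for an additive-risk extension; identity-link steps are
  halved until fitted means stay positive and the fit errors if no
  feasible step exists.  Rate ratios are refused for identity-link fits.
* `alpha` (0.05): the classification gate.  `bonferroni = TRUE` divides
  it by the number of LRTs in a panel.
* `adjust_age`: the source analyses say age was considered as a
  confounder without stating which fits include it, so `run_ladder()`
  fits and reports both settings by default (a single linear age term).
* `k` (default 4): the multiplex threshold for `penetrance_profile()` —
  the probability of at least `k` cases in a family,
  $P(Y \ge k) = 1 - F_{\mathrm{Pois}}(k - 1; \hat\lambda)$, the only
  construction consistent with "predicted by the Poisson regression
  model".  Both the difference and the ratio of double-carrier vs
  double-noncarrier tail probabilities are reported, since a "13% higher
  risk" phrasing does not distinguish them.

Missing genotypes are never imputed: models are complete-case, and
`kept_rows` in every design records exactly which subjects (or
families) entered, so the per-model sample sizes (947 subjects with the
first SNP, 943 with both, in the reference contingency data) stay
auditable.

## What the simulator emulates

`sim_params()` defaults encode the study conditions of the motivating
cohort:

* 76 families; family sizes uniform on 8–17 members (mean 12.5, matching
  947 subjects in 76 families — note the 2–6 range often quoted for such
  cohorts refers to affected members per family, which the Poisson model
  produces, not to family size);
* risk-allele frequencies 0.223 and 0.249, the values implied by the
  published genotype counts; carrier status is drawn from the
  Hardy–Weinberg dominant carrier probability $1-(1-q)^2$;
* within-family genotype sharing 0.5: each member copies the founder's
  carrier status with that probability, else draws fresh.  This is a
  phenomenological stand-in for familial correlation — the analysis
  never uses pedigree relationships, so meiotic transmission is not
  modelled;
* penetrance coefficients $(1.1815, 0.0872, 0.0085, 0.0799)$, the
  published multiplicative-model estimates for the all-cases endpoint;
* a quarter of cases aggressive; ages Normal(62.3, 10) truncated at 40.

The family's count is drawn from the Poisson at the family's *modal*
carrier statuses and right-truncated at the family size (real families
cannot have more cases than members); the truncated fraction is recorded
and a warning is raised when it exceeds 5%.  The analysis model ignores
truncation exactly as the Poisson penetrance model does.

What the simulator does **not** emulate: multiplex ascertainment (real
study families were recruited through probands and all have two or more
cases, a selection that biases an unconditioned refit of the intercept),
linkage disequilibrium between the loci (they lie on different
chromosomes), age-at-onset dynamics, and pedigree structure.  Passing
tests therefore demonstrate the estimator's correctness under the
generative model, not unbiasedness under the ascertainment of any
particular real cohort.

`fixture_table1()` is different in kind: a fully deterministic
pseudo-cohort of 947 subjects in 76 families whose aggregate tables
equal, cell for cell, the published carrier-by-case-count contingency
table, genotype margins (61/301/585 and 61/348/534 with 4 missing), case
distribution (30/26/12/6/2 families with 2–6 cases; 228 cases, 57
aggressive) and group mean ages.  The cell allocations were solved as a
small transportation problem so that all four published margins hold
simultaneously; individual rows are synthetic and only these aggregates
are faithful.

## Numerical and design choices

* The reported log-likelihood includes the $\log y!$ term, so AIC values
  are absolute and comparable across software.
* LRT statistics are clipped at zero; comparing a model with itself
  returns $\chi^2 = 0$, df 0, $p = 1$ rather than an error.
* Rank-deficient designs fail fast, naming the collinear columns;
  strata in which the target locus is constant are reported as
  inestimable rather than dropped.
* The Pearson chi-square on the K×2 contingency table (df $K-1$) is the
  default association test; the source table's test is unnamed, and a
  Cochran–Armitage-style trend test is offered as an alternative.
  Neither is claimed to reproduce the source's secondary p-values
  (e.g. 0.0383) exactly.
* Family-size ties in the modal carrier status resolve to carrier;
  percentages print to one decimal, matching the published layout.

## Problem sizes used by the test-suite properties

The calibration properties are computed at the following sizes, chosen
to estimate each quantity with useful precision while keeping the suite
quick: 50 random instances (n = 20–40) for the IRLS-vs-Nelder–Mead
oracle agreement at $10^{-5}$; 200 study-scale cohorts for 95% CI
coverage of the generative coefficients (all four coefficients covered
in ≥ 90% of replicates); 2000 null cohorts for the empirical size of the
interaction LRT (within [0.03, 0.07] at nominal 0.05); 100 cohorts with
fully shared family genotypes for the subject-level power check.  That
last setting deserves a note: with partial sharing the subject-level
interaction covariate is diluted relative to the modal status that
generated the outcome, and the subject-level LRT at the published effect
size ($\beta_3 \approx 0.08$) rejects far less often; with full sharing
the subject rows exactly replicate the family data, mirroring the
source attribution, and the test has power above one half at the
≈950-subject scale.  The contrast between the two is itself the clearest
demonstration of why the family-level unit is used for calibrated
inference.

## Known limitations

* No overdispersion handling (quasi-Poisson/negative-binomial) and no
  family random effects: the ladder deliberately mirrors the source
  method, with the sandwich covariance as the only clustering
  concession.
* Exact reproduction of the source's fitted coefficients, LRT statistics
  and stratified intervals is impossible without the individual-level
  data; the package instead proves its estimator on synthetic cohorts
  with the same structure and reproduces exactly those aggregates the
  publication prints in full.
* Two-locus only; extending the ladder to more loci multiplies the model
  set combinatorially and is out of scope.
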