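test_that("designs on the contingency fixture have the published sizes", {
  coh <- fixture_table1()
  d1 <- build_design(coh, "rs4242382", "all")
  expect_equal(dim(d1$X), c(947L, 2L))
  d2 <- build_design(coh, SNPS, "all", interaction = TRUE)
  expect_equal(dim(d2$X), c(943L, 4L))   # 4 subjects lack rs10486567
  expect_equal(length(d2$kept_rows), 943L)
  expect_equal(d2$X[, 4L],
               d2$X[, "rs4242382"] * d2$X[, "rs10486567"])
  d3 <- build_design(coh, SNPS, "all", interaction = TRUE,
                     adjust_age = TRUE)
  expect_equal(colnames(d3$X)[5L], "age")
})

test_that("endpoints map to the right family counts", {
  coh <- toy_cohort()
  d_all <- build_design(coh, "snpB", "all")
  d_agg <- build_design(coh, "snpB", "aggressive")
  d_non <- build_design(coh, "snpB", "nonaggressive")
  # f1: 2 affected, 1 aggressive; f2: 2 affected, 0 aggressive
  expect_equal(d_all$y, c(2L, 2L, 2L, 2L, 2L))
  expect_equal(d_agg$y, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(d_non$y, c(1L, 1L, 2L, 2L, 2L))
  noagg <- coh
  noagg$aggressive <- NA
  expect_error(build_design(noagg, "snpB", "aggressive"),
               "aggressive-disease flags")
})

test_that("family-level designs use modal carrier status", {
  coh <- toy_cohort()
  d <- build_design(coh, "snpB", "all", unit = "family")
  # f1: codes 0,0 -> modal 0; f2: codes 1,1,1 -> modal 1
  expect_equal(unname(d$X[, "snpB"]), c(0, 1))
  expect_equal(d$y, c(2L, 2L))
  expect_equal(d$kept_rows, c("f1", "f2"))
})

test_that("a constant genotype column is reported as collinear", {
  coh <- toy_cohort()
  const <- coh
  const$snpB <- "AG"
  expect_error(
    fit_design(build_design(const, "snpB", "all")),
    "collinear")
})

test_that("log-likelihood is monotone along the model ladder", {
  for (seed in c(3, 17)) {
    coh <- simulate_cohort(sim_params(), seed = seed)
    for (unit in c("subject", "family")) {
      rep_ <- run_ladder(coh, SNPS, "all", adjust_age = FALSE,
                         unit = unit)
      a <- rep_$panels[[1L]]$aics
      ll <- setNames(a$loglik, a$model)
      expect_lte(ll["intercept"], ll[2L] + 1e-9)
      expect_lte(ll[2L], ll["additive"] + 1e-9)
      expect_lte(ll[3L], ll["additive"] + 1e-9)
      expect_lte(ll["additive"], ll["multiplicative"] + 1e-9)
      expect_equal(a$aic, -2 * a$loglik + 2 * a$k)
    }
  }
})

test_that("the ladder reports both age-adjustment settings and flags AIC best", {
  coh <- simulate_cohort(sim_params(), seed = 5)
  rep_ <- run_ladder(coh, SNPS, "all", unit = "family")
  expect_named(rep_$panels, c("unadjusted", "age_adjusted"))
  for (p in rep_$panels) {
    expect_equal(sum(p$aics$best), 1L)
    expect_equal(nrow(p$lrts), 5L)
    expect_true(all(p$aics$converged))
  }
  expect_output(print(rep_), "Epistasis classification")
})

test_that("interaction LRT agrees with the squared Wald statistic", {
  # asymptotic identity, checked at large n
  set.seed(19)
  coh <- simulate_cohort(sim_params(n_families = 900))
  d <- build_design(coh, SNPS, "all", interaction = TRUE,
                    unit = "family")
  full <- fit_poisson(d$X, d$y)
  add <- fit_poisson(d$X[, 1:3], d$y)
  chi2 <- lrt(add, full)$chi2
  b3 <- coef(full)[4L]
  z2 <- unname(b3^2 / diag(vcov(full))[4L])
  expect_lt(abs(chi2 - z2) / max(z2, 1), 0.15)
})

test_that("subject-level ladder detects the published-scale interaction", {
  # With genotypes fully shared within families the subject rows
  # replicate the family data, mirroring the source attribution; the
  # additive-vs-multiplicative LRT then rejects beta3 = 0.08 in most
  # cohorts of ~950 subjects.
  set.seed(23)
  p <- sim_params(within_family_sharing = 1)
  rej <- replicate(100, {
    coh <- simulate_cohort(p)
    d <- build_design(coh, SNPS, "all", interaction = TRUE,
                      unit = "subject")
    lrt(fit_poisson(d$X[, 1:3], d$y), fit_poisson(d$X, d$y))$p.value
  }) < 0.05
  expect_gt(mean(rej), 0.5)
})

test_that("stratified rate ratios expose synergistic interaction", {
  set.seed(29)
  p <- sim_params(n_families = 600,
                  betas = c(1.1815, 0.0872, 0.0085, 0.3))
  coh <- simulate_cohort(p)
  st <- stratified_rate_ratio(coh, "rs10486567", "rs4242382", "all",
                              unit = "family")
  expect_true(all(st$estimable))
  rr <- setNames(st$rate_ratio, st$stratum)
  expect_gt(rr["carrier"], rr["noncarrier"])
})

test_that("stratum ratios coincide under the null at large n", {
  set.seed(31)
  p <- sim_params(n_families = 3000,
                  betas = c(1.1815, 0.15, 0.1, 0))
  coh <- simulate_cohort(p)
  st <- stratified_rate_ratio(coh, "rs10486567", "rs4242382", "all",
                              unit = "family")
  expect_lt(abs(log(st$rate_ratio[1]) - log(st$rate_ratio[2])), 0.12)
})

test_that("strata without carriers are flagged inestimable", {
  d <- data.frame(family_id = rep(c("f1", "f2"), each = 2),
                  subject_id = paste0("s", 1:4), age = 60,
                  affected = TRUE, aggressive = FALSE,
                  snpA = c("AG", "GG", "AG", "GG"),
                  snpB = "GG",   # stratifier has no carriers at all
                  stringsAsFactors = FALSE)
  coh <- cohort(d, snps = c(snpA = "A", snpB = "A"))
  st <- stratified_rate_ratio(coh, "snpA", "snpB", "all")
  expect_false(st$estimable[st$stratum == "carrier"])
  expect_equal(st$n[st$stratum == "carrier"], 0L)
  expect_true(is.na(st$rate_ratio[st$stratum == "carrier"]))
  expect_true(st$estimable[st$stratum == "noncarrier"])
})

test_that("epistasis classification follows sign and significance gate", {
  set.seed(37)
  p <- sim_params(n_families = 800,
                  betas = c(1.1815, 0.0872, 0.0085, 0.35))
  coh <- simulate_cohort(p)
  rep_ <- run_ladder(coh, SNPS, "all", adjust_age = FALSE,
                     unit = "family")
  cls <- rep_$panels[[1L]]$classification
  expect_equal(cls$label[cls$scale == "multiplicative"], "positive")
  # gate at an absurdly small alpha -> none
  cls0 <- classify_epistasis(rep_$panels[[1L]], SNPS, alpha = 1e-12)
  expect_equal(unique(cls0$label), "none")
})

test_that("additive-scale label is the sign of the fitted-mean contrast", {
  # engineered fit: joint mean below the sum of marginal increments
  X <- cbind(`(Intercept)` = 1, a = c(0, 1, 0, 1), b = c(0, 0, 1, 1),
             `a:b` = c(0, 0, 0, 1))
  X <- X[rep(1:4, each = 400), ]
  lam <- c(2, 4, 4, 4.5)  # 4.5 < 4 + 4 - 2: negative additive epistasis
  set.seed(41)
  y <- rpois(nrow(X), rep(lam, each = 400))
  fit <- fit_poisson(X, y)
  add <- fit_poisson(X[, 1:3], y)
  lrts <- data.frame(nested = "additive", full = "multiplicative",
                     chi2 = lrt(add, fit)$chi2, df = 1,
                     p = lrt(add, fit)$p.value)
  panel <- list(fits = list(multiplicative = fit), lrts = lrts)
  cls <- classify_epistasis(panel, c("a", "b"), alpha = 0.05)
  expect_equal(cls$label, c("negative", "negative"))
  expect_lt(cls$contrast[cls$scale == "additive"], 0)
})
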