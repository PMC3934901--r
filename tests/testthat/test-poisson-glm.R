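test_that("closed-form fits are exact", {
  # intercept-only: MLE of the Poisson mean is the sample mean
  f <- fit_poisson(matrix(1, 4, 1), c(2, 2, 2, 2))
  expect_equal(unname(coef(f)), log(2), tolerance = 1e-9)
  expect_equal(unname(f$fitted), rep(2, 4), tolerance = 1e-8)
  # saturated two-group model: slope is the log mean ratio
  X <- cbind(1, rep(0:1, each = 3))
  y <- c(1, 2, 3, 4, 6, 8)
  f2 <- fit_poisson(X, y)
  expect_equal(unname(coef(f2)), c(log(2), log(6 / 2)), tolerance = 1e-8)
})

test_that("IRLS matches the brute-force likelihood oracle on small instances", {
  set.seed(7)
  for (i in 1:12) {
    inst <- random_instance(n = 30, p_extra = 2)
    f <- fit_poisson(inst$X, inst$y)
    expect_true(f$converged)
    expect_equal(unname(coef(f)), oracle_poisson(inst$X, inst$y),
                 tolerance = 1e-5)
  }
})

test_that("engine agrees with stats::glm for the log link", {
  set.seed(8)
  d <- data.frame(y = rpois(80, 3), g1 = rbinom(80, 1, 0.4),
                  g2 = rbinom(80, 1, 0.5), age = rnorm(80, 62, 9))
  f <- fam_poisson(y ~ g1 * g2 + age, d)
  g <- glm(y ~ g1 * g2 + age, poisson, d)
  expect_equal(coef(f)[names(coef(g))], coef(g), tolerance = 1e-7)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-9)
  expect_equal(f$aic, AIC(g), tolerance = 1e-8)
  expect_equal(vcov(f)[names(coef(g)), names(coef(g))], vcov(g),
               tolerance = 1e-5)
})

test_that("identity link fits additive-risk models and guards positivity", {
  set.seed(9)
  X <- cbind(1, rbinom(60, 1, 0.5))
  y <- rpois(60, 2 + 1.5 * X[, 2])
  f <- fit_poisson(X, y, link = "identity")
  g <- glm(y ~ X[, 2], poisson(link = "identity"),
           start = c(2, 1.5))
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_error(rate_ratio(f), "log link")
  # a mean forced through zero is infeasible for the identity link
  expect_error(fit_poisson(cbind(1, c(-5, -5, 1, 1)), c(0, 0, 3, 3),
                           link = "identity", start = c(1, 0.1)),
               "positive|feasible")
})

test_that("converged fits have zero score and consistent AIC", {
  set.seed(10)
  for (i in 1:5) {
    inst <- random_instance(n = 40, p_extra = 2)
    f <- fit_poisson(inst$X, inst$y)
    score <- drop(crossprod(inst$X, inst$y - f$fitted))
    expect_lt(max(abs(score)), 1e-6)
    expect_equal(f$aic, -2 * f$loglik + 2 * length(coef(f)))
  }
})

test_that("adding a covariate never decreases the log-likelihood", {
  set.seed(11)
  inst <- random_instance(n = 50, p_extra = 2)
  f1 <- fit_poisson(inst$X[, 1:2], inst$y)
  f2 <- fit_poisson(inst$X, inst$y)
  expect_gte(f2$loglik, f1$loglik - 1e-10)
  t <- lrt(f1, f2)
  expect_equal(t$df, 1L)
  expect_gte(t$chi2, 0)
})

test_that("rank-deficient designs are rejected naming the columns", {
  X <- cbind(`(Intercept)` = 1, a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))
  expect_error(fit_poisson(X, c(1, 2, 3, 4)), "collinear.*b")
})

test_that("likelihood-ratio test handles identical and invalid pairs", {
  f <- fit_poisson(matrix(1, 6, 1), rpois(6, 2) + 1)
  same <- lrt(f, f)
  expect_equal(same$chi2, 0)
  expect_equal(same$p.value, 1)
  set.seed(12)
  inst <- random_instance(30, 2)
  f_sub <- fit_poisson(inst$X[1:20, ], inst$y[1:20])
  f_full <- fit_poisson(inst$X, inst$y)
  expect_error(lrt(f_sub, f_full), "different observations")
})

test_that("rate ratios exponentiate coefficients with Wald intervals", {
  set.seed(13)
  X <- cbind(`(Intercept)` = 1, g = rep(0:1, 30))
  y <- rpois(60, exp(1 + 0.4 * X[, "g"]))
  f <- fit_poisson(X, y)
  rr <- rate_ratio(f, "g")
  b <- coef(f)["g"]; se <- sqrt(vcov(f)["g", "g"])
  expect_equal(rr$rate_ratio, unname(exp(b)))
  expect_equal(rr$lower, unname(exp(b - qnorm(0.975) * se)))
  expect_equal(rr$upper, unname(exp(b + qnorm(0.975) * se)))
  expect_equal(rr$p, unname(2 * pnorm(-abs(b / se))))
  # a null coefficient gives a ratio of 1 with a CI symmetric about 1
  y0 <- rep(c(2L, 3L), 30)
  f0 <- fit_poisson(X, c(y0[X[, "g"] == 0], y0[X[, "g"] == 1]))
  rr0 <- rate_ratio(f0, "g")
  expect_equal(rr0$rate_ratio, 1, tolerance = 1e-7)
  expect_equal(rr0$lower * rr0$upper, 1, tolerance = 1e-6)
  expect_error(rate_ratio(f, "nope"), "not in fit")
})

test_that("cluster-robust covariance undoes artificial replication", {
  set.seed(14)
  n <- 400
  d <- data.frame(y = rpois(n, 3), g = rbinom(n, 1, 0.5))
  base <- fam_poisson(y ~ g, d)
  d3 <- d[rep(1:n, each = 3), ]
  d3$id <- rep(1:n, each = 3)
  rep3 <- fam_poisson(y ~ g, d3, cluster = "id")
  naive_se <- sqrt(vcov(rep3)["g", "g"])
  robust_se <- sqrt(vcov(rep3, robust = TRUE)["g", "g"])
  # naive SE shrinks by sqrt(3) under triplication; the sandwich does not
  expect_gt(robust_se / naive_se, 1.5)
  expect_equal(robust_se, sqrt(vcov(base)["g", "g"]), tolerance = 0.1)
})

test_that("formula interface records complete cases and predicts", {
  d <- data.frame(y = c(1, 2, 3, 4), x = c(0, 1, NA, 1))
  f <- fam_poisson(y ~ x, d)
  expect_equal(f$kept_rows, c(1L, 2L, 4L))
  p <- predict(f, newdata = data.frame(x = c(0, 1)), type = "response")
  expect_equal(unname(p[1]), unname(exp(coef(f)[1])), tolerance = 1e-8)
  r <- residuals(f, "response")
  expect_equal(unname(r), f$y - unname(fitted(f)))
  s <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(s), c(3L, 2L))
})
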