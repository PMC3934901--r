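# Independent brute-force maximiser of the Poisson log-likelihood
# (Nelder-Mead with restarts), used to validate the IRLS engine.  It
# shares nothing with the IRLS code path beyond the likelihood formula.
oracle_poisson <- function(X, y, link = "log") {
  nll <- function(b) {
    eta <- drop(X %*% b)
    mu <- if (link == "log") exp(eta) else eta
    if (any(mu <= 0)) return(1e10)
    -sum(y * log(mu) - mu - lgamma(y + 1))
  }
  b0 <- rep(0, ncol(X))
  b0[1L] <- if (link == "log") log(mean(y) + 0.5) else mean(y) + 0.5
  fit <- optim(b0, nll, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-15))
  for (i in 1:3)
    fit <- optim(fit$par, nll, method = "Nelder-Mead",
                 control = list(maxit = 10000, reltol = 1e-15))
  fit$par
}

# random small Poisson-regression instance with binary + continuous
# covariates, guaranteed full rank
random_instance <- function(n = 30, p_extra = 2) {
  repeat {
    X <- cbind(1, matrix(rbinom(n * p_extra, 1, 0.4), n, p_extra))
    if (p_extra >= 2) X[, p_extra + 1] <- rnorm(n)
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p_extra)))
    if (qr(X)$rank == ncol(X)) break
  }
  beta <- c(runif(1, 0, 1.2), runif(p_extra, -0.5, 0.5))
  y <- rpois(n, exp(drop(X %*% beta)))
  list(X = X, y = y, beta = beta)
}

# minimal hand-built cohort: two families, configurable flags
toy_cohort <- function() {
  cohort(data.frame(
    family_id  = c("f1", "f1", "f2", "f2", "f2"),
    subject_id = paste0("s", 1:5),
    age        = c(60, 70, 55, 65, 75),
    affected   = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    aggressive = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    snpA       = c("AG", "GG", "AA", "GG", NA),
    snpB       = c("GG", "GG", "AG", "AG", "AG"),
    stringsAsFactors = FALSE),
    snps = c(snpA = "A", snpB = "A"))
}

SNPS <- c("rs4242382", "rs10486567")
TABLE3_BETAS <- c(1.1815, 0.0872, 0.0085, 0.0799)
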