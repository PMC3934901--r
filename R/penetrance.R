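#' Probability of at least k cases under a Poisson rate
#'
#' Upper tail of the Poisson distribution at the fitted family rate:
#' `P(Y >= k) = 1 - F(k - 1; lambda)`.  This is the multiplex-family risk
#' implied by a fitted penetrance model — e.g. the probability that a
#' family accumulates four or more cases.
#'
#' @param lambda fitted Poisson rate(s), strictly positive.
#' @param k nonnegative integer case threshold.
#' @return Probabilities in `[0, 1]`, vectorised over `lambda`.
#' @examples
#' prob_at_least_k(1, 1)    # 1 - exp(-1)
#' prob_at_least_k(3.5, 4)
#' @export
prob_at_least_k <- function(lambda, k) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be strictly positive", call. = FALSE)
  if (length(k) != 1L || k < 0 || k != floor(k))
    stop("k must be a single nonnegative integer", call. = FALSE)
  if (k == 0) return(rep(1, length(lambda)))
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Multiplex-family risk profile by joint carrier status
#'
#' Evaluates a fitted log-link penetrance model on a grid of carrier-status
#' combinations, returning the fitted family rate and the probability of
#' at least `k` cases for each combination, together with the
#' double-carrier vs double-noncarrier contrast both as a difference and
#' as a ratio of tail probabilities.
#'
#' @param fit a log-link `"fampois"` fit from [fam_poisson()] or
#'   [build_design()]/[fit_poisson()].
#' @param k case threshold (default 4, the multiplex endpoint of
#'   interest).
#' @param combos data frame of carrier-status combinations; defaults to
#'   the full 0/1 grid over the fit's SNP terms.
#' @param covariates named list of settings for further covariates (e.g.
#'   `list(age = 65)`); an age term defaults to the fitting data's mean.
#' @return A `"penetrance_profile"` data frame with the combos, `lambda`
#'   and `prob`; attributes `risk_difference` and `risk_ratio` hold the
#'   double-carrier vs double-noncarrier contrasts.
#' @export
penetrance_profile <- function(fit, k = 4, combos = NULL,
                               covariates = list()) {
  stopifnot(inherits(fit, "fampois"))
  if (fit$link != "log")
    stop("penetrance profiles require a log-link fit", call. = FALSE)
  cn <- names(fit$coefficients)
  main <- setdiff(cn, c("(Intercept)", "age"))
  main <- main[!grepl(":", main, fixed = TRUE)]
  if (is.null(combos)) {
    if (length(main) == 0L)
      stop("fit has no carrier-status terms to profile", call. = FALSE)
    combos <- do.call(expand.grid, stats::setNames(
      rep(list(0:1), length(main)), main))
  }
  miss <- setdiff(names(combos), cn)
  if (length(miss))
    stop("combo column(s) not in the fitted model: ",
         paste(miss, collapse = ", "), call. = FALSE)
  eta <- rep(fit$coefficients[["(Intercept)"]], nrow(combos))
  for (v in names(combos)) eta <- eta + fit$coefficients[[v]] * combos[[v]]
  for (v in cn[grepl(":", cn, fixed = TRUE)]) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1L]]
    if (all(parts %in% names(combos)))
      eta <- eta + fit$coefficients[[v]] *
        Reduce(`*`, lapply(parts, function(p) combos[[p]]))
  }
  if ("age" %in% cn) {
    age_val <- if (!is.null(covariates$age)) covariates$age
    else mean(fit$X[, "age"])
    eta <- eta + fit$coefficients[["age"]] * age_val
  }
  lambda <- exp(eta)
  out <- cbind(combos, lambda = lambda,
               prob = prob_at_least_k(lambda, k))
  if (length(main) >= 1L) {
    all1 <- rowSums(combos[, main, drop = FALSE] == 1) == length(main)
    all0 <- rowSums(combos[, main, drop = FALSE] == 0) == length(main)
    if (any(all1) && any(all0)) {
      p1 <- out$prob[which(all1)[1L]]
      p0 <- out$prob[which(all0)[1L]]
      attr(out, "risk_difference") <- p1 - p0
      attr(out, "risk_ratio") <- p1 / p0
    }
  }
  attr(out, "k") <- k
  class(out) <- c("penetrance_profile", "data.frame")
  out
}

#' @export
print.penetrance_profile <- function(x, digits = 4, ...) {
  cat("Multiplex-family risk profile, P(cases >= ", attr(x, "k"),
      ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = digits)
  if (!is.null(attr(x, "risk_difference")))
    cat("double-carrier vs double-noncarrier: difference ",
        round(attr(x, "risk_difference"), digits), ", ratio ",
        round(attr(x, "risk_ratio"), digits), "\n", sep = "")
  invisible(x)
}

#' @export
plot.penetrance_profile <- function(x, ...) {
  combo_cols <- setdiff(names(x), c("lambda", "prob"))
  lab <- apply(x[, combo_cols, drop = FALSE], 1L, function(r)
    paste(ifelse(r == 1, "carrier", "noncarr."), collapse = "\n"))
  graphics::barplot(x$prob, names.arg = lab,
                    ylab = paste0("P(cases >= ", attr(x, "k"), ")"),
                    xlab = "joint carrier status", ...)
  invisible(x)
}
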