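#' Build a design/response object for the penetrance models
#'
#' Turns a cohort into the numeric design matrix and count outcome for the
#' Poisson penetrance models.  The outcome is the family's affected count
#' for the chosen endpoint; covariates are dominant carrier codes at the
#' requested SNPs (plus their product when `interaction = TRUE`, and a
#' linear age term when `adjust_age = TRUE`).  Subjects missing any
#' required covariate are dropped (complete-case) and the kept row indices
#' are recorded so sample sizes stay auditable.
#'
#' Two observation units are supported.  `unit = "subject"` replicates the
#' source study's attribution: every genotyped family member carries the
#' family's case count as their outcome (so contingency-table column
#' totals equal subject counts).  Because the outcome is then shared
#' within a family, model-based inference at this unit is anticonservative
#' under family clustering.  `unit = "family"` uses one row per family
#' with the family's modal carrier status per SNP and mean age — the
#' generative unit, giving calibrated likelihood inference.
#'
#' @param cohort a [cohort].
#' @param snps character vector of one or two SNP column names (risk
#'   alleles are taken from the cohort's declaration).
#' @param endpoint `"all"`, `"nonaggressive"` or `"aggressive"` family
#'   case count.
#' @param interaction include the product term (requires two SNPs).
#' @param adjust_age include a linear age term.
#' @param unit `"subject"` (source-study attribution) or `"family"`.
#' @return A `"design_response"` list: `X`, `y`, `labels`, `kept_rows`
#'   (row indices into the cohort, or family IDs for `unit = "family"`),
#'   `family_id`, `unit`, `endpoint`.
#' @export
build_design <- function(cohort, snps,
                         endpoint = c("all", "nonaggressive", "aggressive"),
                         interaction = FALSE, adjust_age = FALSE,
                         unit = c("subject", "family")) {
  stopifnot(inherits(cohort, "cohort"))
  endpoint <- match.arg(endpoint)
  unit <- match.arg(unit)
  declared <- attr(cohort, "snps")
  miss <- setdiff(snps, names(declared))
  if (length(miss))
    stop("SNP(s) not declared in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (interaction && length(snps) != 2L)
    stop("an interaction term requires exactly two SNPs", call. = FALSE)
  if (endpoint != "all" && all(is.na(cohort$aggressive)))
    stop("endpoint '", endpoint, "' needs aggressive-disease flags, but ",
         "none are recorded", call. = FALSE)

  fam <- family_case_counts(cohort)
  fam$outcome <- switch(endpoint,
                        all = fam$n_affected,
                        aggressive = fam$n_aggressive,
                        nonaggressive = fam$n_affected - fam$n_aggressive)
  alphabet <- attr(cohort, "alphabet")
  codes <- sapply(snps, function(s)
    dominant_code(cohort[[s]], declared[[s]], alphabet))
  codes <- matrix(codes, ncol = length(snps),
                  dimnames = list(NULL, snps))

  if (unit == "subject") {
    y <- fam$outcome[match(cohort$family_id, fam$family_id)]
    age <- cohort$age
    keep <- stats::complete.cases(codes) &
      (!adjust_age | !is.na(age))
    G <- codes[keep, , drop = FALSE]
    y <- y[keep]
    age <- age[keep]
    kept_rows <- which(keep)
    family_id <- cohort$family_id[keep]
  } else {
    # family level: modal carrier status among genotyped members
    fid <- factor(cohort$family_id, levels = fam$family_id)
    G <- sapply(snps, function(s) {
      m <- tapply(codes[, s], fid, function(v) mean(v, na.rm = TRUE))
      ifelse(is.nan(m), NA_real_, as.numeric(m >= 0.5))
    })
    G <- matrix(G, ncol = length(snps),
                dimnames = list(NULL, snps))
    age <- as.numeric(tapply(cohort$age, fid,
                             function(v) mean(v, na.rm = TRUE)))
    age[is.nan(age)] <- NA_real_
    y <- fam$outcome
    keep <- stats::complete.cases(G) & (!adjust_age | !is.na(age))
    G <- G[keep, , drop = FALSE]
    y <- y[keep]
    age <- age[keep]
    kept_rows <- fam$family_id[keep]
    family_id <- fam$family_id[keep]
  }

  X <- cbind(`(Intercept)` = 1, G)
  if (interaction)
    X <- cbind(X, structure(G[, 1L] * G[, 2L], dim = c(nrow(G), 1L),
                            dimnames = list(NULL,
                                            paste(snps, collapse = ":"))))
  if (adjust_age) X <- cbind(X, age = age)
  structure(list(X = X, y = as.integer(y), labels = colnames(X),
                 kept_rows = kept_rows, family_id = family_id,
                 unit = unit, endpoint = endpoint, snps = snps),
            class = "design_response")
}

#' @export
print.design_response <- function(x, ...) {
  cat("Design/response (", x$unit, " level, endpoint ", x$endpoint, "): ",
      nrow(x$X), " rows x ", ncol(x$X), " columns [",
      paste(x$labels, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

fit_design <- function(design, cluster = TRUE, ...) {
  fit <- fit_poisson(design$X, design$y, ...)
  fit$kept_rows <- design$kept_rows
  if (cluster && design$unit == "subject")
    fit$vcov_cluster <- cluster_vcov(fit, design$X, design$y,
                                     design$family_id)
  fit
}

#' Fit the two-locus model ladder and assemble an epistasis report
#'
#' Fits, for each requested age-adjustment setting, the five-model ladder:
#' intercept-only, each single-locus model, the two-locus additive model
#' (both main effects) and the multiplicative model (main effects plus
#' interaction).  Computes all nested likelihood-ratio tests (adding each
#' locus to the intercept-only and to the other single-locus model, and
#' additive vs multiplicative), the AIC ranking, stratified rate ratios in
#' both directions, and the epistasis-sign classification on the
#' multiplicative and additive scales.
#'
#' @inheritParams build_design
#' @param adjust_age logical vector; each value yields one report panel
#'   (the default fits both unadjusted and age-adjusted ladders, since
#'   the age-adjustment status of published single-locus fits is
#'   ambiguous).
#' @param alpha significance gate for the epistasis classification.
#' @param bonferroni apply a Bonferroni correction (by the number of LRTs
#'   in the panel) to the classification gate.
#' @return An `"epistasis_report"`: list of panels (one per
#'   age-adjustment setting), each with `fits`, `lrts`, `aics`,
#'   `stratified`, `classification`, `kept_n`.
#' @export
run_ladder <- function(cohort, snps,
                       endpoint = c("all", "nonaggressive", "aggressive"),
                       adjust_age = c(FALSE, TRUE), alpha = 0.05,
                       bonferroni = FALSE,
                       unit = c("subject", "family")) {
  endpoint <- match.arg(endpoint)
  unit <- match.arg(unit)
  if (length(snps) != 2L)
    stop("the model ladder requires exactly two SNPs", call. = FALSE)
  panels <- lapply(adjust_age, function(adj)
    ladder_panel(cohort, snps, endpoint, adj, alpha, bonferroni, unit))
  names(panels) <- ifelse(adjust_age, "age_adjusted", "unadjusted")
  structure(list(panels = panels, snps = snps, endpoint = endpoint,
                 alpha = alpha, unit = unit),
            class = "epistasis_report")
}

ladder_panel <- function(cohort, snps, endpoint, adjust_age, alpha,
                         bonferroni, unit) {
  # one complete-case set for the whole ladder so every LRT is valid
  d_full <- build_design(cohort, snps, endpoint, interaction = TRUE,
                         adjust_age = adjust_age, unit = unit)
  sub_design <- function(cols) {
    d <- d_full
    d$X <- d_full$X[, cols, drop = FALSE]
    d$labels <- cols
    d
  }
  age_col <- if (adjust_age) "age" else NULL
  specs <- list(
    intercept      = "(Intercept)",
    single_1       = c("(Intercept)", snps[1L], age_col),
    single_2       = c("(Intercept)", snps[2L], age_col),
    additive       = c("(Intercept)", snps, age_col),
    multiplicative = c("(Intercept)", snps, paste(snps, collapse = ":"),
                       age_col))
  names(specs)[2:3] <- paste0("single_", snps)
  fits <- lapply(specs, function(cols) fit_design(sub_design(cols)))

  pairs <- list(c("intercept", names(specs)[2L]),
                c("intercept", names(specs)[3L]),
                c(names(specs)[2L], "additive"),
                c(names(specs)[3L], "additive"),
                c("additive", "multiplicative"))
  lrts <- do.call(rbind, lapply(pairs, function(p) {
    t <- lrt(fits[[p[1L]]], fits[[p[2L]]])
    data.frame(nested = p[1L], full = p[2L], chi2 = t$chi2, df = t$df,
               p = t$p.value, stringsAsFactors = FALSE)
  }))
  aics <- data.frame(model = names(fits),
                     k = vapply(fits, function(f)
                       length(f$coefficients), integer(1)),
                     loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                     aic = vapply(fits, `[[`, numeric(1), "aic"),
                     converged = vapply(fits, `[[`, logical(1),
                                        "converged"),
                     stringsAsFactors = FALSE, row.names = NULL)
  aics$best <- aics$aic == min(aics$aic)
  strat <- rbind(
    stratified_rate_ratio(cohort, snps[2L], snps[1L], endpoint,
                          adjust_age, unit = unit),
    stratified_rate_ratio(cohort, snps[1L], snps[2L], endpoint,
                          adjust_age, unit = unit))
  gate_alpha <- if (bonferroni) alpha / nrow(lrts) else alpha
  panel <- list(fits = fits, lrts = lrts, aics = aics, stratified = strat,
                adjust_age = adjust_age,
                kept_n = nrow(d_full$X))
  panel$classification <- classify_epistasis(panel, snps,
                                             alpha = gate_alpha)
  panel
}

#' Stratified rate ratios of one locus within carrier strata of the other
#'
#' Fits a single-locus model for `target_snp` separately among carriers
#' and noncarriers of `stratifier_snp` and returns the per-stratum rate
#' ratio with confidence interval.  A larger ratio in the carrier stratum
#' than in the noncarrier stratum is the effect-modification signature of
#' synergistic epistasis.  Strata where the target code is constant (or
#' empty) are reported as inestimable rather than dropped.
#'
#' @inheritParams build_design
#' @param target_snp SNP whose effect is estimated per stratum.
#' @param stratifier_snp SNP defining the carrier/noncarrier strata.
#' @param level confidence level.
#' @return Data frame with one row per stratum: `target`, `stratifier`,
#'   `stratum` ("carrier"/"noncarrier"), `n`, `rate_ratio`, `lower`,
#'   `upper`, `p`, `estimable`.
#' @export
stratified_rate_ratio <- function(cohort, target_snp, stratifier_snp,
                                  endpoint = c("all", "nonaggressive",
                                               "aggressive"),
                                  adjust_age = FALSE, level = 0.95,
                                  unit = c("subject", "family")) {
  endpoint <- match.arg(endpoint)
  unit <- match.arg(unit)
  d <- build_design(cohort, c(target_snp, stratifier_snp), endpoint,
                    interaction = FALSE, adjust_age = adjust_age,
                    unit = unit)
  strata <- list(carrier = d$X[, stratifier_snp] == 1,
                 noncarrier = d$X[, stratifier_snp] == 0)
  out <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    base <- data.frame(target = target_snp, stratifier = stratifier_snp,
                       stratum = s, n = sum(idx), rate_ratio = NA_real_,
                       lower = NA_real_, upper = NA_real_, p = NA_real_,
                       estimable = FALSE, stringsAsFactors = FALSE)
    if (sum(idx) == 0L) return(base)
    cols <- c("(Intercept)", target_snp, if (adjust_age) "age")
    Xs <- d$X[idx, cols, drop = FALSE]
    if (length(unique(Xs[, target_snp])) < 2L) return(base)
    fit <- fit_poisson(Xs, d$y[idx])
    rr <- rate_ratio(fit, target_snp, level = level)
    base[c("rate_ratio", "lower", "upper", "p")] <-
      rr[1L, c("rate_ratio", "lower", "upper", "p")]
    base$estimable <- TRUE
    base
  })
  do.call(rbind, out)
}

#' Classify the sign of epistasis on the multiplicative and additive scales
#'
#' On the multiplicative (log-rate) scale the label is the sign of the
#' interaction coefficient, gated by the additive-vs-multiplicative LRT at
#' `alpha`.  On the additive (risk) scale the label is the sign of the
#' contrast of fitted means `l11 - l10 - l01 + l00` from the
#' multiplicative fit: a positive interaction coefficient that still
#' leaves the joint risk below the sum of marginal increments is negative
#' (antagonistic) epistasis on the additive scale.
#'
#' @param panel one panel of an [run_ladder()] report (or an
#'   `"epistasis_report"`, in which case every panel is classified).
#' @param snps the two SNP names.
#' @param alpha significance gate; `"none"` is returned when the gate
#'   fails.
#' @return A data frame with `scale`, `label` and the underlying contrast.
#' @export
classify_epistasis <- function(panel, snps, alpha = 0.05) {
  if (inherits(panel, "epistasis_report"))
    return(lapply(panel$panels, classify_epistasis, snps = panel$snps,
                  alpha = alpha))
  fit <- panel$fits$multiplicative
  if (!fit$converged)
    stop("multiplicative fit did not converge; cannot classify",
         call. = FALSE)
  b3 <- fit$coefficients[[paste(snps, collapse = ":")]]
  p_int <- panel$lrts$p[panel$lrts$nested == "additive" &
                          panel$lrts$full == "multiplicative"]
  gate <- is.finite(p_int) && p_int < alpha
  sign_label <- function(v, gated) {
    if (!gated || v == 0) "none" else if (v > 0) "positive" else "negative"
  }
  # fitted means on the risk scale at the four carrier combinations
  # (age, if present, held at its design mean)
  b <- fit$coefficients
  age_term <- if ("age" %in% names(b)) b[["age"]] * mean(fit$X[, "age"]) else 0
  lam <- function(g1, g2)
    exp(b[["(Intercept)"]] + b[[snps[1L]]] * g1 + b[[snps[2L]]] * g2 +
          b3 * g1 * g2 + age_term)
  contrast_add <- lam(1, 1) - lam(1, 0) - lam(0, 1) + lam(0, 0)
  data.frame(
    scale = c("multiplicative", "additive"),
    label = c(sign_label(b3, gate), sign_label(contrast_add, gate)),
    contrast = c(b3, contrast_add),
    lrt_p = p_int,
    stringsAsFactors = FALSE)
}

#' @export
print.epistasis_report <- function(x, digits = 4, ...) {
  cat("Two-locus epistasis report: ", paste(x$snps, collapse = " x "),
      " (endpoint ", x$endpoint, ", ", x$unit, " level)\n", sep = "")
  for (nm in names(x$panels)) {
    p <- x$panels[[nm]]
    cat("\n--- ", nm, " (n = ", p$kept_n, ") ---\n", sep = "")
    cat("AIC ranking:\n")
    print(transform(p$aics, loglik = round(loglik, 2),
                    aic = round(aic, 2)), row.names = FALSE)
    cat("Likelihood-ratio tests:\n")
    print(transform(p$lrts, chi2 = round(chi2, digits),
                    p = signif(p, 3)), row.names = FALSE)
    cat("Stratified rate ratios:\n")
    print(transform(p$stratified, rate_ratio = round(rate_ratio, digits),
                    lower = round(lower, digits),
                    upper = round(upper, digits), p = signif(p, 3)),
          row.names = FALSE)
    cat("Epistasis classification:\n")
    print(transform(p$classification, contrast = signif(contrast, 4),
                    lrt_p = signif(lrt_p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.epistasis_report <- function(object, ...) print(object, ...)
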