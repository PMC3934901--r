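#' Run the full familial-epistasis analysis pipeline
#'
#' Orchestrates cohort input (file or simulation), carrier contingency
#' tables, the two-locus model ladder, stratified rate ratios and the
#' multiplex-family risk profile, writing every result table as TSV plus
#' a JSON reproducibility manifest into `out_dir`.  Two runs with the
#' same configuration and seed produce byte-identical tables.
#'
#' @param input path to a cohort TSV, or `NULL` when simulating.
#' @param simulate a [sim_params()] object (or `"paper"` for the
#'   replication preset), or `NULL` when reading a file.  Exactly one of
#'   `input`/`simulate` must be given.
#' @param snps named character vector of the two SNPs' risk alleles
#'   (mandatory; there is no default risk allele).
#' @param endpoints endpoints to analyse.
#' @param adjust_age logical vector of age-adjustment settings for the
#'   ladder.
#' @param alpha classification gate passed to [run_ladder()].
#' @param k multiplex case threshold for the risk profile.
#' @param unit observation unit passed to [build_design()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for simulation.
#' @param digits decimals for numeric columns in result tables.
#' @param strict strict cohort validation (multiplex family structure).
#' @return Invisibly, a list with the cohort, reports, profile and the
#'   manifest.  On any stage failure a `FAILED` marker file with the
#'   error message is left in `out_dir` and the error is re-thrown.
#' @export
run_pipeline <- function(input = NULL, simulate = NULL, snps,
                         endpoints = c("all", "nonaggressive",
                                       "aggressive"),
                         adjust_age = c(FALSE, TRUE), alpha = 0.05,
                         k = 4, unit = c("subject", "family"),
                         out_dir, seed = NULL, digits = 4,
                         strict = FALSE) {
  unit <- match.arg(unit)
  if (missing(snps) || is.null(snps) || is.null(names(snps)))
    stop("risk alleles are mandatory: supply snps = c(<snp> = <allele>, ...)",
         call. = FALSE)
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be given",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  result <- tryCatch({
    coh <- if (!is.null(input)) {
      read_cohort(input, snps = snps, strict = strict)
    } else {
      p <- if (identical(simulate, "paper")) sim_params() else simulate
      stopifnot(inherits(p, "sim_params"))
      simulate_cohort(p, seed = seed)
    }
    snp_names <- names(attr(coh, "snps"))

    # carrier contingency tables, both SNPs x both table endpoints
    for (s in snp_names) for (ep in c("all", "aggressive")) {
      tab <- carrier_count_table(coh, s, endpoint = ep)
      write_table(table_with_total(tab),
                  file.path(out_dir,
                            sprintf("table1_%s_%s.tsv", s, ep)),
                  digits = 1)
    }

    reports <- list()
    kept_n <- list()
    for (ep in endpoints) {
      rep_ep <- run_ladder(coh, snp_names, endpoint = ep,
                           adjust_age = adjust_age, alpha = alpha,
                           unit = unit)
      reports[[ep]] <- rep_ep
      for (nm in names(rep_ep$panels)) {
        panel <- rep_ep$panels[[nm]]
        kept_n[[paste(ep, nm, sep = "_")]] <- panel$kept_n
        coefs <- do.call(rbind, lapply(names(panel$fits), function(m) {
          f <- panel$fits[[m]]
          data.frame(model = m, term = names(f$coefficients),
                     coefficient = unname(f$coefficients),
                     se = sqrt(diag(f$vcov)), converged = f$converged,
                     stringsAsFactors = FALSE)
        }))
        stub <- sprintf("%s_%s", ep, nm)
        write_table(coefs,
                    file.path(out_dir, sprintf("fits_%s.tsv", stub)),
                    digits = digits)
        write_table(panel$lrts,
                    file.path(out_dir, sprintf("lrt_%s.tsv", stub)),
                    digits = digits)
        write_table(panel$aics,
                    file.path(out_dir, sprintf("aic_%s.tsv", stub)),
                    digits = 2)
        write_table(panel$stratified,
                    file.path(out_dir,
                              sprintf("stratified_%s.tsv", stub)),
                    digits = 2)
        write_table(panel$classification,
                    file.path(out_dir,
                              sprintf("classification_%s.tsv", stub)),
                    digits = digits)
      }
    }

    # multiplex risk profile from the all-cases multiplicative fit
    prof <- NULL
    if ("all" %in% endpoints) {
      fit <- reports[["all"]]$panels[[1L]]$fits$multiplicative
      prof <- penetrance_profile(fit, k = k)
      ptab <- as.data.frame(prof)
      ptab$risk_difference <- c(attr(prof, "risk_difference"),
                                rep(NA_real_, nrow(ptab) - 1L))
      write_table(ptab, file.path(out_dir, "penetrance_profile.tsv"),
                  digits = digits)
    }

    manifest <- list(
      package = "famepi",
      version = as.character(utils::packageVersion("famepi")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      input = if (!is.null(input)) input else "simulated",
      seed = seed, snps = as.list(snps),
      endpoints = endpoints, adjust_age = adjust_age, alpha = alpha,
      k = k, unit = unit,
      n_subjects = nrow(coh),
      n_families = length(unique(coh$family_id)),
      complete_case_n = kept_n,
      converged = lapply(reports, function(r)
        lapply(r$panels, function(p)
          vapply(p$fits, `[[`, logical(1), "converged"))))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(cohort = coh, reports = reports, profile = prof,
         manifest = manifest)
  }, error = function(e) {
    writeLines(conditionMessage(e), failed_marker)
    stop(e)
  })
  invisible(result)
}
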