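#' Per-family case counts
#'
#' Summarises each family of a cohort: number of members, number affected
#' and number with aggressive disease.  The distribution of `n_affected`
#' across families is the familial-aggregation outcome used throughout the
#' penetrance models.
#'
#' @param cohort a [cohort].
#' @return A data frame with columns `family_id`, `n_members`,
#'   `n_affected`, `n_aggressive`, one row per family, in order of first
#'   appearance.
#' @export
family_case_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  fid <- factor(cohort$family_id, levels = unique(cohort$family_id))
  out <- data.frame(
    family_id    = levels(fid),
    n_members    = as.integer(table(fid)),
    n_affected   = as.integer(tapply(cohort$affected, fid, sum)),
    n_aggressive = as.integer(tapply(!is.na(cohort$aggressive) &
                                       cohort$aggressive, fid, sum)),
    stringsAsFactors = FALSE)
  stopifnot(all(out$n_aggressive <= out$n_affected),
            all(out$n_affected <= out$n_members))
  out
}

#' Dominant carrier coding of a genotype
#'
#' Codes a genotype 1 if the risk allele appears at least once (carrier:
#' homozygous or heterozygous) and 0 otherwise; missing genotypes stay
#' missing.  This is the carrier/noncarrier collapse (e.g. AA or GA vs GG)
#' used by all models in the package.
#'
#' @param genotype character vector of two-allele genotypes (`NA` allowed).
#' @param risk_allele single allele character.
#' @param alphabet allowed alleles.
#' @return Integer vector of 0/1/`NA`.
#' @examples
#' dominant_code(c("AG", "GG", "AA", NA), "A")  # 1 0 1 NA
#' @export
dominant_code <- function(genotype, risk_allele, alphabet = c("A", "G")) {
  if (length(risk_allele) != 1L || !(risk_allele %in% alphabet))
    stop("risk allele '", risk_allele, "' is not in the allele alphabet",
         call. = FALSE)
  g <- as.character(genotype)
  out <- rep(NA_integer_, length(g))
  idx <- !is.na(g)
  out[idx] <- as.integer(grepl(risk_allele, g[idx], fixed = TRUE))
  out
}

# Default outcome bins replicating the published contingency layout:
# family case count {2,3,4,5+} for all cases, {0,1,2,3} for aggressive.
default_bins <- function(endpoint) {
  switch(endpoint, all = c("2", "3", "4", "5+"),
         aggressive = c("0", "1", "2", "3"))
}

assign_bins <- function(counts, bins) {
  open <- grepl("\\+$", bins)
  if (sum(open) > 1L) stop("at most one open-ended bin ('k+') allowed",
                           call. = FALSE)
  lab <- rep(NA_character_, length(counts))
  vals <- suppressWarnings(as.integer(sub("\\+$", "", bins)))
  for (i in seq_along(bins)) {
    hit <- if (open[i]) counts >= vals[i] else counts == vals[i]
    lab[hit & is.na(lab)] <- bins[i]
  }
  if (anyNA(lab))
    stop("bin specification does not cover observed count(s): ",
         paste(unique(counts[is.na(lab)]), collapse = ", "), call. = FALSE)
  factor(lab, levels = bins)
}

#' Carrier contingency table by family case count
#'
#' Cross-tabulates carrier status at one SNP against the per-family case
#' count, every genotyped member of a family contributing one row with the
#' family's count as outcome (so column totals equal the number of
#' genotyped subjects).  Row percentages are reported to one decimal.
#'
#' @param cohort a [cohort].
#' @param snp SNP column name.
#' @param endpoint `"all"` (total affected per family) or `"aggressive"`.
#' @param bins character vector of bin labels; integers plus at most one
#'   open-ended `"k+"` label.  Defaults to the endpoint's standard preset.
#' @return A `"carrier_table"` data frame with columns `bin`,
#'   `noncarrier_n`, `noncarrier_pct`, `carrier_n`, `carrier_pct`.
#' @export
carrier_count_table <- function(cohort, snp,
                                endpoint = c("all", "aggressive"),
                                bins = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  endpoint <- match.arg(endpoint)
  snps <- attr(cohort, "snps")
  if (!(snp %in% names(snps)))
    stop("SNP '", snp, "' is not declared in the cohort", call. = FALSE)
  fam <- family_case_counts(cohort)
  cnt <- if (endpoint == "all") fam$n_affected else fam$n_aggressive
  names(cnt) <- fam$family_id
  if (is.null(bins)) {
    # published preset when it covers the data, else one bin per
    # observed count
    bins <- default_bins(endpoint)
    covered <- tryCatch({assign_bins(cnt, bins); TRUE},
                        error = function(e) FALSE)
    if (!covered) bins <- as.character(sort(unique(cnt)))
  }
  carrier <- dominant_code(cohort[[snp]], snps[[snp]],
                           attr(cohort, "alphabet"))
  keep <- !is.na(carrier)
  bin <- assign_bins(cnt[cohort$family_id[keep]], bins)
  tab <- table(bin, factor(carrier[keep], levels = 0:1))
  n0 <- as.integer(tab[, 1L]); n1 <- as.integer(tab[, 2L])
  tot <- n0 + n1
  pct <- function(n) ifelse(tot == 0, NA_real_, round(100 * n / tot, 1))
  structure(
    data.frame(bin = bins, noncarrier_n = n0, noncarrier_pct = pct(n0),
               carrier_n = n1, carrier_pct = pct(n1),
               stringsAsFactors = FALSE),
    snp = snp, endpoint = endpoint,
    totals = c(noncarrier = sum(n0), carrier = sum(n1)),
    class = c("carrier_table", "data.frame"))
}

#' @export
print.carrier_table <- function(x, ...) {
  cat("Carrier contingency table for ", attr(x, "snp"),
      " (endpoint: ", attr(x, "endpoint"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "totals")
  cat("Total  noncarriers:", tot["noncarrier"],
      " carriers:", tot["carrier"], "\n")
  invisible(x)
}

#' Append a totals row to a carrier contingency table
#'
#' Returns the table as a plain data frame with a final `Total` row of
#' column sums (percent columns left blank), the layout used in the
#' published table.
#'
#' @param table a `"carrier_table"`.
#' @return A data frame with `nrow(table) + 1` rows.
#' @export
table_with_total <- function(table) {
  stopifnot(inherits(table, "carrier_table"))
  out <- as.data.frame(table)
  out[nrow(out) + 1L, ] <- list("Total", sum(table$noncarrier_n),
                                NA_real_, sum(table$carrier_n), NA_real_)
  out
}

#' Chi-square tests on a carrier contingency table
#'
#' Pearson chi-square of independence on the K x 2 count table
#' (df = K - 1), or a Cochran-Armitage-style trend test across the ordered
#' bins (`test = "trend"`).
#'
#' @param table a `"carrier_table"` from [carrier_count_table()], or a
#'   K x 2 count matrix.
#' @param test `"pearson"` (default) or `"trend"`.
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
contingency_chisq <- function(table, test = c("pearson", "trend")) {
  test <- match.arg(test)
  m <- if (inherits(table, "carrier_table"))
    cbind(table$noncarrier_n, table$carrier_n)
  else as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 outcome bins", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero expected cell count; merge sparse bins before testing",
         call. = FALSE)
  if (test == "pearson") {
    ht <- stats::chisq.test(m, correct = FALSE)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value))
  } else {
    ht <- stats::prop.trend.test(m[, 2L], rowSums(m), score = seq_len(nrow(m)))
    list(statistic = unname(ht$statistic), df = 1L,
         p.value = unname(ht$p.value))
  }
}
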