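#' Assemble and validate a family cohort
#'
#' A cohort is a data frame with one row per subject and columns
#' `family_id`, `subject_id`, `age`, `affected`, `aggressive`, plus one
#' character column per SNP holding a two-letter genotype (alphabetically
#' normalised, e.g. `"AG"`) or `NA`.  The SNP columns and their declared
#' risk alleles are carried in the `"snps"` attribute; risk alleles are
#' mandatory, explicit configuration and are never defaulted.
#'
#' @param data data frame with the columns listed above.
#' @param snps named character vector mapping SNP column names to their
#'   risk allele, e.g. `c(rs4242382 = "A", rs10486567 = "A")`.
#' @param alphabet allowed alleles at every SNP.
#' @param strict when `TRUE`, additionally require every family to have at
#'   least two members and between 2 and 6 affected members, the multiplex
#'   ascertainment condition of the replication cohort.
#' @return An object of class `"cohort"` (a validated data frame).
#' @export
cohort <- function(data, snps, alphabet = c("A", "G"), strict = FALSE) {
  stopifnot(is.data.frame(data))
  if (length(snps) == 0L || is.null(names(snps)) || any(names(snps) == ""))
    stop("'snps' must be a named character vector of risk alleles ",
         "(risk alleles are mandatory configuration)", call. = FALSE)
  needed <- c("family_id", "subject_id", "age", "affected", "aggressive",
              names(snps))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("cohort data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[, needed]
  data$family_id  <- as.character(data$family_id)
  data$subject_id <- as.character(data$subject_id)
  data$age        <- as.numeric(data$age)
  data$affected   <- as.logical(data$affected)
  data$aggressive <- as.logical(data$aggressive)
  for (s in names(snps)) {
    data[[s]] <- normalize_genotype(data[[s]], snp = s, alphabet = alphabet)
    if (!(snps[[s]] %in% alphabet))
      stop("risk allele '", snps[[s]], "' for ", s,
           " is not in the allele alphabet", call. = FALSE)
  }
  obj <- structure(data,
                   snps = snps, alphabet = alphabet,
                   class = c("cohort", "data.frame"))
  validate_cohort(obj, strict = strict)
  obj
}

# Sort each two-allele genotype string and check it against the alphabet.
# Errors name the offending row so malformed files are diagnosable.
normalize_genotype <- function(x, snp, alphabet) {
  x <- as.character(x)
  x[x %in% c("NA", "", ".", "00", "0")] <- NA_character_
  ok <- is.na(x) | (nchar(x) == 2L &
                      substr(x, 1, 1) %in% alphabet &
                      substr(x, 2, 2) %in% alphabet)
  if (!all(ok))
    stop("malformed genotype for ", snp, " at row(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ", "),
         ": expected two alleles from {",
         paste(alphabet, collapse = ","), "} or NA", call. = FALSE)
  idx <- !is.na(x)
  x[idx] <- vapply(strsplit(x[idx], ""),
                   function(a) paste(sort(a), collapse = ""), character(1))
  x
}

validate_cohort <- function(x, strict = FALSE) {
  dup <- duplicated(x$subject_id)
  if (any(dup))
    stop("duplicate subject_id at row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  if (any(!is.na(x$age) & x$age < 0))
    stop("negative age at row(s) ",
         paste(utils::head(which(!is.na(x$age) & x$age < 0), 5L),
               collapse = ", "), call. = FALSE)
  bad_aggr <- !is.na(x$aggressive) & x$aggressive & !x$affected
  if (any(bad_aggr))
    stop("aggressive = TRUE with affected = FALSE at row(s) ",
         paste(utils::head(which(bad_aggr), 5L), collapse = ", "),
         call. = FALSE)
  if (strict) {
    n_mem <- table(x$family_id)
    n_aff <- tapply(x$affected, x$family_id, sum)
    small <- names(n_mem)[n_mem < 2L]
    if (length(small))
      stop("strict mode: family(ies) with fewer than 2 members: ",
           paste(utils::head(small, 5L), collapse = ", "), call. = FALSE)
    out <- names(n_aff)[n_aff < 2L | n_aff > 6L]
    if (length(out))
      stop("strict mode: family(ies) with affected count outside 2-6: ",
           paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read a cohort from a tab-separated file
#'
#' The canonical cohort file is UTF-8 TSV with a header row and columns
#' `family_id`, `subject_id`, `age`, `affected`, `aggressive` and one
#' column per SNP with two-character genotypes (`"NA"` for missing).
#' Genotypes are order-insensitive and normalised to sorted allele order on
#' read; missing genotypes are preserved, never imputed; row order is kept.
#'
#' @inheritParams cohort
#' @param path path to the TSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (and SNP names) to the file's column names.
#' @param missing_token token denoting a missing value (default `"NA"`).
#' @return A [cohort] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_cohort(fixture_table1(), tf)
#' coh <- read_cohort(tf, snps = c(rs4242382 = "A", rs10486567 = "A"))
#' nrow(coh)  # 947
#' @export
read_cohort <- function(path, snps, schema = NULL, strict = FALSE,
                        alphabet = c("A", "G"), missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = missing_token,
                           check.names = FALSE, quote = "", comment.char = "")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!(schema[[canon]] %in% names(raw)))
        stop("schema column '", schema[[canon]], "' not found in header",
             call. = FALSE)
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  cohort(raw, snps = snps, alphabet = alphabet, strict = strict)
}

#' Read a PED-style genotype file as a cohort
#'
#' Secondary entry point for interoperability with genotype tooling: a
#' whitespace-delimited file without header whose columns are family ID,
#' individual ID, phenotype (1 = unaffected, 2 = affected), then two
#' single-allele columns per SNP (`0` = missing).  PED files carry no age
#' or disease-aggressiveness information, so those fields are `NA`.
#'
#' @inheritParams read_cohort
#' @return A [cohort] object.
#' @export
read_ped <- function(path, snps, strict = FALSE, alphabet = c("A", "G")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  k <- length(snps)
  if (ncol(raw) != 3L + 2L * k)
    stop("PED file has ", ncol(raw), " columns; expected ", 3L + 2L * k,
         " (family, individual, phenotype, 2 allele columns per SNP)",
         call. = FALSE)
  pheno <- raw[[3L]]
  if (!all(pheno %in% c("1", "2")))
    stop("PED phenotype must be 1 (unaffected) or 2 (affected); offending ",
         "row(s): ", paste(utils::head(which(!pheno %in% c("1", "2")), 5L),
                           collapse = ", "), call. = FALSE)
  out <- data.frame(family_id  = raw[[1L]],
                    subject_id = raw[[2L]],
                    age        = NA_real_,
                    affected   = pheno == "2",
                    aggressive = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    a1 <- raw[[2L + 2L * i]]
    a2 <- raw[[3L + 2L * i]]
    g <- paste0(a1, a2)
    g[a1 == "0" | a2 == "0"] <- NA_character_
    out[[names(snps)[i]]] <- g
  }
  cohort(out, snps = snps, alphabet = alphabet, strict = strict)
}

#' Write a cohort to the canonical TSV format
#'
#' @param x a [cohort].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  write_table(as.data.frame(x), path, format = "tsv", digits = 6)
}

#' Write a result table deterministically
#'
#' Columns keep their order; numeric columns are formatted at a fixed
#' number of decimals so identical inputs yield byte-identical files.
#'
#' @param rows a data frame of homogeneous result records (may be empty).
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @param digits decimals used for numeric (non-integer) columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv"), digits = 4) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  sep <- if (format == "tsv") "\t" else ","
  out <- rows
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v) && !is.integer(v)) {
      out[[j]] <- ifelse(is.na(v),
                         "NA", formatC(v, digits = digits, format = "f"))
    } else if (is.logical(v) || is.integer(v)) {
      out[[j]] <- ifelse(is.na(v), "NA", as.character(v))
    } else {
      out[[j]] <- ifelse(is.na(v), "NA", as.character(v))
    }
  }
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  lines <- c(paste(names(out), collapse = sep),
             if (nrow(out))
               do.call(paste, c(unname(as.list(out)), list(sep = sep))))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  snps <- attr(x, "snps")
  cat("Family cohort: ", nrow(x), " subjects in ",
      length(unique(x$family_id)), " families; ",
      sum(x$affected), " affected (",
      sum(x$aggressive, na.rm = TRUE), " aggressive)\n", sep = "")
  cat("SNPs (risk allele): ",
      paste(names(snps), snps, sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.cohort` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("family_id", "affected") %in% names(out))) {
    attr(out, "snps") <- attr(x, "snps")
    attr(out, "alphabet") <- attr(x, "alphabet")
    class(out) <- c("cohort", "data.frame")
  }
  out
}
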