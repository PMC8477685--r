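#' Construct a cohort table
#'
#' A cohort table holds one row per subject per timepoint: a numeric
#' matrix of variable values together with subject identifiers, a
#' per-row sex label (`"male"`/`"female"`) and a per-row timepoint label
#' (`"baseline"`/`"followup"`), plus a variable specification assigning
#' each column a role (`metabolite` or `covariate`).  No missing values
#' are allowed: the analysis is complete-case by design and never imputes.
#'
#' @param values Numeric matrix, subjects x variables.
#' @param subject_id Character vector of subject identifiers (one per row).
#' @param sex Character vector of `"male"`/`"female"` labels (one per row).
#' @param timepoint Character vector of `"baseline"`/`"followup"` labels.
#' @param variables A variable specification data.frame from
#'   [variable_spec()] or [trp_variables()]; must match `ncol(values)`.
#' @return An object of class `tn_cohort`.
#' @export
cohort_table <- function(values, subject_id, sex, timepoint, variables) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  variables <- variables[, c("name", "role", "unit")]
  if (ncol(values) != nrow(variables)) {
    stop("values has ", ncol(values), " columns but variables describes ",
         nrow(variables))
  }
  if (length(subject_id) != n || length(sex) != n || length(timepoint) != n) {
    stop("subject_id, sex and timepoint must each have one entry per row")
  }
  if (anyNA(values)) {
    bad <- which(rowSums(is.na(values)) > 0)
    stop("missing values in row(s) ", paste(head(bad, 5), collapse = ", "),
         "; cohort tables are complete-case and values are never imputed")
  }
  bad_sex <- setdiff(unique(sex), c("male", "female"))
  if (length(bad_sex)) stop("unknown sex label(s): ",
                            paste(bad_sex, collapse = ", "))
  bad_tp <- setdiff(unique(timepoint), c("baseline", "followup"))
  if (length(bad_tp)) stop("unknown timepoint label(s): ",
                           paste(bad_tp, collapse = ", "))
  key <- paste(subject_id, timepoint)
  if (anyDuplicated(key)) {
    stop("duplicated (subject, timepoint) combination: ",
         key[anyDuplicated(key)])
  }
  colnames(values) <- variables$name
  structure(list(values = values,
                 subject_id = as.character(subject_id),
                 sex = as.character(sex),
                 timepoint = as.character(timepoint),
                 variables = variables),
            class = "tn_cohort")
}

#' @export
print.tn_cohort <- function(x, ...) {
  cat("Cohort table:", nrow(x$values), "rows x", ncol(x$values),
      "variables\n")
  cat("  metabolites:", sum(x$variables$role == "metabolite"),
      " covariates:", sum(x$variables$role == "covariate"), "\n")
  tab <- table(x$sex, x$timepoint)
  print(tab)
  invisible(x)
}

#' @export
dim.tn_cohort <- function(x) dim(x$values)

#' Read a cohort table from a delimited file
#'
#' Expects a header row with an `id` column, a `sex` column, a
#' `timepoint` column and one numeric column per variable in `schema`.
#' Any missing or non-numeric cell is an error (no imputation).
#'
#' @param path Path to a CSV (or TSV, `sep = "\t"`) file.
#' @param schema Variable specification ([variable_spec()]); defaults to
#'   the full tryptophan vocabulary of [trp_variables()].
#' @param sep Field separator, `","` by default.
#' @param id_col,sex_col,timepoint_col Column names for the identifier
#'   and stratification labels.
#' @return A `tn_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema = trp_variables(), sep = ",",
                        id_col = "id", sex_col = "sex",
                        timepoint_col = "timepoint") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c(id_col, sex_col, timepoint_col, schema$name)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(df), nrow(schema),
                 dimnames = list(NULL, schema$name))
  for (v in schema$name) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !nzchar(trimws(raw)))
    if (length(bad)) {
      stop("validation error: missing or non-numeric value for '", v,
           "' in data row(s) ", paste(head(bad, 5), collapse = ", "))
    }
    vals[, v] <- num
  }
  cohort_table(vals, df[[id_col]], df[[sex_col]], df[[timepoint_col]],
               schema)
}

#' Write a cohort table to CSV
#'
#' @param table A `tn_cohort`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "tn_cohort"))
  df <- data.frame(id = table$subject_id, sex = table$sex,
                   timepoint = table$timepoint,
                   as.data.frame(table$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize all variables to mean zero, unit standard deviation
#'
#' Every variable (metabolites and covariates alike) is z-scored using the
#' sample standard deviation (denominator n - 1).  Standardization is
#' idempotent to numerical tolerance.  By default the analysis pipeline
#' re-applies standardization within each sex-by-timepoint stratum that is
#' actually fed to a network fit.
#'
#' @param table A `tn_cohort`.
#' @return A `tn_cohort` whose columns have mean 0 and sample sd 1.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "tn_cohort"))
  v <- table$values
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(v)[sds == 0 | !is.finite(sds)]
    stop("degenerate variable(s) with zero variance: ",
         paste(bad, collapse = ", "))
  }
  table$values <- scale(v)[, , drop = FALSE]
  attr(table$values, "scaled:center") <- NULL
  attr(table$values, "scaled:scale") <- NULL
  table
}

#' Extract a sex-by-timepoint stratum
#'
#' Networks are fitted per sex and timepoint; this returns the matching
#' sub-table.  When `include_covariates` is `FALSE` the covariate columns
#' are dropped (unadjusted networks over the 19 metabolites only).  By
#' default the stratum is re-standardized, so that each network sees
#' variables with mean 0 and sd 1 within its own stratum; set
#' `restandardize = FALSE` to keep pooled scaling.
#'
#' @param table A `tn_cohort`.
#' @param sex `"male"` or `"female"`, or `NULL` to keep both.
#' @param timepoint `"baseline"` or `"followup"`, or `NULL` to keep both.
#' @param include_covariates Keep covariate columns as network nodes?
#' @param restandardize Re-apply [standardize()] within the stratum.
#' @return A `tn_cohort`.
#' @export
stratify <- function(table, sex = NULL, timepoint = NULL,
                     include_covariates = TRUE, restandardize = TRUE) {
  stopifnot(inherits(table, "tn_cohort"))
  keep <- rep(TRUE, nrow(table$values))
  if (!is.null(sex)) {
    if (!sex %in% table$sex) stop("no rows with sex label '", sex, "'")
    keep <- keep & table$sex == sex
  }
  if (!is.null(timepoint)) {
    if (!timepoint %in% table$timepoint) {
      stop("no rows with timepoint label '", timepoint, "'")
    }
    keep <- keep & table$timepoint == timepoint
  }
  if (!any(keep)) stop("empty stratum: sex=", sex, " timepoint=", timepoint)
  vars <- table$variables
  cols <- if (include_covariates) vars$name else
    vars$name[vars$role == "metabolite"]
  out <- cohort_table(table$values[keep, cols, drop = FALSE],
                      table$subject_id[keep], table$sex[keep],
                      table$timepoint[keep],
                      vars[vars$name %in% cols, , drop = FALSE])
  if (restandardize) out <- standardize(out)
  out
}
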