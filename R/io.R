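# CSV interchange: plate-export-style reaction tables, blank panels and
# sample manifests, with schema validation that names the offending rows.

read_checked_csv <- function(path, required, integer_cols = character(0),
                             what = "table") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort(paste0("no records in ", what, " file: ", path))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(what, " file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in integer_cols) {
    v <- df[[col]]
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad)) {
      abort(sprintf("%s file: column '%s' must hold nonnegative integers (rows %s)",
                    what, col, paste(head(bad, 5), collapse = ", ")))
    }
    df[[col]] <- as.integer(v)
  }
  as_tibble(df)
}

#' Read a reaction-count table (one row per well)
#'
#' Expected columns: `sample_id`, `assay_id`, `role`, `n_droplets`,
#' `k_mutant`, `k_wildtype` (plus any extras such as `plate`, `well`,
#' `eluate_ul`, which are carried through). Count invariants are enforced
#' with row numbers in the error message.
#'
#' @param path CSV file path.
#' @return A validated reaction tibble.
#' @export
read_reactions <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("sample_id", "assay_id", "role", "n_droplets", "k_mutant",
                 "k_wildtype"),
    integer_cols = c("n_droplets", "k_mutant", "k_wildtype"),
    what = "reaction"
  )
  bad <- which(df$k_mutant > df$n_droplets | df$k_wildtype > df$n_droplets)
  if (length(bad)) {
    abort(sprintf("reaction file: positive droplets exceed droplet count (rows %s)",
                  paste(head(bad, 5), collapse = ", ")))
  }
  roles <- c("sample", "NTC", "positive_control", "negative_control")
  bad_role <- which(!df$role %in% roles)
  if (length(bad_role)) {
    abort(sprintf("reaction file: unknown role (rows %s); expected %s",
                  paste(head(bad_role, 5), collapse = ", "),
                  paste(roles, collapse = "/")))
  }
  df
}

#' Read a blank-panel table for noise profiling
#'
#' Expected columns: `assay_id`, `blank_id`, `ge_screened`, `fp_count`.
#'
#' @param path CSV file path.
#' @return A validated blank tibble.
#' @export
read_blanks <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("assay_id", "blank_id", "ge_screened", "fp_count"),
    integer_cols = "fp_count",
    what = "blank"
  )
  bad <- which(!is.finite(df$ge_screened) | df$ge_screened <= 0)
  if (length(bad)) {
    abort(sprintf("blank file: ge_screened must be positive (rows %s)",
                  paste(head(bad, 5), collapse = ", ")))
  }
  df
}

#' Read a sample manifest
#'
#' Expected columns: `sample_id`, `patient_id`, `time_months`,
#' `timing_class`.
#'
#' @param path CSV file path.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("sample_id", "patient_id", "time_months", "timing_class"),
    what = "manifest"
  )
  classes <- c("preop", "postop_window", "surveillance")
  bad <- which(!df$timing_class %in% classes)
  if (length(bad)) {
    abort(sprintf("manifest file: unknown timing_class (rows %s); expected %s",
                  paste(head(bad, 5), collapse = ", "),
                  paste(classes, collapse = "/")))
  }
  if (any(duplicated(df$sample_id))) abort("manifest file: duplicated sample_id")
  df
}

#' Write a per-sample call table to CSV
#'
#' @param calls A call tibble (e.g. `$calls` of [compare_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  keep <- !vapply(calls, is.list, logical(1))
  utils::write.csv(calls[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
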