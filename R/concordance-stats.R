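# Concordance, specificity, correlation and lead-time statistics for the
# paired ST/MT call tables.

#' Cross-tabulate paired ST and MT calls
#'
#' @param calls Either a tibble with logical columns `st_positive` and
#'   `mt_positive` (one row per sample), or nothing if the four cell counts
#'   are given directly.
#' @param n_both_pos,n_st_only,n_mt_only,n_both_neg Cell counts, used when
#'   `calls` is `NULL`.
#'
#' @return An object of class `concordance_table` (a named list of the four
#'   cells with a `total`).
#' @examples
#' concordance_table(n_both_pos = 134, n_st_only = 11,
#'                   n_mt_only = 27, n_both_neg = 207)
#' @export
concordance_table <- function(calls = NULL, n_both_pos = NULL,
                              n_st_only = NULL, n_mt_only = NULL,
                              n_both_neg = NULL) {
  if (!is.null(calls)) {
    stopifnot(is.data.frame(calls),
              all(c("st_positive", "mt_positive") %in% names(calls)))
    ok <- complete.cases(calls[, c("st_positive", "mt_positive")])
    st <- calls$st_positive[ok]
    mt <- calls$mt_positive[ok]
    n_both_pos <- sum(st & mt)
    n_st_only <- sum(st & !mt)
    n_mt_only <- sum(!st & mt)
    n_both_neg <- sum(!st & !mt)
  }
  cells <- c(n_both_pos, n_st_only, n_mt_only, n_both_neg)
  if (any(is.null(cells)) || any(cells < 0)) {
    abort("all four cell counts must be nonnegative")
  }
  structure(
    list(n_both_pos = n_both_pos, n_st_only = n_st_only,
         n_mt_only = n_mt_only, n_both_neg = n_both_neg,
         total = sum(cells)),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  m <- as.matrix(x)
  cat("<concordance_table> N =", x$total, "\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.concordance_table <- function(x, ...) {
  matrix(c(x$n_both_pos, x$n_st_only, x$n_mt_only, x$n_both_neg),
         nrow = 2, byrow = TRUE,
         dimnames = list(ST = c("pos", "neg"), MT = c("pos", "neg")))
}

as_conc_table <- function(x) {
  if (inherits(x, "concordance_table")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2, 2))) {
    return(concordance_table(n_both_pos = x[1, 1], n_st_only = x[1, 2],
                             n_mt_only = x[2, 1], n_both_neg = x[2, 2]))
  }
  if (is.data.frame(x)) return(concordance_table(x))
  abort("expected a concordance_table, a 2x2 matrix, or a calls data frame")
}

#' Cohen's kappa for a paired 2x2 call table
#'
#' \eqn{\kappa = (P_o - P_e) / (1 - P_e)} with observed agreement
#' \eqn{P_o = (a + d)/N} and expected agreement \eqn{P_e} from the marginal
#' positivity rates of the two methods.
#'
#' @param table A [concordance_table()], 2x2 matrix, or calls data frame.
#' @return Kappa in \[-1, 1\]. Degenerate margins (expected agreement 1) are
#'   an error.
#' @examples
#' cohens_kappa(concordance_table(n_both_pos = 134, n_st_only = 11,
#'                                n_mt_only = 27, n_both_neg = 207))
#' @export
cohens_kappa <- function(table) {
  tab <- as_conc_table(table)
  n <- tab$total
  if (n == 0) abort("empty table")
  po <- (tab$n_both_pos + tab$n_both_neg) / n
  st_pos <- (tab$n_both_pos + tab$n_st_only) / n
  mt_pos <- (tab$n_both_pos + tab$n_mt_only) / n
  pe <- st_pos * mt_pos + (1 - st_pos) * (1 - mt_pos)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    abort("degenerate margins: expected agreement is 1, kappa undefined")
  }
  (po - pe) / (1 - pe)
}

#' Raw agreement fraction of a paired 2x2 call table
#'
#' @inheritParams cohens_kappa
#' @return `(a + d) / N`, the fraction of samples classified the same.
#' @export
agreement_fraction <- function(table) {
  tab <- as_conc_table(table)
  if (tab$total == 0) abort("empty table")
  (tab$n_both_pos + tab$n_both_neg) / tab$total
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials (positive).
#' @param confidence Confidence level (default 0.95).
#'
#' @return Named numeric vector `c(lower, upper)`, a subset of \[0, 1\]
#'   containing `k/n`.
#' @examples
#' wilson_interval(3, 124)
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (n <= 0) abort("`n` must be positive")
  if (k < 0 || k > n) abort("`k` must satisfy 0 <= k <= n")
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the sum-of-small-point-probabilities convention:
#' the probability, over all tables with the observed margins, of those at
#' most as probable as the observed one. Tables with an empty margin carry no
#' evidence and return p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A tibble with `p_value` and the conditional odds-ratio estimate.
#' @examples
#' fisher_exact(matrix(c(1, 10, 17, 10), nrow = 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  if (inherits(table, "concordance_table")) table <- as.matrix(table)
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` must hold nonnegative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(p_value = 1, odds_ratio = NA_real_))
  }
  ft <- fisher.test(table)
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p-value for small untied samples, normal
#' approximation with tie correction otherwise (the standard behaviour of
#' [stats::wilcox.test()], which this wraps).
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return Tibble with `statistic` (Mann-Whitney U of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  wt <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Two-sided Wilcoxon signed-rank test on paired data
#'
#' Zero differences are dropped (with all-zero input the test carries no
#' evidence and p = 1 is returned with a warning); midranks are used on tied
#' absolute differences.
#'
#' @param x Numeric vector of differences, or first members of the pairs.
#' @param y Optional second members; differences are `x - y`.
#' @return Tibble with `statistic` (V) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (length(d) == 0) abort("no pairs supplied")
  if (all(d == 0)) {
    warn("all differences are zero; p = 1")
    return(tibble(statistic = 0, p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = NULL, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Log-log linear regression of paired ctDNA levels
#'
#' Least squares on `log10(mt_level) ~ log10(st_level)` over samples called
#' positive by both methods, with the Pearson correlation of the logged
#' levels. Any nonpositive level violates the both-positive filter and is an
#' error.
#'
#' @param levels Tibble with strictly positive columns `st_level` and
#'   `mt_level`.
#' @return An object of class `loglog_fit` with elements `slope`,
#'   `intercept`, `r`, `n` and the underlying `lm` fit. `tidy()` and
#'   `glance()` methods are provided.
#' @export
pearson_loglog <- function(levels) {
  stopifnot(is.data.frame(levels),
            all(c("st_level", "mt_level") %in% names(levels)))
  if (nrow(levels) < 2) abort("need at least two paired levels")
  if (any(levels$st_level <= 0) || any(levels$mt_level <= 0)) {
    abort("both-positive filter violated: all levels must be strictly positive")
  }
  lx <- log10(levels$st_level)
  ly <- log10(levels$mt_level)
  degenerate <- sd(lx) == 0 || sd(ly) == 0
  fit <- if (!degenerate) lm(ly ~ lx) else NULL
  structure(
    list(
      slope = if (degenerate) NA_real_ else unname(coef(fit)[2]),
      intercept = if (degenerate) NA_real_ else unname(coef(fit)[1]),
      r = if (degenerate) NA_real_ else cor(lx, ly),
      n = nrow(levels),
      degenerate = degenerate,
      fit = fit,
      data = tibble(log10_st = lx, log10_mt = ly)
    ),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("<loglog_fit> n =", x$n, "\n")
  if (x$degenerate) {
    cat("  degenerate: constant levels, correlation undefined\n")
  } else {
    cat(sprintf("  log10(MT) = %.3f + %.3f log10(ST), Pearson r = %.3f\n",
                x$intercept, x$slope, x$r))
  }
  invisible(x)
}

#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.loglog_fit <- function(x, ...) {
  tibble(r = x$r, n = x$n, degenerate = x$degenerate)
}

check_serial_records <- function(records, method) {
  col <- paste0(method, "_positive")
  need <- c("patient_id", "time_months", col)
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("serial records lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  col
}

#' Sample-level specificity on non-recurrence serial samples
#'
#' One minus the fraction of serial samples from non-recurrence patients
#' called positive by the given method.
#'
#' @param records Tibble of serial samples of non-recurrence patients with
#'   columns `patient_id`, `time_months` and `st_positive` / `mt_positive`.
#' @param method `"st"` or `"mt"`.
#' @return Specificity as a proportion in \[0, 1\].
#' @export
sample_specificity <- function(records, method = c("st", "mt")) {
  method <- match.arg(method)
  col <- check_serial_records(records, method)
  if (nrow(records) == 0) abort("no serial samples")
  1 - sum(records[[col]]) / nrow(records)
}

#' Patient-level specificity on non-recurrence serial samples
#'
#' A patient is a false positive if any of their serial samples is called
#' positive; specificity is the fraction of patients with no positive call.
#'
#' @inheritParams sample_specificity
#' @export
patient_specificity <- function(records, method = c("st", "mt")) {
  method <- match.arg(method)
  col <- check_serial_records(records, method)
  if (nrow(records) == 0) abort("no patients")
  per_patient <- tapply(records[[col]], records$patient_id, any)
  1 - sum(per_patient) / length(per_patient)
}

#' Lead time from first ctDNA detection to radiological recurrence
#'
#' For recurrence patients, the lead time of a method is the recurrence time
#' minus the time of the method's first positive serial sample (months;
#' supply day-scale data divided by 30.44 if needed). Medians are reported
#' per method together with a signed-rank test of the leads against zero,
#' and a paired signed-rank comparison of the two methods' first-detection
#' times over patients detected by both.
#'
#' @param records Tibble of serial samples of recurrence patients with
#'   columns `patient_id`, `time_months`, `st_positive`, `mt_positive`,
#'   `recurrence_time_months`. Patients without any positive sample before
#'   recurrence are excluded from that method's leads.
#'
#' @return A list with `per_patient` (tibble of first-detection times and
#'   leads), `median_lead` (named vector), `p_vs_zero` (named vector) and
#'   `paired_p` (first-detection ST vs MT).
#' @export
lead_times <- function(records) {
  need <- c("patient_id", "time_months", "st_positive", "mt_positive",
            "recurrence_time_months")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("lead-time records lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  first_pos <- function(df, col) {
    pos <- df$time_months[df[[col]] & df$time_months <= df$recurrence_time_months]
    if (length(pos) == 0) NA_real_ else min(pos)
  }
  per_patient <- records |>
    group_by(.data$patient_id) |>
    summarise(
      recurrence_time_months = .data$recurrence_time_months[1],
      st_first = first_pos(dplyr::pick(dplyr::everything()), "st_positive"),
      mt_first = first_pos(dplyr::pick(dplyr::everything()), "mt_positive"),
      .groups = "drop"
    ) |>
    mutate(st_lead = .data$recurrence_time_months - .data$st_first,
           mt_lead = .data$recurrence_time_months - .data$mt_first)

  med <- c(st = median(per_patient$st_lead, na.rm = TRUE),
           mt = median(per_patient$mt_lead, na.rm = TRUE))
  p0 <- c(
    st = lead_p_vs_zero(per_patient$st_lead),
    mt = lead_p_vs_zero(per_patient$mt_lead)
  )
  both <- per_patient |>
    filter(!is.na(.data$st_first) & !is.na(.data$mt_first))
  paired_p <- if (nrow(both) == 0) {
    NA_real_
  } else if (all(both$st_first == both$mt_first)) {
    1
  } else {
    wilcoxon_signed_rank(both$st_first, both$mt_first)$p_value
  }
  list(per_patient = per_patient, median_lead = med, p_vs_zero = p0,
       paired_p = paired_p)
}

lead_p_vs_zero <- function(leads) {
  leads <- leads[!is.na(leads)]
  if (length(leads) == 0) return(NA_real_)
  if (all(leads == 0)) return(1)
  wilcoxon_signed_rank(leads)$p_value
}
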