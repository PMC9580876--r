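# Time-dependent-covariate Cox regression of recurrence-free survival on
# serial ctDNA status.

#' Cox regression with ctDNA as a time-dependent covariate
#'
#' Recurrence-free survival runs from surgery (time 0) to radiological
#' recurrence or end of follow-up. ctDNA status is a time-dependent
#' covariate switching from 0 to 1 at the method's first positive serial
#' sample; follow-up is episode-split into a start-stop (counting-process)
#' representation and fitted by partial likelihood with Efron tie handling.
#'
#' @param records Tibble of serial samples with columns `patient_id`,
#'   `time_months`, `st_positive` / `mt_positive`,
#'   `recurrence_time_months` (NA for non-recurrence patients) and
#'   `followup_months`.
#' @param method `"st"` or `"mt"`.
#'
#' @return An object of class `mrd_cox` wrapping the [survival::coxph()]
#'   fit, with `hazard_ratio`, `ci_95` and `p_value` elements. `tidy()` and
#'   `glance()` methods are provided.
#' @export
cox_time_dependent <- function(records, method = c("st", "mt")) {
  method <- match.arg(method)
  col <- check_serial_records(records, method)
  if (!"followup_months" %in% names(records)) {
    abort("serial records lack `followup_months`")
  }
  episodes <- build_episodes(records, col)
  if (sum(episodes$event) < 1) {
    abort("no recurrence events: hazard ratio inestimable")
  }
  if (length(unique(episodes$ctdna)) < 2) {
    abort("inestimable: ctDNA covariate never varies")
  }
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ ctdna,
    data = episodes, ties = "efron"
  )
  s <- summary(fit)
  structure(
    list(
      method = toupper(method),
      fit = fit,
      hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
      ci_95 = c(lower = unname(s$conf.int[1, "lower .95"]),
                upper = unname(s$conf.int[1, "upper .95"])),
      p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
      n_patients = length(unique(episodes$patient_id)),
      n_events = sum(episodes$event)
    ),
    class = "mrd_cox"
  )
}

# Start-stop episodes: covariate 0 from surgery until the first positive
# serial sample strictly before the end of risk, 1 afterwards.
build_episodes <- function(records, col) {
  per <- records |>
    group_by(.data$patient_id) |>
    summarise(
      recurrence_time_months = .data$recurrence_time_months[1],
      followup_months = .data$followup_months[1],
      first_pos = if (any(.data[[col]]))
        min(.data$time_months[.data[[col]]]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      end = ifelse(is.na(.data$recurrence_time_months),
                   .data$followup_months, .data$recurrence_time_months),
      event = as.integer(!is.na(.data$recurrence_time_months))
    )
  if (any(per$end <= 0)) abort("nonpositive follow-up time")
  rows <- pmap(
    list(per$patient_id, per$first_pos, per$end, per$event),
    function(pid, t1, end, ev) {
      if (!is.na(t1) && t1 > 0 && t1 < end) {
        tibble(patient_id = pid, start = c(0, t1), stop = c(t1, end),
               ctdna = c(0L, 1L), event = c(0L, ev))
      } else if (!is.na(t1) && t1 <= 0) {
        tibble(patient_id = pid, start = 0, stop = end, ctdna = 1L,
               event = ev)
      } else {
        tibble(patient_id = pid, start = 0, stop = end, ctdna = 0L,
               event = ev)
      }
    }
  )
  bind_rows(rows)
}

#' Cox regression on the postoperative-window ctDNA status
#'
#' The companion analysis to [cox_time_dependent()]: a time-fixed covariate
#' equal to the patient's ctDNA call in the early postoperative window
#' (within 60 days of surgery, before adjuvant treatment), with
#' recurrence-free survival measured from surgery.
#'
#' @param calls Per-sample call tibble (e.g. `$calls` of [compare_cohort()])
#'   with `timing_class`, `st_positive` / `mt_positive`,
#'   `recurrence_time_months` and `followup_months`.
#' @param method `"st"` or `"mt"`.
#' @return An `mrd_cox` object (see [cox_time_dependent()]).
#' @export
cox_postoperative <- function(calls, method = c("st", "mt")) {
  method <- match.arg(method)
  col <- paste0(method, "_positive")
  need <- c("patient_id", "timing_class", col, "recurrence_time_months",
            "followup_months")
  missing <- setdiff(need, names(calls))
  if (length(missing)) {
    abort(paste0("call table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  post <- calls[calls$timing_class == "postop_window", , drop = FALSE]
  if (nrow(post) == 0) abort("no postoperative-window samples")
  per <- post |>
    group_by(.data$patient_id) |>
    summarise(
      ctdna = as.integer(any(.data[[col]])),
      end = ifelse(is.na(.data$recurrence_time_months[1]),
                   .data$followup_months[1], .data$recurrence_time_months[1]),
      event = as.integer(!is.na(.data$recurrence_time_months[1])),
      .groups = "drop"
    )
  if (sum(per$event) < 1) abort("no recurrence events: hazard ratio inestimable")
  if (length(unique(per$ctdna)) < 2) {
    abort("inestimable: ctDNA covariate never varies")
  }
  fit <- survival::coxph(survival::Surv(end, event) ~ ctdna, data = per,
                         ties = "efron")
  s <- summary(fit)
  structure(
    list(
      method = toupper(method),
      fit = fit,
      hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
      ci_95 = c(lower = unname(s$conf.int[1, "lower .95"]),
                upper = unname(s$conf.int[1, "upper .95"])),
      p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
      n_patients = nrow(per),
      n_events = sum(per$event)
    ),
    class = "mrd_cox"
  )
}

#' @export
print.mrd_cox <- function(x, ...) {
  cat("<mrd_cox>", x$method, "serial ctDNA, time-dependent covariate\n")
  cat(sprintf("  HR %.1f (95%% CI %.1f-%.1f), p = %.3g; %d patients, %d events\n",
              x$hazard_ratio, x$ci_95[["lower"]], x$ci_95[["upper"]],
              x$p_value, x$n_patients, x$n_events))
  invisible(x)
}

#' @export
tidy.mrd_cox <- function(x, ...) {
  tibble(
    term = paste0(x$method, " ctDNA positive"),
    estimate = log(x$hazard_ratio),
    hazard_ratio = x$hazard_ratio,
    conf_low = x$ci_95[["lower"]],
    conf_high = x$ci_95[["upper"]],
    p_value = x$p_value
  )
}

#' @export
glance.mrd_cox <- function(x, ...) {
  tibble(n_patients = x$n_patients, n_events = x$n_events,
         hazard_ratio = x$hazard_ratio, p_value = x$p_value)
}
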