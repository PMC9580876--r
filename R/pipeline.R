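# End-to-end pipeline: measure every cohort sample with both strategies and
# compute the comparison statistics (concordance, correlation, detection
# rates, specificity, lead time, survival association).

#' Simulate a blank panel for one ddPCR assay
#'
#' Emulates the fractionated tumour-free (buffy coat) DNA panel used to
#' build per-assay noise profiles: blanks at a ladder of DNA inputs, each
#' with a Poisson false-positive count at the assay's per-GE rate.
#'
#' @param assay A [ddpcr_assay()] supplying `fp_rate_per_ge`.
#' @param n_blanks Number of blanks (default 94).
#' @param ge_range Range of genome equivalents screened across the ladder.
#' @param seed Optional integer seed.
#'
#' @return Tibble with `blank_id`, `ge_screened`, `fp_count`, ready for
#'   [noise_profile()].
#' @export
simulate_blank_panel <- function(assay, n_blanks = 94,
                                 ge_range = c(500, 20000), seed = NULL) {
  stopifnot(inherits(assay, "ddpcr_assay"))
  if (n_blanks < 2) abort("need at least two blanks")
  if (!is.null(seed)) set.seed(seed)
  ge <- exp(seq(log(ge_range[1]), log(ge_range[2]), length.out = n_blanks))
  tibble(
    blank_id = sprintf("B%03d", seq_len(n_blanks)),
    ge_screened = ge,
    fp_count = rpois(n_blanks, assay$fp_rate_per_ge * ge)
  )
}

# One simulated analysis step for all samples at once: `ul` microlitres of
# eluate per sample distributed into `wells` wells. Returns pooled counts.
simulate_st_step <- function(samples, assay, cfg, ul, wells = 1) {
  n_s <- nrow(samples)
  n_dr <- matrix(
    pmax(1000L, as.integer(round(rnorm(n_s * wells, cfg$droplet_mean,
                                       cfg$droplet_sd)))),
    nrow = n_s
  )
  n_tot <- rowSums(n_dr)
  mol_mut <- samples$true_ctdna_ge_per_ml * samples$plasma_ml * ul / cfg$eluate_ul
  mol_wt <- samples$cfdna_ge_per_ml * samples$plasma_ml * ul / cfg$eluate_ul
  lam_mut <- mol_mut / n_tot
  lam_wt <- mol_wt / n_tot
  k_mut <- rbinom(n_s, n_tot, -expm1(-lam_mut))
  k_fp <- rbinom(n_s, n_tot - k_mut, -expm1(-assay$fp_rate_per_ge * lam_wt))
  k_wt <- rbinom(n_s, n_tot, -expm1(-lam_wt))
  # keep the wild-type channel informative and unsaturated
  k_wt <- pmin(pmax(k_wt, 1L), n_tot - 1L)
  tibble(n_droplets = n_tot, k_mutant = k_mut + k_fp, k_wildtype = k_wt)
}

merged_from_counts <- function(samples, counts, cfg, eluate_ul_used) {
  tibble(
    sample_id = samples$sample_id,
    assay_id = "ST",
    n_droplets_total = counts$n_droplets,
    k_mutant_total = counts$k_mutant,
    k_wildtype_total = counts$k_wildtype,
    ge_screened = ddpcr_lambda(counts$k_wildtype, counts$n_droplets) *
      counts$n_droplets,
    plasma_ml = samples$plasma_ml,
    fraction_eluate_analyzed = eluate_ul_used / cfg$eluate_ul
  )
}

#' Measure cohort samples with the single-target ddPCR strategy
#'
#' Implements the two-step eluate protocol: a first pass analyses
#' `step1_ul` of the eluate; samples called positive there are not analysed
#' further, while negatives have the remaining `step2_ul` analysed and all
#' reactions merged before the final call. `fraction_eluate_analyzed`
#' reflects the volume actually consumed, so quantification is comparable
#' across the two routes.
#'
#' @param samples Cohort sample tibble from [simulate_cohort()].
#' @param assay A [ddpcr_assay()].
#' @param profile A [noise_profile()] for the assay.
#' @param config An [mrd_config()].
#' @param seed Integer seed.
#'
#' @return Tibble with one row per sample: `sample_id`, `st_positive`,
#'   `st_level_ge_per_ml`, `st_ge_screened`, `st_votes`,
#'   `st_fraction_eluate`.
#' @export
st_measure_cohort <- function(samples, assay, profile, config = mrd_config(),
                              seed = 1) {
  cfg <- config
  if (nrow(samples) == 0) {
    return(tibble(sample_id = character(), st_positive = logical(),
                  st_level_ge_per_ml = numeric(), st_ge_screened = numeric(),
                  st_votes = integer(), st_fraction_eluate = numeric()))
  }
  set.seed(child_seed(seed, 11L))
  step1 <- simulate_st_step(samples, assay, cfg, cfg$step1_ul, wells = 1)
  merged1 <- merged_from_counts(samples, step1, cfg, cfg$step1_ul)
  call1 <- call_st(merged1, profile, cfg$caller_alpha, cfg$lob_quantile)
  pos1 <- call1$positive[match(samples$sample_id, call1$sample_id)]

  neg_idx <- which(!pos1)
  merged_final <- merged1
  if (length(neg_idx) > 0) {
    neg_samples <- samples[neg_idx, , drop = FALSE]
    step2 <- simulate_st_step(neg_samples, assay, cfg, cfg$step2_ul, wells = 2)
    pooled <- tibble(
      n_droplets = step1$n_droplets[neg_idx] + step2$n_droplets,
      k_mutant = step1$k_mutant[neg_idx] + step2$k_mutant,
      k_wildtype = step1$k_wildtype[neg_idx] + step2$k_wildtype
    )
    merged_final[neg_idx, ] <- merged_from_counts(
      neg_samples, pooled, cfg, cfg$step1_ul + cfg$step2_ul
    )
  }
  call_final <- call_st(merged_final, profile, cfg$caller_alpha,
                        cfg$lob_quantile)
  ord <- match(samples$sample_id, call_final$sample_id)
  tibble(
    sample_id = samples$sample_id,
    st_positive = call_final$positive[ord],
    st_level_ge_per_ml = call_final$level_ge_per_ml[ord],
    st_ge_screened = merged_final$ge_screened[match(samples$sample_id,
                                                    merged_final$sample_id)],
    st_votes = call_final$votes_positive[ord],
    st_fraction_eluate = merged_final$fraction_eluate_analyzed[
      match(samples$sample_id, merged_final$sample_id)]
  )
}

#' Measure cohort samples with the multitarget strategy
#'
#' Vectorised equivalent of [simulate_mt_sample()] + [call_mt()] across all
#' cohort samples: extraction, the library input cap, per-target Poisson
#' molecule sampling with background, the per-target confidence test and the
#' two-of-sixteen rule with mean-of-targets quantification.
#'
#' @inheritParams st_measure_cohort
#' @param panel An [mt_panel()].
#' @return Tibble with one row per sample: `sample_id`, `mt_positive`,
#'   `mt_level_ge_per_ml`, `mt_input_ge`, `mt_targets_detected`.
#' @export
mt_measure_cohort <- function(samples, panel, config = mrd_config(),
                              seed = 1) {
  cfg <- config
  stopifnot(inherits(panel, "mt_panel"))
  if (nrow(samples) == 0) {
    return(tibble(sample_id = character(), mt_positive = logical(),
                  mt_level_ge_per_ml = numeric(), mt_input_ge = numeric(),
                  mt_targets_detected = integer()))
  }
  set.seed(child_seed(seed, 21L))
  n_s <- nrow(samples)
  nt <- panel$n_targets
  extracted <- samples$cfdna_ge_per_ml * samples$plasma_ml
  input_ge <- pmin(extracted, cfg$mt_cap_ge)
  input_frac <- ifelse(extracted > 0, input_ge / extracted, 1)
  mu_tumour <- outer(panel$detectability,
                     samples$true_ctdna_ge_per_ml * samples$plasma_ml *
                       input_frac)
  mu_bg <- outer(panel$background_rate_per_ge, input_ge)
  mol <- matrix(rpois(nt * n_s, mu_tumour + mu_bg), nrow = nt)
  detected <- mol >= 1 &
    ppois(mol - 1, mu_bg, lower.tail = FALSE) < cfg$per_target_alpha
  tibble(
    sample_id = samples$sample_id,
    mt_positive = colSums(detected) >= 2,
    mt_level_ge_per_ml = colSums(mol) / (samples$plasma_ml * nt),
    mt_input_ge = input_ge,
    mt_targets_detected = colSums(detected)
  )
}

#' Run the full comparison pipeline on a synthetic cohort
#'
#' Simulates a cohort, measures every sample with both strategies (paired
#' aliquots sharing the same underlying concentrations), and computes the
#' comparison layer: the 2x2 concordance table with Cohen's kappa and raw
#' agreement, the log-log level correlation over both-positive samples, the
#' discordant-sample analysis (levels and preoperative enrichment),
#' timing-stratified detection rates with Wilson intervals, serial
#' sample- and patient-level specificity, lead times, and time-dependent
#' Cox regressions.
#'
#' @param config An [mrd_config()].
#' @param seed Integer seed; all stages derive their seeds from it.
#'
#' @return An object of class `mrd_comparison`; see `glance()` for the
#'   headline numbers and the individual elements (`concordance`,
#'   `correlation`, `discordance`, `detection`, `serial`, `lead_time`,
#'   `cox`) for the full results. The per-sample call table is in `$calls`.
#' @export
compare_cohort <- function(config = mrd_config(), seed = 1) {
  cfg <- config
  validate_mrd_config(cfg)
  cohort <- simulate_cohort(cfg, seed)
  assay <- ddpcr_assay("ST", fp_rate_per_ge = cfg$fp_rate_per_ge)
  panel <- mt_panel(n_targets = cfg$n_targets,
                    background_rate_per_ge = cfg$mt_background_rate_per_ge)
  blanks <- simulate_blank_panel(assay, cfg$n_blanks,
                                 seed = child_seed(seed, 3L))
  profile <- noise_profile(blanks, assay_id = assay$assay_id)
  st <- st_measure_cohort(cohort$samples, assay, profile, cfg,
                          seed = child_seed(seed, 4L))
  mt <- mt_measure_cohort(cohort$samples, panel, cfg,
                          seed = child_seed(seed, 5L))

  calls <- cohort$samples |>
    left_join(st, by = "sample_id") |>
    left_join(mt, by = "sample_id") |>
    left_join(cohort$patients |>
                select("patient_id", "recurrence",
                       "recurrence_time_months", "followup_months", "stage"),
              by = "patient_id")

  tab <- concordance_table(calls)
  concordance <- list(
    table = tab,
    kappa = tryCatch(cohens_kappa(tab), error = function(e) NA_real_),
    agreement = agreement_fraction(tab)
  )

  both_pos <- calls |>
    filter(.data$st_positive & .data$mt_positive,
           .data$st_level_ge_per_ml > 0, .data$mt_level_ge_per_ml > 0)
  correlation <- if (nrow(both_pos) >= 3) {
    tryCatch(
      pearson_loglog(tibble(st_level = both_pos$st_level_ge_per_ml,
                            mt_level = both_pos$mt_level_ge_per_ml)),
      error = function(e) NULL
    )
  } else NULL

  discordance <- discordance_summary(calls)
  detection <- detection_summary(calls)
  serial <- serial_summary(calls)
  lead <- lead_summary(calls)
  cox <- list(
    st = tryCatch(cox_time_dependent(serial$records, "st"),
                  error = function(e) NULL),
    mt = tryCatch(cox_time_dependent(serial$records, "mt"),
                  error = function(e) NULL),
    postop_st = tryCatch(cox_postoperative(calls, "st"),
                         error = function(e) NULL),
    postop_mt = tryCatch(cox_postoperative(calls, "mt"),
                         error = function(e) NULL)
  )

  structure(
    list(config = cfg, seed = seed, patients = cohort$patients,
         calls = calls, concordance = concordance,
         correlation = correlation, discordance = discordance,
         detection = detection, serial = serial, lead_time = lead,
         cox = cox),
    class = "mrd_comparison"
  )
}

discordance_summary <- function(calls) {
  st_only <- calls |> filter(.data$st_positive & !.data$mt_positive)
  mt_only <- calls |> filter(!.data$st_positive & .data$mt_positive)
  level_p <- if (nrow(st_only) > 0 && nrow(mt_only) > 0) {
    wilcoxon_rank_sum(st_only$st_level_ge_per_ml,
                      mt_only$mt_level_ge_per_ml)$p_value
  } else NA_real_
  preop_tab <- matrix(
    c(sum(st_only$timing_class == "preop"),
      sum(st_only$timing_class != "preop"),
      sum(mt_only$timing_class == "preop"),
      sum(mt_only$timing_class != "preop")),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("st_only", "mt_only"), c("preop", "postop"))
  )
  list(
    n_st_only = nrow(st_only),
    n_mt_only = nrow(mt_only),
    median_level_st_only = median(st_only$st_level_ge_per_ml),
    median_level_mt_only = median(mt_only$mt_level_ge_per_ml),
    level_p = level_p,
    preop_table = preop_tab,
    preop_fisher_p = fisher_exact(preop_tab)$p_value
  )
}

rate_row <- function(timing, method, k, n) {
  ci <- if (n > 0) wilson_interval(k, n) else c(lower = NA_real_,
                                                upper = NA_real_)
  tibble(timing = timing, method = method, k = k, n = n,
         rate = if (n > 0) k / n else NA_real_,
         ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
}

detection_summary <- function(calls) {
  pre <- calls |> filter(.data$timing_class == "preop")
  post <- calls |> filter(.data$timing_class == "postop_window")
  post_rec <- post |> filter(.data$recurrence)
  post_non <- post |> filter(!.data$recurrence)
  bind_rows(
    rate_row("preop", "ST", sum(pre$st_positive), nrow(pre)),
    rate_row("preop", "MT", sum(pre$mt_positive), nrow(pre)),
    rate_row("postop_recurrence", "ST", sum(post_rec$st_positive),
             nrow(post_rec)),
    rate_row("postop_recurrence", "MT", sum(post_rec$mt_positive),
             nrow(post_rec)),
    rate_row("postop_nonrecurrence", "ST", sum(post_non$st_positive),
             nrow(post_non)),
    rate_row("postop_nonrecurrence", "MT", sum(post_non$mt_positive),
             nrow(post_non))
  )
}

serial_summary <- function(calls) {
  records <- calls |>
    filter(.data$timing_class == "surveillance") |>
    select("patient_id", "time_months", "st_positive", "mt_positive",
           "recurrence", "recurrence_time_months", "followup_months")
  nonrec <- records |> filter(!.data$recurrence)
  spec <- if (nrow(nonrec) > 0) {
    list(
      st_sample = sample_specificity(nonrec, "st"),
      mt_sample = sample_specificity(nonrec, "mt"),
      st_patient = patient_specificity(nonrec, "st"),
      mt_patient = patient_specificity(nonrec, "mt"),
      n_samples = nrow(nonrec),
      n_patients = length(unique(nonrec$patient_id))
    )
  } else NULL
  list(records = records, specificity = spec)
}

lead_summary <- function(calls) {
  rec <- calls |>
    filter(.data$timing_class == "surveillance", .data$recurrence)
  if (nrow(rec) == 0) {
    return(list(note = "no eligible patients"))
  }
  lead_times(rec |>
               select("patient_id", "time_months", "st_positive",
                      "mt_positive", "recurrence_time_months"))
}

#' @export
print.mrd_comparison <- function(x, ...) {
  cat("<mrd_comparison>", nrow(x$calls), "samples from",
      nrow(x$patients), "patients (seed", paste0(x$seed, ")"), "\n")
  cat(sprintf("  concordance: %.1f%% agreement, Cohen's kappa %.2f\n",
              100 * x$concordance$agreement, x$concordance$kappa))
  if (!is.null(x$correlation)) {
    cat(sprintf("  level correlation (both positive, n=%d): Pearson r = %.3f\n",
                x$correlation$n, x$correlation$r))
  }
  print(glance(x))
  invisible(x)
}

#' @export
glance.mrd_comparison <- function(x, ...) {
  det <- function(timing, method) {
    r <- x$detection[x$detection$timing == timing &
                       x$detection$method == method, ]
    if (nrow(r) == 0) NA_real_ else r$rate
  }
  sp <- x$serial$specificity
  lead <- x$lead_time
  tibble(
    n_samples = nrow(x$calls),
    n_patients = nrow(x$patients),
    kappa = x$concordance$kappa,
    agreement = x$concordance$agreement,
    r_loglog = if (is.null(x$correlation)) NA_real_ else x$correlation$r,
    preop_sens_st = det("preop", "ST"),
    preop_sens_mt = det("preop", "MT"),
    postop_sens_st = det("postop_recurrence", "ST"),
    postop_sens_mt = det("postop_recurrence", "MT"),
    spec_sample_st = if (is.null(sp)) NA_real_ else sp$st_sample,
    spec_sample_mt = if (is.null(sp)) NA_real_ else sp$mt_sample,
    median_lead_st = if (is.null(lead$median_lead)) NA_real_ else
      lead$median_lead[["st"]],
    median_lead_mt = if (is.null(lead$median_lead)) NA_real_ else
      lead$median_lead[["mt"]],
    cox_hr_st = if (is.null(x$cox$st)) NA_real_ else x$cox$st$hazard_ratio,
    cox_hr_mt = if (is.null(x$cox$mt)) NA_real_ else x$cox$mt$hazard_ratio,
    cox_hr_postop_st = if (is.null(x$cox$postop_st)) NA_real_ else
      x$cox$postop_st$hazard_ratio,
    cox_hr_postop_mt = if (is.null(x$cox$postop_mt)) NA_real_ else
      x$cox$postop_mt$hazard_ratio
  )
}
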