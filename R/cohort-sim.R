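# Synthetic patient cohort: stage II-III resected colorectal cancer patients
# with preoperative, early-postoperative and surveillance blood draws, and a
# shared-concentration pair of plasma aliquots per draw (one for the ST ddPCR
# measurement, one for the MT sequencing measurement).

#' Simulate a synthetic study cohort
#'
#' Generates patients (stage, adjuvant treatment, recurrence status and time,
#' follow-up, ctDNA kinetics parameters) and their timed blood draws. Each
#' draw carries a single cell-free DNA concentration and a single true ctDNA
#' concentration shared by the paired ST and MT aliquots.
#'
#' Postoperative ctDNA kinetics: recurrence patients carry a residual level
#' at surgery, drawn from a mixture of a "shedding" component (detectable
#' immediately after surgery) and a "not-yet-shedding" component (far below
#' the detection floor, becoming detectable during surveillance through
#' exponential regrowth). A small fraction of non-recurrence patients shed
#' postoperatively and are cleared at the start of adjuvant treatment.
#'
#' @param config An [mrd_config()] list.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#'
#' @return A list with tibbles `patients` and `samples`.
#'   `patients`: `patient_id`, `stage`, `adjuvant`, `recurrence`,
#'   `recurrence_time_months`, `followup_months`, `preop_ctdna_ge_per_ml`,
#'   `postop_residual_ge_per_ml`, `cleared_by_adjuvant`,
#'   `doubling_time_months`, `cfdna_baseline_ge_per_ml`, sampling flags.
#'   `samples`: `sample_id`, `patient_id`, `time_months`, `timing_class`
#'   (`preop`, `postop_window`, `surveillance`), `cfdna_ge_per_ml`,
#'   `true_ctdna_ge_per_ml`, `plasma_ml`.
#' @export
simulate_cohort <- function(config = mrd_config(), seed = 1) {
  cfg <- config
  validate_mrd_config(cfg)
  set.seed(child_seed(seed, 1L))
  n <- cfg$n_patients

  recurrence <- runif(n) < cfg$recurrence_frac
  adjuvant <- runif(n) < cfg$adjuvant_frac
  shedding <- ifelse(
    recurrence,
    runif(n) < cfg$residual_shedding_frac,
    adjuvant & runif(n) < cfg$nonrec_shedding_frac
  )
  residual <- numeric(n)
  residual[recurrence & shedding] <- rlnorm(sum(recurrence & shedding),
                                            log(cfg$residual_high_median),
                                            cfg$residual_high_sdlog)
  residual[recurrence & !shedding] <- rlnorm(sum(recurrence & !shedding),
                                             log(cfg$residual_low_median),
                                             cfg$residual_low_sdlog)
  residual[!recurrence & shedding] <- rlnorm(sum(!recurrence & shedding),
                                             log(cfg$residual_high_median),
                                             cfg$residual_high_sdlog)

  recurrence_time <- rep(NA_real_, n)
  recurrence_time[recurrence] <- rlnorm(sum(recurrence),
                                        log(cfg$recurrence_time_median),
                                        cfg$recurrence_time_sdlog)
  followup <- pmax(12, rnorm(n, cfg$followup_median, cfg$followup_sd))

  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    stage = ifelse(runif(n) < cfg$stage2_frac, "II", "III"),
    adjuvant = adjuvant,
    recurrence = recurrence,
    recurrence_time_months = recurrence_time,
    followup_months = followup,
    preop_ctdna_ge_per_ml = rlnorm(n, log(cfg$preop_level_median),
                                   cfg$preop_level_sdlog),
    postop_residual_ge_per_ml = residual,
    cleared_by_adjuvant = !recurrence & shedding,
    doubling_time_months = rlnorm(n, log(cfg$doubling_time_median),
                                  cfg$doubling_time_sdlog),
    cfdna_baseline_ge_per_ml = rlnorm(n, log(cfg$cfdna_median),
                                      cfg$cfdna_sdlog),
    preop_sampled = runif(n) < cfg$preop_sampled_frac,
    postop_sampled = runif(n) < cfg$postop_sampled_frac,
    serial_monitored = runif(n) < cfg$serial_monitored_frac
  )

  set.seed(child_seed(seed, 2L))
  samples <- draw_schedule(patients, cfg)
  samples <- realise_draws(samples, patients, cfg)
  list(patients = patients, samples = samples)
}

# Sampling timetable for every patient: one preoperative draw, one early
# postoperative draw (inside the 60-day window, before adjuvant start), and
# surveillance draws at fixed intervals after end of definitive treatment.
draw_schedule <- function(patients, cfg) {
  rows <- pmap(
    list(patients$patient_id, patients$preop_sampled,
         patients$postop_sampled, patients$serial_monitored,
         patients$adjuvant, patients$recurrence_time_months,
         patients$followup_months),
    function(pid, pre, post, serial, adj, rec_t, fu) {
      times <- numeric(0)
      classes <- character(0)
      if (pre) {
        times <- c(times, cfg$preop_draw_month)
        classes <- c(classes, "preop")
      }
      if (post) {
        times <- c(times, cfg$postop_draw_month)
        classes <- c(classes, "postop_window")
      }
      if (serial) {
        def_end <- if (adj) cfg$adjuvant_start_month +
          cfg$adjuvant_duration_months else cfg$adjuvant_start_month
        horizon <- min(fu, rec_t, na.rm = TRUE)
        start <- def_end + cfg$serial_start_gap_months
        if (start <= horizon) {
          st <- seq(start, horizon, by = cfg$serial_interval_months)
          times <- c(times, st)
          classes <- c(classes, rep("surveillance", length(st)))
        }
      }
      tibble(patient_id = pid, time_months = times, timing_class = classes)
    }
  )
  bind_rows(rows)
}

realise_draws <- function(schedule, patients, cfg) {
  if (nrow(schedule) == 0) {
    return(tibble(sample_id = character(), patient_id = character(),
                  time_months = numeric(), timing_class = character(),
                  cfdna_ge_per_ml = numeric(),
                  true_ctdna_ge_per_ml = numeric(), plasma_ml = numeric()))
  }
  idx <- match(schedule$patient_id, patients$patient_id)
  base_level <- trajectory_level(patients[idx, ], schedule$time_months, cfg)
  m <- nrow(schedule)
  noise <- rlnorm(m, 0, cfg$biological_noise_sdlog)
  cf_mult <- ifelse(schedule$time_months < 0, cfg$preop_cfdna_multiplier, 1)
  schedule |>
    mutate(
      sample_id = sprintf("%s_S%02d", .data$patient_id,
                          as.integer(stats::ave(seq_len(m), .data$patient_id,
                                                FUN = seq_along))),
      cfdna_ge_per_ml = patients$cfdna_baseline_ge_per_ml[idx] * cf_mult *
        rlnorm(m, 0, cfg$cfdna_noise_sdlog),
      true_ctdna_ge_per_ml = base_level * noise,
      plasma_ml = cfg$plasma_ml
    ) |>
    select("sample_id", "patient_id", "time_months", "timing_class",
           "cfdna_ge_per_ml", "true_ctdna_ge_per_ml", "plasma_ml")
}

# Vectorised noiseless trajectory for rows of the patients tibble.
trajectory_level <- function(p, t, cfg) {
  preop <- t < 0
  lvl <- numeric(length(t))
  lvl[preop] <- p$preop_ctdna_ge_per_ml[preop]
  post <- !preop
  grow <- post & p$recurrence
  lvl[grow] <- p$postop_residual_ge_per_ml[grow] *
    2^(t[grow] / p$doubling_time_months[grow])
  flat <- post & !p$recurrence & p$postop_residual_ge_per_ml > 0
  cleared <- flat & p$cleared_by_adjuvant & (t >= cfg$adjuvant_start_month)
  lvl[flat & !cleared] <- p$postop_residual_ge_per_ml[flat & !cleared]
  lvl
}

#' Noise-free ctDNA trajectory of one patient
#'
#' Before surgery the level is the patient's preoperative level. After
#' surgery, recurrence patients grow exponentially from their residual level
#' with the patient's doubling time (`residual * 2^(t / doubling_time)`);
#' cured patients are at zero; non-recurrence patients who shed
#' postoperatively hold their residual level until the start of adjuvant
#' treatment, which clears them.
#'
#' @param patient A one-row slice of the `patients` tibble from
#'   [simulate_cohort()].
#' @param t_months Time(s) in months relative to surgery (negative =
#'   preoperative).
#' @param config An [mrd_config()] (supplies the adjuvant start month).
#'
#' @return ctDNA level(s) in GE per mL plasma.
#' @export
tumor_trajectory <- function(patient, t_months, config = mrd_config()) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1)
  p <- patient[rep(1, length(t_months)), ]
  trajectory_level(p, t_months, config)
}

#' Realise a single timed blood draw
#'
#' Applies lognormal biological noise to the patient's trajectory and cfDNA
#' baseline and returns one sample row; the paired ST and MT aliquots of a
#' draw share this row's concentrations by construction.
#'
#' @inheritParams tumor_trajectory
#' @param seed Optional integer seed.
#' @return A one-row sample tibble (see [simulate_cohort()]).
#' @export
draw_sample <- function(patient, t_months, config = mrd_config(), seed = NULL) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1, length(t_months) == 1)
  if (!is.null(seed)) set.seed(seed)
  timing <- if (t_months < 0) "preop" else if
    (t_months <= config$adjuvant_start_month) "postop_window" else "surveillance"
  schedule <- tibble(patient_id = patient$patient_id, time_months = t_months,
                     timing_class = timing)
  realise_draws(schedule, patient, config)
}
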