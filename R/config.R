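# Run configuration: every protocol constant and cohort parameter in one
# validated list, loadable from YAML/JSON.

mrd_config_defaults <- function() {
  list(
    # -- wet-lab constants ---------------------------------------------------
    plasma_ml = 8,            # plasma volume per aliquot (mL)
    eluate_ul = 60,           # cfDNA eluate volume (uL)
    analysis_ul = 54,         # eluate volume intended for ctDNA analysis (uL)
    step1_ul = 18,            # first-pass eluate volume (uL)
    step2_ul = 36,            # remainder analysed when step 1 is negative (uL)
    reaction_volume_ul = 20,  # reaction volume converted to droplets (uL)
    droplet_volume_nl = 0.834,
    droplet_mean = 16948,     # droplets per well (instrument mean)
    droplet_sd = 1852,
    min_droplets = 8000,      # QC floor
    pg_per_ge = 3.3,          # pg DNA per haploid genome equivalent
    mt_cap_ge = 20000,        # MT library input cap (~66 ng)
    n_targets = 16,
    n_blanks = 94,            # blank panel size per assay
    # -- calling -------------------------------------------------------------
    caller_alpha = 0.05,
    lob_quantile = 0.95,
    per_target_alpha = 1e-3,
    fp_rate_per_ge = 1e-6,        # ddPCR assay false-positive rate (truth)
    mt_background_rate_per_ge = 2e-8,
    # -- cohort --------------------------------------------------------------
    n_patients = 112,
    stage2_frac = 0.232,
    recurrence_frac = 0.24,
    adjuvant_frac = 0.705,
    recurrence_time_median = 12.2,  # months
    recurrence_time_sdlog = 0.24,
    followup_median = 35.8,         # months, non-recurrence patients
    followup_sd = 0.5,
    preop_level_median = 0.7,       # GE/mL, lognormal
    preop_level_sdlog = 2,
    residual_shedding_frac = 0.5,   # recurrence patients shedding at surgery
    residual_high_median = 1,       # GE/mL
    residual_high_sdlog = 1,
    residual_low_median = 0.003,    # GE/mL, not-yet-shedding component
    residual_low_sdlog = 1,
    nonrec_shedding_frac = 0.06,    # non-recurrence postoperative shedders
    doubling_time_median = 1.5,     # months
    doubling_time_sdlog = 0.3,
    cfdna_median = 1625,            # GE/mL (~13,000 GE per 8 mL)
    cfdna_sdlog = 0.5,
    preop_cfdna_multiplier = 1.5,
    biological_noise_sdlog = 0.3,   # draw-to-draw ctDNA variability
    cfdna_noise_sdlog = 0.2,
    # -- sampling schedule (months; surgery at 0) ----------------------------
    preop_draw_month = -0.25,
    postop_draw_month = 1,
    adjuvant_start_month = 2,
    adjuvant_duration_months = 6,
    serial_interval_months = 3,
    serial_start_gap_months = 1,    # gap after end of definitive treatment
    preop_sampled_frac = 0.82,
    postop_sampled_frac = 0.5,
    serial_monitored_frac = 0.58
  )
}

#' Build a validated run configuration
#'
#' Returns the full set of protocol constants and cohort parameters with
#' their defaults, overridden by any named arguments. Unknown names are
#' rejected, as are values outside their admissible ranges.
#'
#' @param ... Named overrides of the default fields (see
#'   `mrd_config_defaults` in the package source for the full list; the
#'   returned list names them all).
#'
#' @return A named list of class `mrd_config`.
#' @examples
#' cfg <- mrd_config(n_patients = 20)
#' cfg$mt_cap_ge
#' @export
mrd_config <- function(...) {
  defaults <- mrd_config_defaults()
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(names(overrides) == ""))) {
    abort("all configuration overrides must be named")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  validate_mrd_config(cfg)
  structure(cfg, class = c("mrd_config", "list"))
}

validate_mrd_config <- function(cfg) {
  pos <- c("plasma_ml", "eluate_ul", "reaction_volume_ul", "droplet_volume_nl",
           "droplet_mean", "pg_per_ge", "mt_cap_ge", "n_targets", "n_patients",
           "recurrence_time_median", "followup_median", "cfdna_median",
           "doubling_time_median", "serial_interval_months")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(sprintf("configuration field '%s' must be a positive number", f))
    }
  }
  fracs <- c("stage2_frac", "recurrence_frac", "adjuvant_frac",
             "residual_shedding_frac", "nonrec_shedding_frac",
             "preop_sampled_frac", "postop_sampled_frac",
             "serial_monitored_frac", "caller_alpha", "per_target_alpha",
             "lob_quantile")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("configuration field '%s' must lie in [0, 1]", f))
    }
  }
  if (cfg$step1_ul + cfg$step2_ul > cfg$eluate_ul) {
    abort("step volumes exceed the eluate volume")
  }
  if (cfg$fp_rate_per_ge < 0 || cfg$mt_background_rate_per_ge < 0) {
    abort("noise rates must be nonnegative")
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML (or JSON) file
#'
#' The file may specify any subset of the configuration fields; the rest
#' take their defaults. Unknown keys are rejected with an error naming them.
#'
#' @param path Path to a YAML file of named fields.
#' @return A validated `mrd_config` list.
#' @export
read_mrd_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("config file must hold a mapping of fields")
  do.call(mrd_config, raw)
}

# Deterministic child seeds below 2^31, fanned out from one run seed.
child_seed <- function(seed, stage) {
  (seed * 1009L + stage * 9973L) %% 2147483647L
}
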