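# 16-target mPCR-NGS measurement model: per-target molecule sampling under
# the library input cap, per-target confidence detection, the >= 2-of-16
# positivity rule, and mean-of-targets quantification.

#' Describe a multitarget panel
#'
#' @param patient_id Optional patient the panel was designed for.
#' @param n_targets Number of tumour variants tracked (default 16).
#' @param background_rate_per_ge Nonnegative expected false mutant molecules
#'   per genome equivalent of input, per target.
#' @param detectability Per-target fraction of tumour molecules recoverable,
#'   in (0, 1]. Scalar or length `n_targets`.
#'
#' @return An object of class `mt_panel`.
#' @export
mt_panel <- function(patient_id = NA_character_, n_targets = 16,
                     background_rate_per_ge = 2e-8, detectability = 1) {
  if (n_targets < 1) abort("`n_targets` must be >= 1")
  if (any(background_rate_per_ge < 0)) abort("background rate must be >= 0")
  if (any(detectability <= 0) || any(detectability > 1)) {
    abort("`detectability` must lie in (0, 1]")
  }
  structure(
    list(patient_id = patient_id,
         n_targets = as.integer(n_targets),
         background_rate_per_ge = rep_len(background_rate_per_ge, n_targets),
         detectability = rep_len(detectability, n_targets)),
    class = "mt_panel"
  )
}

#' Simulate one multitarget measurement
#'
#' Extracted cell-free DNA is `cfdna_ge_per_ml * plasma_ml` genome
#' equivalents; library input is capped at `cap_ge` (the ~66 ng protocol
#' maximum, ~20,000 GE at 3.3 pg per haploid GE). Per-target tumour molecule
#' counts are Poisson with mean
#' `ctdna_ge_per_ml * plasma_ml * (input/extracted) * detectability`, plus
#' Poisson background at the panel's per-GE background rate times the input.
#'
#' @param panel An [mt_panel()].
#' @param ctdna_ge_per_ml,cfdna_ge_per_ml True mutant and total cfDNA
#'   concentrations (GE per mL plasma).
#' @param plasma_ml Plasma volume (default 8 mL).
#' @param cap_ge Library input cap in genome equivalents (default 20000).
#' @param sample_id Identifier carried into the result.
#' @param per_target_alpha Significance level of the per-target Poisson
#'   detection test (default 1e-3).
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per target: `sample_id`, `target_index`,
#'   `mutant_molecules`, `background_mean`, `detected`, `input_ge`,
#'   `plasma_ml`.
#' @export
simulate_mt_sample <- function(panel, ctdna_ge_per_ml, cfdna_ge_per_ml,
                               plasma_ml = 8, cap_ge = 20000,
                               sample_id = NA_character_,
                               per_target_alpha = 1e-3, seed = NULL) {
  stopifnot(inherits(panel, "mt_panel"))
  if (plasma_ml <= 0) abort("`plasma_ml` must be positive")
  if (ctdna_ge_per_ml < 0 || cfdna_ge_per_ml < 0) {
    abort("concentrations must be nonnegative")
  }
  if (!is.null(seed)) set.seed(seed)
  extracted <- cfdna_ge_per_ml * plasma_ml
  input_ge <- min(extracted, cap_ge)
  input_frac <- if (extracted > 0) input_ge / extracted else 1
  mu_tumour <- ctdna_ge_per_ml * plasma_ml * input_frac * panel$detectability
  mu_bg <- panel$background_rate_per_ge * input_ge
  molecules <- rpois(panel$n_targets, mu_tumour) + rpois(panel$n_targets, mu_bg)
  tibble(
    sample_id = sample_id,
    target_index = seq_len(panel$n_targets),
    mutant_molecules = as.integer(molecules),
    background_mean = mu_bg,
    detected = detect_targets(molecules, mu_bg, per_target_alpha),
    input_ge = input_ge,
    plasma_ml = plasma_ml
  )
}

#' Per-target confidence detection
#'
#' A target is detected when the Poisson upper tail probability of its
#' molecule count under the background mean falls below `alpha`. With zero
#' background a single molecule is sufficient; zero molecules are never
#' detected.
#'
#' @param molecules Nonnegative integer molecule counts (vectorised).
#' @param background_mean Expected background molecules per target.
#' @param alpha Per-target significance level (default 1e-3).
#' @return Logical vector of detections.
#' @export
detect_targets <- function(molecules, background_mean, alpha = 1e-3) {
  if (any(molecules < 0) || any(background_mean < 0)) {
    abort("`molecules` and `background_mean` must be nonnegative")
  }
  p <- ppois(molecules - 1, background_mean, lower.tail = FALSE)
  molecules >= 1 & p < alpha
}

check_mt_result <- function(result, n_targets = 16) {
  need <- c("sample_id", "target_index", "mutant_molecules", "detected",
            "plasma_ml")
  missing <- setdiff(need, names(result))
  if (length(missing)) {
    abort(paste0("MT result lacks column(s): ", paste(missing, collapse = ", ")))
  }
  sizes <- table(result$sample_id)
  if (any(sizes != n_targets)) {
    abort(sprintf("each sample must carry exactly %d targets", n_targets))
  }
  invisible(result)
}

#' Multitarget sample call: positive when >= 2 targets are detected
#'
#' @param result Per-target tibble from [simulate_mt_sample()] (one or many
#'   samples row-bound).
#' @param min_targets Detection threshold on the number of positive targets
#'   (default 2).
#' @param n_targets Expected panel size (default 16).
#'
#' @return Tibble with one row per sample: `sample_id`, `method` ("MT"),
#'   `positive`, `level_ge_per_ml` (from [mt_level()]), `n_targets_detected`.
#' @export
call_mt <- function(result, min_targets = 2, n_targets = 16) {
  check_mt_result(result, n_targets)
  result |>
    group_by(.data$sample_id) |>
    summarise(
      n_targets_detected = sum(.data$detected),
      level_ge_per_ml = sum(.data$mutant_molecules / .data$plasma_ml) /
        dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(method = "MT", positive = .data$n_targets_detected >= min_targets) |>
    select("sample_id", "method", "positive", "level_ge_per_ml",
           "n_targets_detected")
}

#' Mean-of-targets ctDNA level
#'
#' The multitarget level is the mean over all panel targets of molecules per
#' mL plasma, explicitly including targets with zero molecules; with all
#' targets at the same count it equals the single-target value.
#'
#' @inheritParams call_mt
#' @return Named numeric vector of GE/mL per sample.
#' @export
mt_level <- function(result, n_targets = 16) {
  check_mt_result(result, n_targets)
  if (any(result$plasma_ml <= 0)) abort("`plasma_ml` must be positive")
  agg <- result |>
    group_by(.data$sample_id) |>
    summarise(level = sum(.data$mutant_molecules / .data$plasma_ml) / dplyr::n(),
              .groups = "drop")
  setNames(agg$level, agg$sample_id)
}
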