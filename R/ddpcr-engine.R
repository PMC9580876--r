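# Partition-level ddPCR model: droplet classification, Poisson concentration
# math, reaction QC, merging, and a seeded reaction simulator.

#' Describe a ddPCR assay
#'
#' Bundles the per-assay constants used for simulation and threshold setting:
#' the positive-droplet threshold rule (a number of standard deviations below
#' the positive-control positive-cluster mean), the amplitude cluster
#' parameters of the three droplet populations on the mutant channel (empty,
#' wild-type-positive, mutant-positive), and the assay's intrinsic
#' false-positive rate (false mutant-positive events per wild-type genome
#' equivalent screened) used as simulator ground truth.
#'
#' @param assay_id Assay identifier.
#' @param target_label Human-readable target (e.g. a mutation name).
#' @param threshold_sd_k Positive number of SDs below the positive-cluster
#'   mean at which the amplitude threshold is placed.
#' @param amplitude_empty,amplitude_wildtype,amplitude_mutant Named numeric
#'   vectors `c(mean =, sd =)` for the three amplitude clusters, in arbitrary
#'   fluorescence units. Cluster means must be ordered
#'   empty < wild-type < mutant and SDs must be positive.
#' @param fp_rate_per_ge Nonnegative false-positive mutant events per
#'   wild-type genome equivalent screened.
#'
#' @return An object of class `ddpcr_assay`.
#' @examples
#' ddpcr_assay("KRAS_G12V")
#' @export
ddpcr_assay <- function(assay_id,
                        target_label = assay_id,
                        threshold_sd_k = 3,
                        amplitude_empty = c(mean = 1000, sd = 200),
                        amplitude_wildtype = c(mean = 2000, sd = 250),
                        amplitude_mutant = c(mean = 10000, sd = 500),
                        fp_rate_per_ge = 1e-6) {
  stopifnot(is.character(assay_id), length(assay_id) == 1)
  if (!is.numeric(threshold_sd_k) || length(threshold_sd_k) != 1 ||
      threshold_sd_k < 0) {
    abort("`threshold_sd_k` must be a single nonnegative number.")
  }
  clusters <- list(empty = amplitude_empty, wildtype = amplitude_wildtype,
                   mutant = amplitude_mutant)
  for (nm in names(clusters)) {
    cl <- clusters[[nm]]
    if (!all(c("mean", "sd") %in% names(cl)) || cl[["sd"]] <= 0) {
      abort(sprintf("amplitude cluster '%s' needs mean and positive sd", nm))
    }
  }
  if (!(amplitude_empty[["mean"]] < amplitude_wildtype[["mean"]] &&
        amplitude_wildtype[["mean"]] < amplitude_mutant[["mean"]])) {
    abort("amplitude cluster means must be ordered empty < wildtype < mutant")
  }
  if (fp_rate_per_ge < 0) abort("`fp_rate_per_ge` must be >= 0")
  structure(
    list(assay_id = assay_id, target_label = target_label,
         threshold_sd_k = threshold_sd_k,
         amplitude_empty = amplitude_empty,
         amplitude_wildtype = amplitude_wildtype,
         amplitude_mutant = amplitude_mutant,
         fp_rate_per_ge = fp_rate_per_ge),
    class = "ddpcr_assay"
  )
}

#' @export
print.ddpcr_assay <- function(x, ...) {
  cat("<ddpcr_assay>", x$assay_id, "targeting", x$target_label, "\n")
  cat("  threshold: mean(pos cluster) -", x$threshold_sd_k, "SD\n")
  cat("  fp rate:", format(x$fp_rate_per_ge, digits = 3), "per GE screened\n")
  invisible(x)
}

#' Set the positive-droplet amplitude threshold from a positive control
#'
#' The threshold is placed a predetermined assay-specific number of standard
#' deviations below the mean amplitude of the positive droplets in the
#' positive-control well. The positive cluster is identified from the
#' control's own amplitude structure (2-means clustering; the high-amplitude
#' cluster is the positive one).
#'
#' @param positive_control Either a numeric vector of droplet amplitudes or a
#'   one-row reaction tibble (as returned by [simulate_ddpcr_reaction()] with
#'   `with_amplitudes = TRUE`) whose `amplitudes` list-column holds them.
#' @param k_sd Number of standard deviations below the positive-cluster mean.
#'
#' @return The amplitude threshold (a single number). Droplets at or above it
#'   are classified positive by [classify_droplets()].
#' @export
amplitude_threshold <- function(positive_control, k_sd = 3) {
  amps <- extract_amplitudes(positive_control)
  if (length(amps) < 2 || diff(range(amps)) == 0) {
    abort("uninformative positive control: no distinct positive droplet cluster")
  }
  if (!is.numeric(k_sd) || length(k_sd) != 1 || k_sd < 0) {
    abort("`k_sd` must be a single nonnegative number")
  }
  km <- stats::kmeans(amps, centers = range(amps))
  hi <- which.max(km$centers)
  pos <- amps[km$cluster == hi]
  lo_amps <- amps[km$cluster != hi]
  # Require genuine separation between the clusters, otherwise the control
  # carries no positive population to anchor the threshold.
  spread <- sd(pos)
  if (length(pos) < 1 || length(lo_amps) < 1 ||
      (km$centers[hi] - min(km$centers)) < 4 * max(sd(lo_amps), 1e-8)) {
    abort("uninformative positive control: no distinct positive droplet cluster")
  }
  if (is.na(spread)) spread <- 0
  mean(pos) - k_sd * spread
}

extract_amplitudes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x) && "amplitudes" %in% names(x)) {
    if (nrow(x) != 1) abort("expected a single reaction row")
    amps <- x$amplitudes[[1]]
    if (is.null(amps)) abort("reaction carries no amplitudes")
    return(as.numeric(amps))
  }
  abort("supply a numeric amplitude vector or a reaction row with amplitudes")
}

#' Classify droplets against an amplitude threshold
#'
#' @param amplitudes Numeric vector of per-droplet fluorescence values.
#' @param threshold Finite amplitude threshold; droplets with amplitude at or
#'   above it are counted positive.
#'
#' @return Named integer vector `c(k_above, k_below)` summing to the droplet
#'   count. An empty amplitude vector yields `c(0, 0)`.
#' @export
classify_droplets <- function(amplitudes, threshold) {
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  if (length(amplitudes) == 0) {
    return(c(k_above = 0L, k_below = 0L))
  }
  k <- sum(amplitudes >= threshold)
  c(k_above = as.integer(k), k_below = as.integer(length(amplitudes) - k))
}

#' Poisson mean copies per droplet from positive-droplet counts
#'
#' Standard ddPCR partition statistics: with `k` of `n` droplets positive,
#' the mean number of target copies per droplet is
#' \eqn{\lambda = -\ln(1 - k/n)}.
#'
#' @param k Number of positive droplets (vectorised).
#' @param n Total droplets analysed.
#'
#' @return Mean copies per droplet, \eqn{\lambda}. Zero iff `k` is zero.
#'   Saturated wells (`k == n`) are rejected rather than mapped to an
#'   infinite estimate.
#' @examples
#' ddpcr_lambda(3000, 16948)
#' @export
ddpcr_lambda <- function(k, n) {
  if (any(n <= 0)) abort("`n` must be positive")
  if (any(k < 0) || any(k > n)) abort("`k` must satisfy 0 <= k <= n")
  if (any(k == n)) abort("saturated well: all droplets positive, lambda unbounded")
  -log1p(-k / n)
}

#' Concentration from the per-droplet Poisson mean
#'
#' @param lambda Mean copies per droplet (nonnegative).
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.834 nL).
#'
#' @return Concentration in copies per microlitre:
#'   `lambda / droplet_volume_nl * 1000`.
#' @examples
#' ddpcr_concentration(0.19485) # ~ 233.6 copies/uL
#' @export
ddpcr_concentration <- function(lambda, droplet_volume_nl = 0.834) {
  if (any(lambda < 0)) abort("`lambda` must be >= 0")
  if (droplet_volume_nl <= 0) abort("`droplet_volume_nl` must be positive")
  lambda / droplet_volume_nl * 1000
}

#' Quality control for ddPCR reactions
#'
#' Applies the four reaction-level QC rules: no mutant signal in the
#' no-template control, signal in the positive control, droplet amplitudes
#' within the expected interval (when amplitudes and bounds are available),
#' and a minimum droplet count in the well. A reaction passes only if every
#' rule passes.
#'
#' @param reactions Tibble of reactions (one row per well) containing at
#'   least `assay_id`, `role`, `n_droplets`, `k_mutant`. Control wells are
#'   identified by `role %in% c("NTC", "positive_control")` and are matched
#'   to sample wells of the same `assay_id`.
#' @param min_droplets Minimum droplets per well (default 8000).
#' @param amplitude_bounds Optional length-2 numeric interval; when a well
#'   carries an `amplitudes` list-column its droplets must all fall inside.
#'
#' @return The sample rows of `reactions` with logical flag columns
#'   `qc_droplets`, `qc_ntc`, `qc_positive_control`, `qc_amplitude` and the
#'   conjunction `qc_pass`.
#' @export
qc_reactions <- function(reactions, min_droplets = 8000,
                         amplitude_bounds = NULL) {
  check_reaction_cols(reactions, c("assay_id", "role", "n_droplets", "k_mutant"))
  out <- vector("list", 0)
  for (aid in unique(reactions$assay_id)) {
    rx <- reactions[reactions$assay_id == aid, , drop = FALSE]
    ntc <- rx[rx$role == "NTC", , drop = FALSE]
    pos <- rx[rx$role == "positive_control", , drop = FALSE]
    smp <- rx[!(rx$role %in% c("NTC", "positive_control", "negative_control")), ,
              drop = FALSE]
    if (nrow(ntc) < 1 || nrow(pos) < 1) {
      abort(sprintf("assay '%s': NTC and positive control wells are required", aid))
    }
    ntc_clean <- all(ntc$k_mutant == 0)
    pos_signal <- any(pos$k_mutant >= 1)
    amp_ok <- rep(TRUE, nrow(smp))
    if (!is.null(amplitude_bounds) && "amplitudes" %in% names(smp)) {
      stopifnot(length(amplitude_bounds) == 2)
      amp_ok <- map_lgl(smp$amplitudes, function(a) {
        is.null(a) || all(a >= amplitude_bounds[1] & a <= amplitude_bounds[2])
      })
    }
    smp$qc_droplets <- smp$n_droplets >= min_droplets
    smp$qc_ntc <- ntc_clean
    smp$qc_positive_control <- pos_signal
    smp$qc_amplitude <- amp_ok
    smp$qc_pass <- smp$qc_droplets & smp$qc_ntc &
      smp$qc_positive_control & smp$qc_amplitude
    out[[length(out) + 1]] <- smp
  }
  bind_rows(out)
}

check_reaction_cols <- function(df, cols) {
  if (!is.data.frame(df)) abort("`reactions` must be a data frame")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("missing reaction column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Merge QC-passing reactions into sample-level results
#'
#' Droplet and positive-droplet counts are summed over the contributing
#' wells of each sample; the wild-type genome equivalents screened are then
#' recovered from the pooled wild-type channel by partition statistics
#' (`ge_screened = lambda_wt * n_droplets_total`, one locus copy per haploid
#' genome equivalent).
#'
#' @param reactions Tibble of QC-passing sample reactions with columns
#'   `sample_id`, `assay_id`, `n_droplets`, `k_mutant`, `k_wildtype` and
#'   optionally `eluate_ul` (the eluate volume consumed by each well).
#' @param plasma_ml Plasma volume the eluate derives from (default 8 mL).
#' @param eluate_ul_total Total eluate volume (default 60 uL); with a
#'   per-well `eluate_ul` column, `fraction_eluate_analyzed` is the summed
#'   analysed volume over this total.
#' @param fraction_eluate_analyzed Fallback fraction in (0, 1] when no
#'   `eluate_ul` column is present.
#'
#' @return A tibble with one row per `sample_id` x `assay_id`:
#'   `n_droplets_total`, `k_mutant_total`, `k_wildtype_total`, `ge_screened`,
#'   `plasma_ml`, `fraction_eluate_analyzed`.
#' @export
merge_reactions <- function(reactions, plasma_ml = 8, eluate_ul_total = 60,
                            fraction_eluate_analyzed = 1) {
  check_reaction_cols(reactions,
                      c("sample_id", "assay_id", "n_droplets", "k_mutant",
                        "k_wildtype"))
  if (nrow(reactions) == 0) abort("no reactions to merge")
  n_assay <- dplyr::n_distinct
  per_sample_assays <- tapply(reactions$assay_id, reactions$sample_id,
                              function(a) length(unique(a)))
  if (any(per_sample_assays > 1)) {
    abort("mixed assays within a sample cannot be merged")
  }
  if (any(reactions$k_mutant > reactions$n_droplets) ||
      any(reactions$k_wildtype > reactions$n_droplets)) {
    abort("positive-droplet counts exceed droplet counts")
  }
  has_eluate <- "eluate_ul" %in% names(reactions) &&
    !anyNA(reactions$eluate_ul)
  merged <- reactions |>
    group_by(.data$sample_id, .data$assay_id) |>
    summarise(
      n_droplets_total = sum(.data$n_droplets),
      k_mutant_total = sum(.data$k_mutant),
      k_wildtype_total = sum(.data$k_wildtype),
      fraction_eluate_analyzed = if (has_eluate) {
        sum(.data$eluate_ul) / eluate_ul_total
      } else {
        fraction_eluate_analyzed
      },
      .groups = "drop"
    )
  if (any(merged$fraction_eluate_analyzed <= 0) ||
      any(merged$fraction_eluate_analyzed > 1)) {
    abort("fraction of eluate analysed must lie in (0, 1]")
  }
  merged |>
    mutate(
      ge_screened = ddpcr_lambda(.data$k_wildtype_total,
                                 .data$n_droplets_total) *
        .data$n_droplets_total,
      plasma_ml = plasma_ml
    ) |>
    select("sample_id", "assay_id", "n_droplets_total", "k_mutant_total",
           "k_wildtype_total", "ge_screened", "plasma_ml",
           "fraction_eluate_analyzed")
}

#' Mutant genome equivalents per millilitre of plasma
#'
#' Converts an (error-corrected) mutant molecule count into mutant genome
#' equivalents per mL plasma, compensating for the fraction of the eluate
#' actually analysed. Negative corrected counts (possible after noise
#' subtraction) are clamped to zero.
#'
#' @param corrected_copies Mutant molecules observed (after correction).
#' @param plasma_ml Plasma volume extracted (default 8 mL).
#' @param fraction_eluate_analyzed Fraction of the eluate analysed, in (0, 1].
#'
#' @return Mutant GE per mL plasma (vectorised, never negative).
#' @examples
#' mutant_per_ml(8, plasma_ml = 8, fraction_eluate_analyzed = 1) # 1 GE/mL
#' @export
mutant_per_ml <- function(corrected_copies, plasma_ml = 8,
                          fraction_eluate_analyzed = 1) {
  if (any(plasma_ml <= 0)) abort("`plasma_ml` must be positive")
  if (any(fraction_eluate_analyzed <= 0) || any(fraction_eluate_analyzed > 1)) {
    abort("`fraction_eluate_analyzed` must lie in (0, 1]")
  }
  pmax(corrected_copies, 0) / (plasma_ml * fraction_eluate_analyzed)
}

#' Simulate one ddPCR reaction
#'
#' Mutant and wild-type molecule totals are Poisson draws from concentration
#' times the dropletised reaction volume and are distributed uniformly over
#' the droplets; a droplet is channel-positive when it holds at least one
#' molecule of that species. Under this model the positive-droplet count is
#' marginally Binomial(n, 1 - exp(-lambda)), which the counts-only path
#' samples directly; per-droplet occupancy and amplitudes are materialised
#' only when `with_amplitudes = TRUE`. False-positive mutant events are added
#' at the assay's `fp_rate_per_ge` per wild-type genome equivalent screened.
#'
#' @param assay A [ddpcr_assay()].
#' @param mutant_copies_per_ul,wt_copies_per_ul Concentrations in the
#'   reaction mix (copies per uL, nonnegative).
#' @param reaction_volume_ul Volume converted to droplets (default 20 uL).
#' @param n_droplets Droplet count; when `NULL`, drawn from the instrument's
#'   Normal(16948, 1852) well-to-well distribution (floored at 1000).
#' @param role Well role: `"sample"`, `"NTC"`, `"positive_control"` or
#'   `"negative_control"`.
#' @param sample_id,eluate_ul Metadata carried through to downstream merging.
#' @param with_amplitudes Attach a per-droplet amplitude vector drawn from
#'   the assay's three Gaussian clusters.
#' @param seed Optional integer seed; fixed seeds reproduce the reaction
#'   exactly.
#'
#' @return A one-row tibble with columns `sample_id`, `assay_id`, `role`,
#'   `n_droplets`, `k_mutant`, `k_wildtype`, `eluate_ul` and (optionally) an
#'   `amplitudes` list-column.
#' @export
simulate_ddpcr_reaction <- function(assay,
                                    mutant_copies_per_ul,
                                    wt_copies_per_ul,
                                    reaction_volume_ul = 20,
                                    n_droplets = NULL,
                                    role = "sample",
                                    sample_id = NA_character_,
                                    eluate_ul = NA_real_,
                                    with_amplitudes = FALSE,
                                    seed = NULL) {
  stopifnot(inherits(assay, "ddpcr_assay"))
  if (mutant_copies_per_ul < 0 || wt_copies_per_ul < 0) {
    abort("concentrations must be nonnegative")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_droplets)) {
    n_droplets <- max(1000L, as.integer(round(rnorm(1, 16948, 1852))))
  }
  n <- as.integer(n_droplets)
  lam_mut <- mutant_copies_per_ul * reaction_volume_ul / n
  lam_wt <- wt_copies_per_ul * reaction_volume_ul / n
  lam_fp <- assay$fp_rate_per_ge * lam_wt * n / n # fp molecules per droplet

  if (with_amplitudes) {
    m_mut <- rpois(1, lam_mut * n) + rpois(1, lam_fp * n)
    m_wt <- rpois(1, lam_wt * n)
    mut_occ <- occupancy_vector(n, m_mut)
    wt_occ <- occupancy_vector(n, m_wt)
    k_mut <- sum(mut_occ)
    k_wt <- sum(wt_occ)
    amps <- numeric(n)
    draw <- function(cl, m) rnorm(m, cl[["mean"]], cl[["sd"]])
    amps[!mut_occ & !wt_occ] <- draw(assay$amplitude_empty, sum(!mut_occ & !wt_occ))
    amps[!mut_occ & wt_occ] <- draw(assay$amplitude_wildtype, sum(!mut_occ & wt_occ))
    amps[mut_occ] <- draw(assay$amplitude_mutant, sum(mut_occ))
    res <- tibble(
      sample_id = sample_id, assay_id = assay$assay_id, role = role,
      n_droplets = n, k_mutant = as.integer(k_mut),
      k_wildtype = as.integer(k_wt), eluate_ul = eluate_ul,
      amplitudes = list(amps)
    )
  } else {
    k_mut <- rbinom(1, n, -expm1(-lam_mut))
    k_fp <- rbinom(1, n - k_mut, -expm1(-lam_fp))
    k_wt <- rbinom(1, n, -expm1(-lam_wt))
    res <- tibble(
      sample_id = sample_id, assay_id = assay$assay_id, role = role,
      n_droplets = n, k_mutant = as.integer(k_mut + k_fp),
      k_wildtype = as.integer(k_wt), eluate_ul = eluate_ul
    )
  }
  res
}

occupancy_vector <- function(n, m) {
  occ <- logical(n)
  if (m > 0) occ[unique(sample.int(n, m, replace = TRUE))] <- TRUE
  occ
}
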