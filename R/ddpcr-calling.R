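# Blank-derived per-assay noise profiles and the four-caller consensus call.
#
# The four callers share an interface (merged sample table in, one row per
# sample out) but model the blank noise differently:
#   * Poisson      — pooled blank rate, Poisson tail test;
#   * CASTLE-style — negative-binomial noise fit with exposure = GE screened,
#                    tail test, and error-corrected molecule count;
#   * ALPACA-style — beta-binomial test on the mutant droplet fraction with
#                    moments estimated from the blanks;
#   * dynamic LOB  — empirical limit of blank rescaled to the sample's DNA
#                    input.
# A consensus is positive/negative when >= 3 of 4 agree; 2-2 ties fall back
# to the error-corrected (CASTLE-style) caller, which also supplies the
# quantitative ctDNA level.

#' Build a per-assay noise profile from blank samples
#'
#' Stores the blank panel verbatim (one row per blank: genome equivalents
#' screened and false-positive mutant count) together with the derived noise
#' models each caller needs: the pooled false-positive rate, a
#' negative-binomial fit with log link and exposure equal to GE screened
#' (falling back to Poisson when dispersion is unidentifiable), the empirical
#' per-GE rate distribution for the dynamic limit of blank, and beta-binomial
#' moments of the blank mutant fractions.
#'
#' @param blanks Tibble with columns `ge_screened` (positive) and `fp_count`
#'   (nonnegative integers). Output of [merge_reactions()] on blank wells is
#'   accepted directly (columns `ge_screened`, `k_mutant_total`).
#' @param assay_id Optional assay identifier recorded in the profile.
#'
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(blanks, assay_id = NA_character_) {
  if (!is.data.frame(blanks)) abort("`blanks` must be a data frame")
  if (!"fp_count" %in% names(blanks) && "k_mutant_total" %in% names(blanks)) {
    blanks$fp_count <- blanks$k_mutant_total
  }
  missing <- setdiff(c("ge_screened", "fp_count"), names(blanks))
  if (length(missing)) {
    abort(paste0("`blanks` must contain column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(blanks) < 2) abort("profile underdetermined: need >= 2 blanks")
  if (any(blanks$ge_screened <= 0)) abort("blank `ge_screened` must be positive")
  if (any(blanks$fp_count < 0)) abort("blank `fp_count` must be nonnegative")

  ge <- blanks$ge_screened
  fp <- blanks$fp_count
  pooled_rate <- sum(fp) / sum(ge)

  # Negative-binomial noise fit (CASTLE-style error model). Degenerate blank
  # panels (e.g. all-zero counts) are flagged and served by the pooled
  # Poisson rate instead.
  castle <- tryCatch({
    fit <- suppressWarnings(
      MASS::glm.nb(fp ~ 1 + offset(log(ge)), control = glm.control(maxit = 50))
    )
    theta <- fit$theta
    if (!is.finite(theta) || theta <= 0) stop("dispersion unidentifiable")
    list(rate = unname(exp(coef(fit)[1])), theta = theta,
         family = "negative_binomial", fallback = FALSE)
  }, error = function(e) {
    list(rate = pooled_rate, theta = Inf, family = "poisson", fallback = TRUE)
  })

  # Beta-binomial moments on blank mutant fractions (ALPACA-style). Trials
  # per blank are the molecules screened (wild-type GE plus false positives).
  trials <- round(ge) + fp
  p_hat <- sum(fp) / sum(trials)
  alpaca <- list(p = p_hat, model = "binomial", a = NA_real_, b = NA_real_)
  if (p_hat > 0 && nrow(blanks) > 1) {
    phi <- sum((fp - trials * p_hat)^2 / (trials * p_hat * (1 - p_hat))) /
      (nrow(blanks) - 1)
    rho <- (phi - 1) / (mean(trials) - 1)
    if (is.finite(rho) && rho > 0 && rho < 1) {
      ab <- 1 / rho - 1
      alpaca <- list(p = p_hat, model = "beta_binomial",
                     a = p_hat * ab, b = (1 - p_hat) * ab)
    }
  }

  structure(
    list(assay_id = assay_id,
         blanks = as_tibble(blanks[, c("ge_screened", "fp_count")]),
         n_blanks = nrow(blanks),
         pooled_rate = pooled_rate,
         rates = fp / ge,
         castle = castle,
         alpaca = alpaca),
    class = "noise_profile"
  )
}

#' @export
print.noise_profile <- function(x, ...) {
  cat("<noise_profile>", x$n_blanks, "blanks",
      if (!is.na(x$assay_id)) paste0("(assay ", x$assay_id, ")") else "", "\n")
  cat("  pooled fp rate:", format(x$pooled_rate, digits = 3), "per GE\n")
  cat("  noise model:", x$castle$family, "\n")
  invisible(x)
}

check_called_sample <- function(samples) {
  need <- c("sample_id", "k_mutant_total", "ge_screened")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    abort(paste0("merged sample table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(samples$ge_screened <= 0)) abort("`ge_screened` must be positive")
  invisible(samples)
}

caller_tbl <- function(samples, caller, positive, p_value,
                       expected_noise, corrected = NA_real_) {
  tibble(sample_id = samples$sample_id, caller = caller,
         positive = positive, p_value = p_value,
         expected_noise = expected_noise, corrected_copies = corrected)
}

#' Poisson blank-rate caller
#'
#' Expected noise is the pooled blank false-positive rate times the sample's
#' genome equivalents screened; the sample is positive when the Poisson upper
#' tail probability of its mutant count falls below `alpha`.
#'
#' @param samples Merged sample tibble ([merge_reactions()] output).
#' @param profile A [noise_profile()].
#' @param alpha Per-caller significance level (default 0.05).
#'
#' @return Tibble with one row per sample: `caller`, `positive`, `p_value`,
#'   `expected_noise`, `corrected_copies` (NA for this caller).
#' @export
call_poisson <- function(samples, profile, alpha = 0.05) {
  stopifnot(inherits(profile, "noise_profile"))
  check_called_sample(samples)
  mu <- profile$pooled_rate * samples$ge_screened
  p <- ppois(samples$k_mutant_total - 1, mu, lower.tail = FALSE)
  caller_tbl(samples, "poisson", p < alpha, p, mu)
}

#' Dynamic limit-of-blank caller
#'
#' Each blank's false-positive count is rescaled to the sample's DNA input
#' (`fp_i * ge_sample / ge_i`); the limit of blank is the chosen empirical
#' quantile of those rescaled counts and the sample is positive when its
#' mutant count strictly exceeds it (an exactly-LOB count is negative).
#'
#' @inheritParams call_poisson
#' @param lob_quantile Blank quantile defining the LOB (default 0.95).
#' @export
call_dynamic_lob <- function(samples, profile, lob_quantile = 0.95) {
  stopifnot(inherits(profile, "noise_profile"))
  check_called_sample(samples)
  q_rate <- unname(quantile(profile$rates, lob_quantile))
  lob <- q_rate * samples$ge_screened
  res <- caller_tbl(samples, "dynamic_lob", samples$k_mutant_total > lob,
                    NA_real_, lob)
  res$lob <- lob
  res
}

#' Error-corrected (CASTLE-style) caller
#'
#' Tests the mutant count against the profile's negative-binomial noise fit
#' (Poisson when the dispersion was unidentifiable) and reports the
#' error-corrected molecule count `max(0, k - expected_noise)`, which is the
#' quantity converted to GE/mL by the consensus.
#'
#' @inheritParams call_poisson
#' @export
call_castle <- function(samples, profile, alpha = 0.05) {
  stopifnot(inherits(profile, "noise_profile"))
  check_called_sample(samples)
  mu <- profile$castle$rate * samples$ge_screened
  k <- samples$k_mutant_total
  if (profile$castle$family == "negative_binomial") {
    p <- pnbinom(k - 1, size = profile$castle$theta, mu = mu,
                 lower.tail = FALSE)
  } else {
    p <- ppois(k - 1, mu, lower.tail = FALSE)
  }
  caller_tbl(samples, "castle", p < alpha, p, mu, pmax(0, k - mu))
}

# Upper tail P(X >= k) of a beta-binomial(n, a, b), vectorised over samples.
betabinom_tail <- function(k, n, a, b) {
  map2_dbl(k, n, function(ki, ni) {
    if (ki <= 0) return(1)
    if (ni <= 0) return(1)
    j <- seq(0, min(ki - 1, ni))
    1 - sum(exp(lchoose(ni, j) + lbeta(a + j, b + ni - j) - lbeta(a, b)))
  })
}

#' Beta-binomial fraction (ALPACA-style) caller
#'
#' Models the mutant droplet fraction `k / (k_mutant + k_wildtype)` as
#' beta-binomial with parameters estimated from the blank fractions by the
#' method of moments; when the blanks show no excess-binomial variance the
#' test reduces to an exact binomial tail. Samples with no positive droplets
#' in either channel are negative with p = 1.
#'
#' @inheritParams call_poisson
#' @export
call_alpaca <- function(samples, profile, alpha = 0.05) {
  stopifnot(inherits(profile, "noise_profile"))
  check_called_sample(samples)
  if (!"k_wildtype_total" %in% names(samples)) {
    abort("ALPACA-style caller needs `k_wildtype_total`")
  }
  k <- samples$k_mutant_total
  n <- k + samples$k_wildtype_total
  al <- profile$alpaca
  p <- if (al$model == "beta_binomial") {
    betabinom_tail(k, n, al$a, al$b)
  } else {
    ifelse(n == 0, 1, stats::pbinom(k - 1, n, al$p, lower.tail = FALSE))
  }
  p[n == 0] <- 1
  caller_tbl(samples, "alpaca", p < alpha & n > 0, p, al$p * n)
}

#' Consensus over the four callers
#'
#' The consensus is the majority verdict when at least three of the four
#' callers agree; on a 2-2 split the error-corrected caller's verdict is
#' used. The ctDNA level is always the error-corrected molecule count
#' converted to mutant GE per mL plasma.
#'
#' @param results Long tibble of caller results: the row-bound output of the
#'   four callers, exactly one row per caller per sample.
#' @param samples Merged sample tibble carrying `plasma_ml` and
#'   `fraction_eluate_analyzed` for the level conversion.
#'
#' @return Tibble with one row per sample: `sample_id`, `method` ("ST"),
#'   `positive`, `level_ge_per_ml`, `votes_positive`, plus per-caller
#'   verdict columns `pos_castle`, `pos_poisson`, `pos_alpaca`,
#'   `pos_dynamic_lob`.
#' @export
consensus_call <- function(results, samples) {
  need <- c("sample_id", "caller", "positive")
  if (!all(need %in% names(results))) {
    abort("`results` must hold sample_id, caller, positive")
  }
  callers <- c("castle", "poisson", "alpaca", "dynamic_lob")
  counts <- table(results$sample_id, results$caller)
  if (!setequal(colnames(counts), callers) || any(counts != 1)) {
    abort("each sample needs exactly one result from each of the four callers")
  }
  wide <- results |>
    select("sample_id", "caller", "positive") |>
    pivot_wider(names_from = "caller", values_from = "positive",
                names_prefix = "pos_")
  corrected <- results |>
    filter(.data$caller == "castle") |>
    select("sample_id", "corrected_copies")
  meta <- samples[, intersect(names(samples),
                              c("sample_id", "plasma_ml",
                                "fraction_eluate_analyzed"))]
  if (!"plasma_ml" %in% names(meta)) meta$plasma_ml <- 8
  if (!"fraction_eluate_analyzed" %in% names(meta)) {
    meta$fraction_eluate_analyzed <- 1
  }
  out <- wide |>
    left_join(corrected, by = "sample_id") |>
    left_join(meta, by = "sample_id") |>
    mutate(
      votes_positive = .data$pos_castle + .data$pos_poisson +
        .data$pos_alpaca + .data$pos_dynamic_lob,
      positive = case_when(
        .data$votes_positive >= 3 ~ TRUE,
        .data$votes_positive <= 1 ~ FALSE,
        TRUE ~ .data$pos_castle
      ),
      level_ge_per_ml = mutant_per_ml(.data$corrected_copies,
                                      .data$plasma_ml,
                                      .data$fraction_eluate_analyzed),
      method = "ST"
    ) |>
    select("sample_id", "method", "positive", "level_ge_per_ml",
           "votes_positive", "pos_castle", "pos_poisson", "pos_alpaca",
           "pos_dynamic_lob")
  out
}

#' Run all four callers and form the consensus
#'
#' Convenience wrapper: applies the Poisson, error-corrected, beta-binomial
#' and dynamic-LOB callers to a merged sample table and returns the
#' consensus call per sample.
#'
#' @inheritParams call_poisson
#' @param lob_quantile Quantile for the dynamic limit of blank.
#' @return See [consensus_call()].
#' @export
call_st <- function(samples, profile, alpha = 0.05, lob_quantile = 0.95) {
  results <- bind_rows(
    call_castle(samples, profile, alpha),
    call_poisson(samples, profile, alpha),
    call_alpaca(samples, profile, alpha),
    call_dynamic_lob(samples, profile, lob_quantile)
  )
  consensus_call(results, samples)
}
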