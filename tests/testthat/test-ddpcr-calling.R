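zero_profile <- function(n = 10, ge = 5000) {
  noise_profile(tibble::tibble(ge_screened = rep(ge, n), fp_count = 0L))
}

test_that("noise profiles store blanks verbatim and pool the rate", {
  set.seed(3)
  rate <- 1e-5
  ge <- exp(seq(log(500), log(20000), length.out = 94))
  fp <- rpois(94, rate * ge)
  prof <- noise_profile(tibble::tibble(ge_screened = ge, fp_count = fp))
  expect_equal(prof$n_blanks, 94)
  expect_equal(prof$blanks$fp_count, fp)
  # pooled estimate within 3 SE of the generating rate
  se <- sqrt(rate / sum(ge))
  expect_lt(abs(prof$pooled_rate - rate), 3 * se)

  expect_equal(zero_profile()$pooled_rate, 0)
  expect_error(noise_profile(tibble::tibble(ge_screened = 1000, fp_count = 0L)),
               "underdetermined")
})

test_that("Poisson caller matches the exact tail and its limits", {
  prof05 <- noise_profile(tibble::tibble(ge_screened = c(1, 1),
                                         fp_count = c(1L, 0L)))
  # mu = 0.5 at ge 1; k = 4: exact tail sum
  res <- call_poisson(merged_row(4, ge = 1, k_wt = 10000), prof05,
                      alpha = 0.01)
  exact <- 1 - exp(-0.5) * (1 + 0.5 + 0.5^2 / 2 + 0.5^3 / 6)
  expect_equal(res$p_value, exact, tolerance = 1e-12)
  expect_true(res$positive)

  # k = 0 is never positive
  res0 <- call_poisson(merged_row(0, ge = 1), prof05)
  expect_equal(res0$p_value, 1)
  expect_false(res0$positive)

  # no-noise limit: any count is decisive
  res1 <- call_poisson(merged_row(1, ge = 5000), zero_profile())
  expect_equal(res1$p_value, 0)
  expect_true(res1$positive)
})

test_that("dynamic LOB scales with DNA input and treats ties as negative", {
  # all-zero blanks: LOB 0, one molecule is positive
  res <- call_dynamic_lob(merged_row(1, ge = 5000), zero_profile())
  expect_true(res$positive)

  blanks <- tibble::tibble(ge_screened = rep(1000, 20),
                           fp_count = rep(c(0L, 2L), 10))
  prof <- noise_profile(blanks)
  s <- merged_row(1, ge = 1000)
  lob <- call_dynamic_lob(s, prof)$lob
  # count exactly at the LOB stays negative (strict inequality)
  at <- call_dynamic_lob(merged_row(as.integer(lob), ge = 1000), prof)
  expect_false(at$positive)
  # doubling the sample GE doubles the LOB
  lob2 <- call_dynamic_lob(merged_row(1, ge = 2000), prof)$lob
  expect_equal(lob2, 2 * lob)
})

test_that("error-corrected caller clamps and falls back cleanly", {
  # zero-noise profile: corrected copies equal the raw count
  res <- call_castle(merged_row(5, ge = 5000), zero_profile())
  expect_equal(res$corrected_copies, 5)
  expect_true(res$positive)
  expect_equal(zero_profile()$castle$family, "poisson") # flagged fallback

  # expected noise above the count clamps the correction at zero
  noisy <- noise_profile(tibble::tibble(ge_screened = rep(100, 20),
                                        fp_count = rep(5L, 20)))
  res2 <- call_castle(merged_row(2, ge = 100), noisy)
  expect_equal(res2$corrected_copies, 0)
  expect_false(res2$positive)
})

test_that("error modelling absorbs overdispersed blanks better than Poisson", {
  set.seed(41)
  n_blank <- 300
  ge <- rep(5000, n_blank)
  # gamma-mixed rates: mean 2e-4 per GE, strongly overdispersed
  rates <- rgamma(n_blank, shape = 0.5, rate = 0.5 / 2e-4)
  fp <- rpois(n_blank, rates * ge)
  prof <- noise_profile(tibble::tibble(ge_screened = ge, fp_count = fp))
  expect_equal(prof$castle$family, "negative_binomial")

  # fresh blanks from the same overdispersed process
  m <- 2000
  new_fp <- rpois(m, rgamma(m, shape = 0.5, rate = 0.5 / 2e-4) * 5000)
  samples <- merged_row(new_fp, ge = rep(5000, m),
                        sample_id = sprintf("B%04d", 1:m))
  fp_castle <- mean(call_castle(samples, prof, alpha = 0.05)$positive)
  fp_pois <- mean(call_poisson(samples, prof, alpha = 0.05)$positive)
  expect_lte(fp_castle, fp_pois)
})

test_that("beta-binomial caller reduces to the binomial tail and is monotone", {
  res0 <- call_alpaca(merged_row(0, ge = 5000), zero_profile())
  expect_false(res0$positive)

  # zero variance in the blank fractions: binomial tail
  blanks <- tibble::tibble(ge_screened = rep(1000, 10), fp_count = rep(1L, 10))
  prof <- noise_profile(blanks)
  expect_equal(prof$alpaca$model, "binomial")
  s <- merged_row(3, ge = 1000, k_wt = 997)
  res <- call_alpaca(s, prof)
  p_hat <- 10 / sum(1001 * 10)
  expect_equal(res$p_value,
               pbinom(2, 1000, p_hat, lower.tail = FALSE),
               tolerance = 1e-12)

  # p-value non-increasing in the mutant count at fixed wild-type count
  ks <- 0:10
  ps <- call_alpaca(merged_row(ks, ge = rep(1000, 11), k_wt = rep(5000, 11),
                               sample_id = sprintf("S%02d", ks)),
                    prof)$p_value
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("every caller is monotone in the mutant count", {
  set.seed(8)
  blanks <- tibble::tibble(ge_screened = exp(seq(log(500), log(20000),
                                                 length.out = 94)))
  blanks$fp_count <- rpois(94, 1e-5 * blanks$ge_screened)
  prof <- noise_profile(blanks)
  ks <- 0:12
  samples <- merged_row(ks, ge = rep(8000, 13), k_wt = rep(8000, 13),
                        sample_id = sprintf("S%02d", ks))
  for (f in list(call_poisson, call_castle, call_alpaca)) {
    pos <- f(samples, prof)$positive
    expect_true(all(diff(pos) >= 0)) # never flips positive -> negative
  }
  pos_lob <- call_dynamic_lob(samples, prof)$positive
  expect_true(all(diff(pos_lob) >= 0))
})

four_results <- function(castle, poisson, alpaca, lob, corrected = 4) {
  tibble::tibble(
    sample_id = "S1",
    caller = c("castle", "poisson", "alpaca", "dynamic_lob"),
    positive = c(castle, poisson, alpaca, lob),
    p_value = 0.5, expected_noise = 0,
    corrected_copies = c(corrected, NA, NA, NA)
  )
}

test_that("consensus follows the 3-of-4 rule with the error-corrected tie-break", {
  s <- merged_row(4, ge = 5000)
  # 3-1 majority is decisive
  maj <- consensus_call(four_results(TRUE, TRUE, TRUE, FALSE), s)
  expect_true(maj$positive)
  # 2-2 tie defers to the error-corrected caller
  tie_neg <- consensus_call(four_results(FALSE, TRUE, FALSE, TRUE), s)
  expect_false(tie_neg$positive)
  tie_pos <- consensus_call(four_results(TRUE, FALSE, TRUE, FALSE), s)
  expect_true(tie_pos$positive)
  # unanimous negative, level from the corrected count
  neg <- consensus_call(four_results(FALSE, FALSE, FALSE, FALSE,
                                     corrected = 0), s)
  expect_false(neg$positive)
  expect_equal(neg$level_ge_per_ml, 0)
  # all four callers are mandatory
  expect_error(consensus_call(four_results(TRUE, TRUE, TRUE, TRUE)[1:3, ], s),
               "four callers")
})

test_that("consensus is symmetric in the three non-tie-break callers", {
  s <- merged_row(4, ge = 5000)
  base <- four_results(FALSE, TRUE, TRUE, FALSE)
  perms <- list(c(2, 3, 4), c(3, 2, 4), c(4, 3, 2), c(2, 4, 3), c(3, 4, 2),
                c(4, 2, 3))
  votes <- vapply(perms, function(p) {
    r <- base
    r$positive[2:4] <- base$positive[p]
    consensus_call(r, s)$positive
  }, logical(1))
  expect_true(all(votes == votes[1]))
})

test_that("blank-like samples stay below the specificity budget", {
  set.seed(23)
  rate <- 1e-5
  ge_b <- exp(seq(log(500), log(20000), length.out = 94))
  prof <- noise_profile(tibble::tibble(ge_screened = ge_b,
                                       fp_count = rpois(94, rate * ge_b)))
  m <- 2000
  ge_s <- exp(runif(m, log(2000), log(15000)))
  samples <- merged_row(rpois(m, rate * ge_s), ge = ge_s,
                        k_wt = round(ge_s), sample_id = sprintf("B%04d", 1:m))
  fps <- c(
    poisson = mean(call_poisson(samples, prof, 0.05)$positive),
    castle = mean(call_castle(samples, prof, 0.05)$positive),
    alpaca = mean(call_alpaca(samples, prof, 0.05)$positive),
    lob = mean(call_dynamic_lob(samples, prof, 0.95)$positive)
  )
  expect_true(all(fps <= 0.07))
  cons <- mean(call_st(samples, prof, 0.05)$positive)
  expect_lte(cons, max(fps))
})

test_that("detection probability grows with the DNA amount screened", {
  set.seed(19)
  rate <- 1e-5
  ge_b <- exp(seq(log(500), log(20000), length.out = 94))
  prof <- noise_profile(tibble::tibble(ge_screened = ge_b,
                                       fp_count = rpois(94, rate * ge_b)))
  conc <- 5e-4 # mutant molecules per GE screened
  rates <- vapply(c(2000, 8000, 20000), function(ge) {
    m <- 600
    k <- rpois(m, (conc + rate) * ge)
    s <- merged_row(k, ge = rep(ge, m), k_wt = rep(round(ge), m),
                    sample_id = sprintf("S%04d", 1:m))
    mean(call_st(s, prof)$positive)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
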