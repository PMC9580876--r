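paper_table <- concordance_table(n_both_pos = 134, n_st_only = 11,
                                 n_mt_only = 27, n_both_neg = 207)

test_that("kappa handles agreement, independence and the study table", {
  diag <- concordance_table(n_both_pos = 30, n_st_only = 0, n_mt_only = 0,
                            n_both_neg = 70)
  expect_equal(cohens_kappa(diag), 1)
  indep <- concordance_table(n_both_pos = 50, n_st_only = 50, n_mt_only = 50,
                             n_both_neg = 50)
  expect_equal(cohens_kappa(indep), 0)
  expect_equal(cohens_kappa(paper_table), 0.79, tolerance = 0.005)
  # invariant under relabelling of the two methods (transpose)
  transposed <- concordance_table(n_both_pos = 134, n_st_only = 27,
                                  n_mt_only = 11, n_both_neg = 207)
  expect_equal(cohens_kappa(transposed), cohens_kappa(paper_table))
  degenerate <- concordance_table(n_both_pos = 10, n_st_only = 0,
                                  n_mt_only = 0, n_both_neg = 0)
  expect_error(cohens_kappa(degenerate), "degenerate")
})

test_that("agreement fraction is the diagonal mass", {
  expect_equal(agreement_fraction(paper_table), 341 / 379)
  all_agree <- concordance_table(n_both_pos = 5, n_st_only = 0,
                                 n_mt_only = 0, n_both_neg = 5)
  expect_equal(agreement_fraction(all_agree), 1)
  none <- concordance_table(n_both_pos = 0, n_st_only = 3, n_mt_only = 4,
                            n_both_neg = 0)
  expect_equal(agreement_fraction(none), 0)
})

test_that("Wilson interval matches the closed form and shrinks with n", {
  expect_equal(wilson_interval(0, 50)[["lower"]], 0)
  expect_equal(wilson_interval(50, 50)[["upper"]], 1)

  # independent evaluation of the score bounds
  k <- 3; n <- 124; z <- qnorm(0.975); p <- k / n
  lo <- (2 * n * p + z^2 - z * sqrt(z^2 + 4 * n * p * (1 - p))) /
    (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + z * sqrt(z^2 + 4 * n * p * (1 - p))) /
    (2 * (n + z^2))
  ci <- wilson_interval(3, 124)
  expect_equal(ci[["lower"]], lo, tolerance = 1e-6)
  expect_equal(ci[["upper"]], hi, tolerance = 1e-6)
  expect_true(ci[["lower"]] <= p && p <= ci[["upper"]])

  widths <- vapply(c(50, 100, 400, 1600), function(nn) {
    ci <- wilson_interval(round(0.1 * nn), nn)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  m <- matrix(c(1, 10, 17, 10), nrow = 2, byrow = TRUE)
  expect_equal(fisher_exact(m)$p_value, 0.0036570, tolerance = 1e-4)
  expect_equal(fisher_exact(m)$p_value, fisher_enum_oracle(m),
               tolerance = 1e-12)
  prop <- matrix(c(2, 4, 3, 6), nrow = 2, byrow = TRUE)
  expect_equal(fisher_exact(prop)$p_value, 1)
  empty <- matrix(c(0, 0, 3, 6), nrow = 2, byrow = TRUE)
  expect_equal(fisher_exact(empty)$p_value, 1)
  # row and column swaps leave the p-value unchanged
  expect_equal(fisher_exact(m[2:1, ])$p_value, fisher_exact(m)$p_value)
  expect_equal(fisher_exact(m[, 2:1])$p_value, fisher_exact(m)$p_value)

  set.seed(2)
  for (i in 1:25) {
    mm <- matrix(rpois(4, 6), nrow = 2)
    expect_equal(fisher_exact(mm)$p_value, fisher_enum_oracle(mm),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum test matches enumeration and rank invariances", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1) # 2 x 1/20, fully separated groups
  expect_equal(r$p_value, ranksum_enum_oracle(c(1, 2, 3), c(4, 5, 6)))

  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)

  set.seed(14)
  x <- rnorm(4); y <- rnorm(5)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, ranksum_enum_oracle(x, y))
  # invariance under a common strictly monotone transform
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$statistic,
               wilcoxon_rank_sum(x, y)$statistic)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("signed-rank test matches sign-pattern enumeration", {
  d <- c(1.2, 0.4, 2.2, 0.9, 1.7)
  r <- wilcoxon_signed_rank(d)
  expect_equal(r$p_value, 2 / 32) # all-positive differences, n = 5
  expect_equal(r$p_value, signedrank_enum_oracle(d))
  # antisymmetry
  expect_equal(wilcoxon_signed_rank(-d)$p_value, r$p_value)
  # symmetric pairs leave the statistic at its null centre
  sym <- c(1, -1, 2, -2, 3, -3)
  v <- wilcoxon_signed_rank(sym)$statistic
  expect_equal(unname(v), length(sym) * (length(sym) + 1) / 4)
  expect_warning(res0 <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res0$p_value, 1)

  set.seed(21)
  dd <- rnorm(7)
  expect_equal(wilcoxon_signed_rank(dd)$p_value, signedrank_enum_oracle(dd))
})

test_that("log-log regression recovers power laws and rejects bad input", {
  x <- c(0.1, 0.5, 2, 10, 40)
  fit <- pearson_loglog(tibble::tibble(st_level = x, mt_level = x^1.7))
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1.7)
  expect_error(
    pearson_loglog(tibble::tibble(st_level = c(1, 0), mt_level = c(1, 2))),
    "both-positive"
  )
  flat <- pearson_loglog(tibble::tibble(st_level = x, mt_level = rep(2, 5)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))

  set.seed(6)
  st <- rlnorm(134, 0, 1.5)
  mt <- st * rlnorm(134, 0, 0.1 * log(10))
  noisy <- pearson_loglog(tibble::tibble(st_level = st, mt_level = mt))
  expect_gt(noisy$r, 0.95)
})

test_that("specificities reproduce their defining fractions", {
  rec <- make_records(
    patient_id = rep(sprintf("P%02d", 1:31), each = 4),
    time = rep(seq(3, 12, by = 3), 31),
    st = FALSE
  )
  rec$st_positive[c(1, 30, 70)] <- TRUE # three sporadic false positives
  expect_equal(sample_specificity(rec, "st"), 1 - 3 / 124)
  expect_equal(sample_specificity(rec, "mt"), 1)
  expect_equal(patient_specificity(rec, "st"), 1 - 3 / 31)
  # with every patient contributing samples, patient-level specificity can
  # only be at or below sample-level specificity
  expect_lte(patient_specificity(rec, "st"), sample_specificity(rec, "st"))
  expect_error(sample_specificity(rec[0, ], "st"), "no serial samples")
})

test_that("lead times are measured from first detection to recurrence", {
  # detection exactly at recurrence: zero lead
  at_rec <- make_records("P1", time = c(6, 12), st = c(FALSE, TRUE),
                         recurrence_time = 12)
  lt <- lead_times(at_rec)
  expect_equal(lt$per_patient$st_lead, 0)

  rec <- make_records(
    patient_id = rep(c("P1", "P2", "P3"), each = 3),
    time = rep(c(3, 6, 9), 3),
    st = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    recurrence_time = rep(c(8, 9, 11), each = 3)
  )
  lt <- lead_times(rec)
  expect_equal(sort(lt$per_patient$st_lead), c(2, 2, 6))
  expect_equal(unname(lt$median_lead[["st"]]), 2)
  # identical detection times in both arms: paired p = 1
  expect_equal(lt$paired_p, 1)
  expect_equal(median(c(2, 4, 6)), 4)
})
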