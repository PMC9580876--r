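test_that("amplitude threshold sits k SDs below the positive-cluster mean", {
  empty <- exact_cluster(5000, 1000, 200, seed = 11)
  pos <- exact_cluster(400, 10000, 500, seed = 12)
  amps <- c(empty, pos)
  expect_equal(amplitude_threshold(amps, k_sd = 3), 10000 - 3 * 500,
               tolerance = 1e-10)
  expect_equal(amplitude_threshold(amps, k_sd = 0), 10000, tolerance = 1e-10)
  # a control with no positive cluster is uninformative
  expect_error(amplitude_threshold(exact_cluster(3000, 1000, 200)),
               "uninformative positive control")
})

test_that("threshold from a simulated control matches the generating clusters", {
  assay <- ddpcr_assay("A", fp_rate_per_ge = 0)
  ctrl <- simulate_ddpcr_reaction(assay, mutant_copies_per_ul = 300,
                                  wt_copies_per_ul = 0, n_droplets = 10000,
                                  role = "positive_control",
                                  with_amplitudes = TRUE, seed = 42)
  thr <- amplitude_threshold(ctrl, k_sd = 3)
  analytic <- 10000 - 3 * 500
  expect_lt(abs(thr - analytic) / analytic, 0.01)
})

test_that("droplet classification counts amplitudes against the threshold", {
  expect_equal(classify_droplets(c(1, 2, 3), 2.5),
               c(k_above = 1L, k_below = 2L))
  expect_equal(classify_droplets(c(1, 2, 3), 10),
               c(k_above = 0L, k_below = 3L))
  expect_equal(classify_droplets(numeric(0), 1), c(k_above = 0L, k_below = 0L))
  expect_error(classify_droplets(1:3, Inf), "finite")

  # two-cluster mixture: counts above threshold follow the mixture tail mass
  set.seed(7)
  n <- 1e4
  w <- 0.2
  from_pos <- runif(n) < w
  amps <- ifelse(from_pos, rnorm(n, 10000, 500), rnorm(n, 1000, 200))
  thr <- 8500
  tail_mass <- w * pnorm(thr, 10000, 500, lower.tail = FALSE) +
    (1 - w) * pnorm(thr, 1000, 200, lower.tail = FALSE)
  k <- classify_droplets(amps, thr)[["k_above"]]
  bounds <- qbinom(c(0.005, 0.995), n, tail_mass)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("lambda follows -log(1 - k/n) with guarded edge cases", {
  expect_identical(ddpcr_lambda(0, 100), 0)
  expect_equal(ddpcr_lambda(3000, 16948), 0.1948137, tolerance = 1e-6)
  expect_equal(ddpcr_lambda(3000, 16948), -log(1 - 3000 / 16948))
  # round trip at the study's typical load of 0.18 copies per droplet
  k <- round(16948 * (1 - exp(-0.18)))
  expect_equal(k, 2792)
  expect_equal(ddpcr_lambda(k, 16948), 0.18, tolerance = 1e-3)
  expect_error(ddpcr_lambda(10, 10), "saturated")
  expect_error(ddpcr_lambda(0, 0), "positive")
  expect_error(ddpcr_lambda(-1, 10))
})

test_that("concentration conversion respects the droplet volume", {
  expect_identical(ddpcr_concentration(0), 0)
  expect_equal(ddpcr_concentration(0.834e-3), 1)
  expect_equal(ddpcr_concentration(0.19485), 233.633, tolerance = 1e-3)
  expect_error(ddpcr_concentration(0.1, 0), "positive")
})

make_plate <- function(n_sample = 16000, k_mut_sample = 2, k_ntc = 0,
                       k_pos = 500) {
  tibble::tibble(
    sample_id = c("S1", "ntc", "pc"),
    assay_id = "A",
    role = c("sample", "NTC", "positive_control"),
    n_droplets = c(n_sample, 16000, 16000),
    k_mutant = c(k_mut_sample, k_ntc, k_pos),
    k_wildtype = c(3000, 0, 3000)
  )
}

test_that("QC applies all four rules conjunctively", {
  clean <- qc_reactions(make_plate(n_sample = 8000))
  expect_true(clean$qc_pass)

  low <- qc_reactions(make_plate(n_sample = 7999))
  expect_false(low$qc_droplets)
  expect_false(low$qc_pass)
  expect_true(low$qc_ntc)

  dirty_ntc <- qc_reactions(make_plate(k_ntc = 1))
  expect_false(dirty_ntc$qc_ntc)
  expect_false(dirty_ntc$qc_pass)

  dead_pc <- qc_reactions(make_plate(k_pos = 0))
  expect_false(dead_pc$qc_positive_control)
  expect_false(dead_pc$qc_pass)

  # controls must exist for the assay
  orphan <- make_plate()[1, ]
  expect_error(qc_reactions(orphan), "NTC and positive control")
})

test_that("merging sums counts and is order-invariant", {
  rx <- tibble::tibble(
    sample_id = "S1", assay_id = "A",
    n_droplets = c(16000L, 17000L), k_mutant = c(1L, 2L),
    k_wildtype = c(3000L, 3100L)
  )
  m <- merge_reactions(rx)
  expect_equal(m$k_mutant_total, 3L)
  expect_equal(m$n_droplets_total, 33000L)
  expect_equal(m$k_wildtype_total, 6100L)
  expect_equal(merge_reactions(rx[2:1, ]), m)
  # single well is the identity on counts
  one <- merge_reactions(rx[1, ])
  expect_equal(one$k_mutant_total, 1L)
  expect_equal(one$n_droplets_total, 16000L)
  # ge_screened is recovered from the pooled wild-type partition estimate
  expect_equal(m$ge_screened, -log(1 - 6100 / 33000) * 33000)
  expect_error(merge_reactions(rx[0, ]), "no reactions")
  rx_mixed <- rx
  rx_mixed$assay_id <- c("A", "B")
  expect_error(merge_reactions(rx_mixed), "mixed assays")
})

test_that("merged concentration recovers the generating concentration", {
  assay <- ddpcr_assay("A", fp_rate_per_ge = 0)
  conc <- 150 # copies/uL
  set.seed(99)
  wells <- dplyr::bind_rows(lapply(1:20, function(i) {
    simulate_ddpcr_reaction(assay, conc, 0, n_droplets = 16948,
                            sample_id = "S1")
  }))
  wells$k_wildtype <- 1L # keep the wt channel defined, unused here
  m <- merge_reactions(wells)
  lam <- ddpcr_lambda(m$k_mutant_total, m$n_droplets_total)
  # pooled copies = lambda * total droplets, spread over 20 wells x 20 uL
  est_conc <- lam * m$n_droplets_total / (20 * 20)
  expect_lt(abs(est_conc - conc) / conc, 0.02)
})

test_that("plasma-level quantification is linear with clamping", {
  expect_equal(mutant_per_ml(8, 8, 1), 1)
  expect_equal(mutant_per_ml(4, 8, 0.5), 1)
  expect_equal(mutant_per_ml(-0.3, 8, 1), 0)
  expect_equal(mutant_per_ml(16, 8, 1), 2 * mutant_per_ml(8, 8, 1))
  expect_equal(mutant_per_ml(8, 16, 1), mutant_per_ml(8, 8, 1) / 2)
  expect_error(mutant_per_ml(1, 8, 0), "0, 1")
  expect_error(mutant_per_ml(1, 8, 1.2), "0, 1")
})

test_that("reaction simulation is seeded, clean at zero input, and Poisson-consistent", {
  assay <- ddpcr_assay("A", fp_rate_per_ge = 0)
  a <- simulate_ddpcr_reaction(assay, 10, 100, seed = 5)
  b <- simulate_ddpcr_reaction(assay, 10, 100, seed = 5)
  expect_identical(a, b)

  zero <- vapply(1:50, function(i) {
    simulate_ddpcr_reaction(assay, 0, 100, n_droplets = 12000)$k_mutant
  }, integer(1))
  expect_true(all(zero == 0L))

  # at the study's average load, the positive fraction matches 1 - e^-0.18
  set.seed(31)
  lam <- 0.18
  n <- 16948
  conc <- lam * n / 20
  frac <- vapply(1:1000, function(i) {
    r <- simulate_ddpcr_reaction(assay, 0, conc, n_droplets = n)
    r$k_wildtype / r$n_droplets
  }, numeric(1))
  expect_lt(abs(mean(frac) - (1 - exp(-lam))) / (1 - exp(-lam)), 0.01)
})

test_that("concentration estimator is consistent over many simulated wells", {
  assay <- ddpcr_assay("A", fp_rate_per_ge = 0)
  set.seed(17)
  n <- 16948
  for (lam in c(0.05, 0.5, 1)) {
    conc <- lam * n / 20
    ks <- vapply(1:2000, function(i) {
      simulate_ddpcr_reaction(assay, conc, 0, n_droplets = n)$k_mutant
    }, integer(1))
    est <- vapply(ks, ddpcr_lambda, numeric(1), n = n)
    expect_lt(abs(mean(est) - lam) / lam, 0.01)
  }
})
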