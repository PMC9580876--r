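# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the wrapped base functions where those ARE
# the implementation), relying on direct enumeration or closed forms.

# Exact two-sided Fisher p by hypergeometric enumeration with the
# sum-of-small-point-probabilities convention.
fisher_enum_oracle <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact rank-sum null distribution by enumeration of all group assignments;
# two-sided p with the same side-doubling convention as the exact test.
ranksum_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  # untied data: the rank set is 1..N, so an assignment is a choice of nx
  # rank positions
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(i) sum(i) - nx * (nx + 1) / 2)
  if (u_obs > nx * ny / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Exact signed-rank null distribution by enumeration of all sign patterns.
signedrank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  if (v_obs > n * (n + 1) / 4) {
    p <- 2 * mean(v_all >= v_obs)
  } else {
    p <- 2 * mean(v_all <= v_obs)
  }
  min(1, p)
}

# Cox partial likelihood (Breslow form, untied event times) evaluated on
# start-stop episode data; used for grid-search verification.
cox_partial_loglik <- function(beta, episodes) {
  ev <- episodes[episodes$event == 1, ]
  ll <- 0
  for (i in seq_len(nrow(ev))) {
    t_i <- ev$stop[i]
    at_risk <- episodes$start < t_i & episodes$stop >= t_i
    ll <- ll + beta * ev$ctdna[i] -
      log(sum(exp(beta * episodes$ctdna[at_risk])))
  }
  ll
}

cox_grid_mle <- function(episodes, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, cox_partial_loglik, numeric(1), episodes = episodes)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, cox_partial_loglik, numeric(1), episodes = episodes)
  fine[which.max(llf)]
}

# Minimal serial-record builder for statistics-layer tests.
make_records <- function(patient_id, time, st, mt = st,
                         recurrence_time = NA_real_, followup = 36) {
  tibble::tibble(
    patient_id = patient_id, time_months = time,
    st_positive = st, mt_positive = mt,
    recurrence_time_months = recurrence_time, followup_months = followup
  )
}

# Amplitude vector with exactly the requested mean and sd.
exact_cluster <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# Merged-sample row(s) for caller tests.
merged_row <- function(k_mut, ge, k_wt = round(ge), n_droplets = 33000,
                       sample_id = paste0("S", seq_along(k_mut))) {
  tibble::tibble(
    sample_id = sample_id, assay_id = "A",
    n_droplets_total = n_droplets, k_mutant_total = k_mut,
    k_wildtype_total = k_wt, ge_screened = ge,
    plasma_ml = 8, fraction_eluate_analyzed = 1
  )
}
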