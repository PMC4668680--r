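# Independent oracles used by both the unit and acceptance suites.
# Each is coded directly from the defining formula, separately from the
# package implementation it checks.

# Independent Taylor-linearization oracle, written as explicit loops from
# the ratio-estimator formula (kept deliberately separate from the
# vectorized implementation).
taylor_se_oracle <- function(y, w, cl) {
  W <- 0
  for (k in seq_along(w)) W <- W + w[k]
  p <- 0
  for (k in seq_along(w)) p <- p + w[k] * y[k]
  p <- p / W
  cl_ids <- unique(cl)
  m <- length(cl_ids)
  total <- 0
  for (c_ in cl_ids) {
    z <- 0
    for (k in seq_along(w)) if (cl[k] == c_) z <- z + w[k] * (y[k] - p)
    total <- total + z^2
  }
  sqrt(m / (m - 1) * total / W^2)
}


# Independent synthetic-cohort counting oracle: explicit per-child loops
# over age segments, coded from the definition (entrants and deaths per
# segment within the period, chained survival).
q5_counting_oracle <- function(births, period, segs = default_age_segments()) {
  n_seg <- length(segs) - 1
  surv <- 1
  for (a in seq_len(n_seg)) {
    at_risk <- logical(nrow(births)); dies <- logical(nrow(births))
    for (k in seq_len(nrow(births))) {
      b <- births[k, ]
      end_age <- if (b$died) b$death_age_months else b$censor_age_months
      entry <- b$birth_date + segs[a] / 12
      if (entry < period[1] || entry >= period[2]) next
      if (end_age < segs[a]) next                       # already dead
      dies_here <- b$died && b$death_age_months >= segs[a] &&
        b$death_age_months < segs[a + 1]
      observable <- b$censor_age_months >= segs[a + 1] || dies_here
      if (!observable) next
      at_risk[k] <- TRUE
      dies[k] <- dies_here
    }
    if (surv <= 0) break
    N_a <- sum(births$weight[at_risk])
    if (N_a <= 0) return(NA_real_)
    surv <- surv * (1 - min(sum(births$weight[dies]) / N_a, 1))
  }
  1 - surv
}


# Brute-force conditioning oracle: build the joint multivariate normal of
# (grid values, noisy observations) and condition by direct solve.
gpr_oracle <- function(prior_mean, years, obs, config) {
  K <- outer(years, years, function(a, b) matern_cov(a, b, config))
  idx <- match(obs$year, years)
  D <- diag(obs$transformed_variance + config$nonsampling_var,
            nrow = nrow(obs))
  Kxd <- K[, idx, drop = FALSE]
  Kdd <- K[idx, idx, drop = FALSE] + D
  Kinv <- solve(Kdd)
  list(mean = prior_mean + drop(Kxd %*% Kinv %*% (obs$transformed_value - prior_mean[idx])),
       cov = K - Kxd %*% Kinv %*% t(Kxd))
}

random_gpr_instance <- function(seed, years = 1990:2011) {
  set.seed(seed)
  cfg <- gpr_config(nu = sample(c(0.5, 1.5, 2.5), 1),
                    length_scale = runif(1, 3, 15),
                    amplitude = runif(1, 0.1, 1),
                    nonsampling_var = runif(1, 0.001, 0.05),
                    n_draws = 10)
  n_obs <- sample(1:8, 1)
  obs <- tibble::tibble(year = sample(years, n_obs, replace = TRUE),
                        transformed_value = rnorm(n_obs),
                        transformed_variance = runif(n_obs, 0.001, 0.2))
  list(cfg = cfg, obs = obs, prior = rnorm(length(years), 0, 0.5))
}

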