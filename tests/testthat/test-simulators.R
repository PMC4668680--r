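test_that("true coverage surfaces follow the logistic trend parameters", {
  g <- make_region_graph(3, "line")
  flat <- simulate_true_coverage(g, 2000:2004,
    data.frame(floor = 0.2, ceiling = 0.6, midpoint = 2002,
               steepness = 0)[rep(1, 3), ])
  expect_true(all(abs(flat$truth - 0.4) < 1e-12))  # midpoint value

  tp <- data.frame(floor = 0.1, ceiling = 0.8, midpoint = 2000,
                   steepness = 0.5)[rep(1, 3), ]
  early <- simulate_true_coverage(g, 1000:1001, tp)
  late <- simulate_true_coverage(g, 2999:3000, tp)
  expect_equal(max(abs(early$truth - 0.1)), 0, tolerance = 1e-9)  # -inf limit
  expect_equal(max(abs(late$truth - 0.8)), 0, tolerance = 1e-9)   # +inf limit

  tr1 <- simulate_true_coverage(g, 1990:2011, seed = 5)
  tr2 <- simulate_true_coverage(g, 1990:2011, seed = 5)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$truth > 0 & tr1$truth < 1))

  expect_error(simulate_true_coverage(g, 2000:2004,
    data.frame(floor = 0.5, ceiling = 0.4, midpoint = 2002,
               steepness = 1)[rep(1, 3), ]), "ceiling")
})

test_that("coverage observations are centred on the shifted transformed truth", {
  g <- make_region_graph(2, "line")
  tp <- data.frame(floor = 0.29, ceiling = 0.31, midpoint = 2000,
                   steepness = 0)[c(1, 1), ]
  tr <- simulate_true_coverage(g, 1999:2001, tp)

  # degenerate noise: effective n -> infinity, no shift
  big <- survey_schedule(tibble::tibble(
    source_id = "DHS", is_dhs = TRUE, years = list(2000L),
    n_eff = 1e12, shift = 0))
  obs <- simulate_coverage_observations(tr, big, seed = 3)
  expect_true(all(abs(obs$transformed_value - qlogis(0.3)) < 1e-4))
  expect_true(all(abs(obs$estimate - 0.3) < 1e-6))

  # DHS sources never receive the shift, even if one is configured
  sched <- survey_schedule(tibble::tibble(
    source_id = "DHS", is_dhs = TRUE, years = list(2000L),
    n_eff = 1e12, shift = 0.5))
  obs2 <- simulate_coverage_observations(tr, sched, seed = 3)
  expect_true(all(abs(obs2$estimate - 0.3) < 1e-6))

  # replicate observations: sample mean within 3 Monte-Carlo SEs of
  # logit(truth) + shift
  shift <- 0.4; n_eff <- 250
  rep_sched <- survey_schedule(tibble::tibble(
    source_id = sprintf("S%04d", 1:500), is_dhs = c(TRUE, rep(FALSE, 499)),
    years = list(2000L), n_eff = n_eff, shift = shift))
  obs3 <- simulate_coverage_observations(tr, rep_sched, seed = 9) |>
    dplyr::filter(!is_dhs, region == 1)
  v <- 1 / (n_eff * 0.3 * 0.7)
  mc_se <- sqrt(v / nrow(obs3))
  expect_lt(abs(mean(obs3$transformed_value) - (qlogis(0.3) + shift)), 3 * mc_se)
})

test_that("microdata reproduce the truth and carry a design effect", {
  g <- make_region_graph(2, "line")
  tp <- data.frame(floor = 0.49, ceiling = 0.51, midpoint = 2000,
                   steepness = 0)[c(1, 1), ]
  tr <- simulate_true_coverage(g, 1999:2001, tp)

  md0 <- simulate_microdata(tr, 2000, clusters_per_region = 50,
                            children_per_cluster = 30, icc = 0,
                            weight_dispersion = 0, seed = 4)
  crude <- mean(md0$covered[md0$region == 1])
  expect_lt(abs(crude - 0.5), 3 * sqrt(0.25 / 1500))

  expect_identical(md0, simulate_microdata(tr, 2000, clusters_per_region = 50,
                                           children_per_cluster = 30, icc = 0,
                                           weight_dispersion = 0, seed = 4))

  # empirical design effect over replicate fixtures exceeds 1 when the
  # intra-cluster correlation is positive
  est_var <- function(icc, seed) {
    md <- simulate_microdata(tr, 2000, clusters_per_region = 10,
                             children_per_cluster = 20, icc = icc,
                             weight_dispersion = 0, seed = seed)
    mean(md$covered[md$region == 1])
  }
  m_clu <- vapply(1:200, function(s) est_var(0.15, s), numeric(1))
  m_srs <- vapply(1:200, function(s) est_var(0, s + 1000), numeric(1))
  expect_gt(var(m_clu) / var(m_srs), 1.5)
})

test_that("birth histories honour degenerate mortality levels", {
  g <- make_region_graph(2, "line")
  base <- data.frame(midpoint = 2000, steepness = 0)

  tr0 <- simulate_true_coverage(g, 1999:2001,
    cbind(base, floor = 1e-9, ceiling = 2e-9)[c(1, 1), ],
    scale_tag = "mortality")
  tr0$truth <- 0
  bh0 <- simulate_birth_histories(tr0, n_mothers = 200, seed = 2)
  expect_equal(sum(bh0$died), 0)

  tr1 <- tr0; tr1$truth <- 1
  bh1 <- simulate_birth_histories(tr1, hazard_shape = c(1, 0, 0, 0, 0, 0, 0),
                                  n_mothers = 100, seed = 2)
  kids <- dplyr::filter(bh1, censor_age_months > 1)  # observable past month 0
  expect_true(all(kids$died))
  expect_true(all(kids$death_age_months < 1))

  # a death-share vector that does not partition the deaths is rejected
  tr9 <- tr0; tr9$truth <- 0.9
  expect_error(simulate_birth_histories(tr9,
    hazard_shape = c(0.6, 0.6, 0.05, 0, 0, 0, 0), n_mothers = 10, seed = 1))
})

test_that("mortality-model simulator matches its degenerate closed form", {
  g <- make_region_graph(4, "ring")
  yrs <- 2000:2009
  par <- list(beta0 = -1.5, beta1 = -0.05, beta2 = 0,
              tau_u = Inf, tau_v = Inf, tau_w = Inf, tau_delta = Inf,
              tau_gamma = Inf, sigma2 = 0)
  sim <- simulate_from_mortality_model(g, yrs, par, mortality_schedule(yrs),
                                       seed = 3)
  t_c <- sim$observations$year - mean(yrs)
  expect_equal(sim$observations$q5, plogis(-1.5 - 0.05 * t_c), tolerance = 1e-12)
})

test_that("drawn CAR effects satisfy constraints and the pseudo-inverse covariance", {
  g <- make_region_graph(6, "ring")
  yrs <- 2000:2005
  par <- default_mortality_params()
  sim <- simulate_from_mortality_model(g, yrs, par, mortality_schedule(yrs),
                                       seed = 8)
  expect_lt(abs(sum(sim$effects$u)), 1e-10)
  expect_lt(abs(sum(sim$effects$v)), 1e-10)
  expect_lt(abs(sum(sim$effects$w)), 1e-10)
  expect_lt(max(abs(rowSums(sim$effects$delta))), 1e-10)
  expect_lt(max(abs(colSums(sim$effects$delta))), 1e-10)

  # Monte-Carlo covariance of u vs the linear-algebra oracle: the
  # Moore-Penrose pseudo-inverse of tau * Q
  us <- vapply(1:1000, function(s) {
    simulate_from_mortality_model(g, yrs, par, mortality_schedule(yrs),
                                  seed = s)$effects$u
  }, numeric(6))
  emp <- stats::cov(t(us))
  Q <- build_icar_precision(g)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > 1e-9
  pinv <- e$vectors[, pos] %*% (t(e$vectors[, pos]) / e$values[pos]) / par$tau_u
  # elementwise MC error of a covariance entry ~ var/sqrt(draws)
  tol <- 5 * max(diag(pinv)) / sqrt(1000)
  expect_lt(max(abs(emp - pinv)), tol)
})
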