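test_that("degenerate truth is recovered on the logit scale", {
  g <- make_region_graph(6, "ring")
  yrs <- 1995:2006
  par <- list(beta0 = -1.8, beta1 = -0.04, beta2 = 0,
              tau_u = Inf, tau_v = Inf, tau_w = Inf, tau_delta = Inf,
              tau_gamma = Inf, sigma2 = 1e-4)
  sim <- simulate_from_mortality_model(g, yrs, par, mortality_schedule(yrs),
                                       seed = 2)
  fit <- suppressWarnings(fit_mortality_model(sim$observations, g, yrs,
                                              iterations = 1200, burnin = 600,
                                              chains = 2, thin = 2, seed = 3))
  med <- apply(fit$samples$theta, 2, median)
  t_c <- rep(yrs - mean(yrs), each = 6)
  truth <- -1.8 - 0.04 * t_c
  expect_lt(max(abs(med - truth)), 0.05)
})

test_that("constraints hold for every retained sample", {
  g <- make_region_graph(5, "ring")
  yrs <- 2000:2009
  sim <- simulate_from_mortality_model(g, yrs, schedule = mortality_schedule(yrs),
                                       seed = 4)
  fit <- suppressWarnings(fit_mortality_model(sim$observations, g, yrs,
                                              iterations = 400, burnin = 200,
                                              chains = 1, thin = 1, seed = 5,
                                              keep_effects = TRUE))
  expect_lt(max(abs(rowSums(fit$samples$u))), 1e-10)
  expect_lt(max(abs(rowSums(fit$samples$v))), 1e-10)
  expect_lt(max(abs(rowSums(fit$samples$w))), 1e-10)
  for (k in c(1, nrow(fit$samples$delta))) {
    dmat <- matrix(fit$samples$delta[k, ], 5, 10)
    expect_lt(max(abs(rowSums(dmat))), 1e-10)
    expect_lt(max(abs(colSums(dmat))), 1e-10)
  }
})

test_that("the sampler is deterministic and invariant to observation order", {
  g <- make_region_graph(4, "ring")
  yrs <- 2000:2007
  sim <- simulate_from_mortality_model(g, yrs, schedule = mortality_schedule(yrs),
                                       seed = 6)
  f1 <- suppressWarnings(fit_mortality_model(sim$observations, g, yrs,
                                             iterations = 300, burnin = 150,
                                             chains = 1, thin = 1, seed = 7))
  f2 <- suppressWarnings(fit_mortality_model(sim$observations, g, yrs,
                                             iterations = 300, burnin = 150,
                                             chains = 1, thin = 1, seed = 7))
  expect_identical(f1$samples$beta, f2$samples$beta)
  expect_identical(f1$samples$theta, f2$samples$theta)

  shuf <- sim$observations[sample(nrow(sim$observations)), ]
  f3 <- suppressWarnings(fit_mortality_model(shuf, g, yrs,
                                             iterations = 300, burnin = 150,
                                             chains = 1, thin = 1, seed = 7))
  expect_equal(f1$samples$theta, f3$samples$theta, tolerance = 1e-10)
})

test_that("source labels are exchangeable for the DHS-scale predictions", {
  g <- make_region_graph(4, "ring")
  yrs <- 2000:2007
  sim <- simulate_from_mortality_model(g, yrs, schedule = mortality_schedule(yrs),
                                       seed = 8)
  obs <- sim$observations
  swapped <- dplyr::mutate(obs, source = dplyr::recode(source,
                                                       AIS = "CEN", CEN = "AIS"))
  f1 <- suppressWarnings(fit_mortality_model(obs, g, yrs, iterations = 1500,
                                             burnin = 750, chains = 1,
                                             thin = 2, seed = 9))
  f2 <- suppressWarnings(fit_mortality_model(swapped, g, yrs, iterations = 1500,
                                             burnin = 750, chains = 1,
                                             thin = 2, seed = 9))
  m1 <- apply(f1$samples$theta, 2, median)
  m2 <- apply(f2$samples$theta, 2, median)
  expect_lt(max(abs(m1 - m2)), 0.06)  # equal in distribution, MC error only
})

test_that("predictions exclude the non-DHS shift and transform quantiles correctly", {
  g <- make_region_graph(6, "ring")
  yrs <- 1995:2006
  par <- default_mortality_params()  # beta2 = 0.3
  sim <- simulate_from_mortality_model(g, yrs, par, mortality_schedule(yrs),
                                       seed = 10)
  fit <- suppressWarnings(fit_mortality_model(sim$observations, g, yrs,
                                              iterations = 1500, burnin = 750,
                                              chains = 2, thin = 2, seed = 11))
  pred <- predict(fit)
  truth <- plogis(as.vector(sim$theta_grid))
  grid_truth <- tibble::tibble(region = rep(1:6, times = 12),
                               year = rep(yrs, each = 6),
                               truth = truth)
  cmp <- dplyr::left_join(pred, grid_truth, by = c("region", "year"))
  # shifted-source mean (what a naive average would track)
  shifted <- dplyr::summarise(
    dplyr::group_by(sim$observations, region, year),
    m = mean(q5), .groups = "drop") |>
    dplyr::left_join(grid_truth, by = c("region", "year"))
  bias_truth <- mean(abs(cmp$q5 - cmp$truth))
  bias_shifted <- mean(abs(cmp$q5 - (shifted$m[match(paste(cmp$region, cmp$year),
                                       paste(shifted$region, shifted$year))])))
  expect_lt(bias_truth, bias_shifted)

  # quantile-then-transform equals transform-then-quantile
  one <- predict_5q0(fit, 3, 2000)
  cols <- (match(2000, yrs) - 1) * 6 + 3
  th <- fit$samples$theta[, cols]
  expect_equal(one$q5, plogis(median(th)))
  expect_equal(one$lower, plogis(quantile(th, 0.025, names = FALSE)))

  # inverse-logit of all-zero samples is exactly one half
  fit0 <- fit
  fit0$samples$theta[] <- 0
  p0 <- predict_5q0(fit0, 1, yrs[1])
  expect_equal(unlist(p0[, c("q5", "lower", "upper")], use.names = FALSE),
               rep(0.5, 3))
})

test_that("tidy and glance summarise the fit", {
  g <- make_region_graph(4, "ring")
  yrs <- 2000:2005
  sim <- simulate_from_mortality_model(g, yrs, schedule = mortality_schedule(yrs),
                                       seed = 12)
  fit <- suppressWarnings(fit_mortality_model(sim$observations, g, yrs,
                                              iterations = 300, burnin = 150,
                                              chains = 2, thin = 1, seed = 13))
  td <- tidy(fit)
  expect_setequal(td$term, c("beta0", "beta1", "beta2", "sigma2", "tau_u",
                             "tau_v", "tau_w", "tau_delta", "tau_gamma"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$chains, 2)
  expect_equal(gl$n_obs, nrow(sim$observations))
})

test_that("invalid inputs are rejected", {
  g <- make_region_graph(3, "ring")
  obs <- tibble::tibble(region = c(1, 5), year = c(2000L, 2001L),
                        source = "DHS", is_dhs = TRUE, logit_q5 = c(-1, -1))
  expect_error(fit_mortality_model(obs, g, 2000:2005, iterations = 10),
               "absent from the graph")
  obs2 <- tibble::tibble(region = 1, year = 2000L, source = "DHS",
                         is_dhs = TRUE, q5 = 1.2)
  expect_error(fit_mortality_model(obs2, g, 2000:2005, iterations = 10),
               "strictly")
})
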