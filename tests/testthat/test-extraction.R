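test_that("weighted coverage handles boundary and single-cluster cases", {
  d <- tibble::tibble(region = 1, cluster = rep(1:4, each = 3),
                      weight = runif(12, 0.5, 2), covered = 1,
                      age_months = 24)
  res <- weighted_coverage(d)
  expect_equal(res$estimate, 1)
  expect_equal(res$se, 0)

  d2 <- tibble::tibble(region = 1, cluster = 1, weight = 1,
                       covered = c(1, 1, 1, 0, 0, 0), age_months = 24)
  expect_equal(weighted_coverage(d2)$estimate, 0.5)
})

test_that("design-based SE matches the independent Taylor oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:10) {
    n_cl <- 20
    per <- sample(5:15, n_cl, replace = TRUE)
    d <- tibble::tibble(
      region = 1,
      cluster = rep(seq_len(n_cl), per),
      weight = rexp(sum(per)) + 0.1,
      covered = rbinom(sum(per), 1, runif(1, 0.2, 0.8)),
      age_months = runif(sum(per), 0, 59)
    )
    res <- weighted_coverage(d)
    expect_equal(res$se, taylor_se_oracle(d$covered, d$weight, d$cluster),
                 tolerance = 1e-12)
  }
})

test_that("weighted coverage is invariant to weight rescaling and flags empty cells", {
  d <- small_microdata()
  r1 <- weighted_coverage(d)
  r2 <- weighted_coverage(dplyr::mutate(d, weight = weight * 7.3))
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)

  # age window excludes everything -> flagged missing, no error
  def <- indicator_definition("measles", age_window = c(500, 600))
  res <- weighted_coverage(d, def)
  expect_true(all(res$missing))
  expect_true(all(is.na(res$estimate)))
})

test_that("indicator definitions apply age windows and predicates first", {
  d <- tibble::tibble(region = 1, cluster = rep(1:2, each = 4), weight = 1,
                      covered = c(1, 1, 1, 1, 0, 0, 0, 0),
                      age_months = c(6, 18, 30, 70, 6, 18, 30, 70))
  def <- indicator_definition("measles", age_window = c(12, 60))
  res <- weighted_coverage(d, def)
  expect_equal(res$n, 4L)           # ages 18 and 30 in both clusters
  expect_equal(res$estimate, 0.5)
})

test_that("transforms carry delta-method variances and invert exactly", {
  r <- transform_observation(data.frame(estimate = 0.5, se = 0.05, n_eff = 100))
  expect_equal(r$transformed_value, 0)
  expect_equal(sqrt(r$transformed_variance), 0.2)  # 0.05 / (0.5 * 0.5)

  r2 <- transform_observation(data.frame(estimate = 1, se = 0.1, n_eff = 100),
                              scale = "positive")
  expect_equal(r2$transformed_value, 0)

  # round trip on the point estimate
  p <- c(0.05, 0.31, 0.5, 0.77, 0.99)
  rt <- transform_observation(data.frame(estimate = p, se = 0.01, n_eff = 1e6))
  expect_equal(back_transform(rt$transformed_value), p, tolerance = 1e-12)

  # zero SE with no effective n is rejected; with n_eff it falls back
  expect_error(transform_observation(
    data.frame(estimate = 0.4, se = 0, n_eff = NA_real_)), "effective sample size")
  ok <- transform_observation(data.frame(estimate = 0.4, se = 0, n_eff = 400))
  expect_equal(ok$transformed_variance, (0.4 * 0.6 / 400) / (0.4 * 0.6)^2)
})

test_that("back-transformed observation draws reproduce the natural-scale mean", {
  set.seed(3)
  p <- 0.3; n_eff <- 800
  tr <- transform_observation(data.frame(estimate = p, se = sqrt(p * (1 - p) / n_eff),
                                         n_eff = n_eff))
  draws <- plogis(rnorm(2e5, tr$transformed_value, sqrt(tr$transformed_variance)))
  # delta-method consistency: MC mean near p within 3 MC SEs + O(var) bias
  expect_lt(abs(mean(draws) - p), 3 * sd(draws) / sqrt(2e5) + 0.25 * tr$transformed_variance)
})

test_that("variance imputation uses the same-indicator 90th percentile", {
  obs <- tibble::tibble(indicator = rep(c("a", "b"), each = 5),
                        transformed_variance = c(1:4, NA, 11:14, NA))
  out <- impute_transformed_variance(obs)
  expect_equal(out$transformed_variance[5], quantile(1:4, 0.9, names = FALSE))
  expect_equal(out$transformed_variance[10], quantile(11:14, 0.9, names = FALSE))
  expect_equal(sum(out$variance_imputed), 2)
})

test_that("observation tables round-trip through the documented CSV header", {
  g <- make_region_graph(3, "ring")
  tr <- simulate_true_coverage(g, 2000:2005, seed = 2)
  obs <- simulate_coverage_observations(tr, recovery_schedule() |>
    dplyr::filter(year %in% 2000:2005), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(as.data.frame(back), as.data.frame(obs), tolerance = 1e-12)
})
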