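index_fixture <- function(values, year = 2011, region = 1) {
  comps <- index_components()
  tibble::tibble(indicator = comps, region = region, year = year,
                 point = values)
}

test_that("the index is the equal-weight mean with underweight complemented", {
  # all components at 0.64 (underweight prevalence 0.36 so its complement
  # is also 0.64)
  vals <- rep(0.64, 11); vals[11] <- 0.36
  expect_equal(overall_coverage(index_fixture(vals))$index, 0.64)

  # ten components at zero, underweight prevalence 0 -> complement 1
  vals2 <- rep(0, 11)
  expect_equal(overall_coverage(index_fixture(vals2))$index, 1 / 11)

  set.seed(9)
  vals3 <- runif(11)
  got <- overall_coverage(index_fixture(vals3))$index
  manual <- 0
  comp <- ifelse(index_components() == "underweight", 1 - vals3, vals3)
  for (x in comp) manual <- manual + x
  expect_equal(got, manual / 11, tolerance = 1e-15)
  expect_gte(got, min(comp)); expect_lte(got, max(comp))
})

test_that("the index is permutation-invariant and shifts with constants", {
  set.seed(10)
  vals <- runif(11, 0.1, 0.8)
  fx <- index_fixture(vals)
  shuffled <- fx[sample(11), ]
  expect_equal(overall_coverage(fx)$index, overall_coverage(shuffled)$index)

  # adding c to every component value (complement included) adds c
  fx2 <- dplyr::mutate(fx, point = ifelse(indicator == "underweight",
                                          point - 0.05, point + 0.05))
  expect_equal(overall_coverage(fx2)$index,
               overall_coverage(fx)$index + 0.05, tolerance = 1e-12)
})

test_that("region-years missing a component are dropped, not imputed", {
  fx <- dplyr::bind_rows(index_fixture(runif(11), region = 1),
                         index_fixture(runif(11), region = 2)[-3, ])
  out <- overall_coverage(fx)
  expect_equal(out$region, 1)
  expect_equal(attr(out, "dropped")$region, 2)
})

test_that("index uncertainty combines matched draws and is bounded by components", {
  g <- make_region_graph(3, "ring")
  yrs <- 2000:2006
  obs <- dplyr::bind_rows(lapply(index_components(), function(ind) {
    tr <- simulate_true_coverage(g, yrs, seed = child_seed(3, ind))
    simulate_coverage_observations(tr, recovery_schedule() |>
      dplyr::filter(year %in% yrs), indicator_id = ind,
      seed = child_seed(4, ind))
  }))
  # tiny fixture: the mixed model legitimately falls back to fixed effects
  fit <- suppressWarnings(run_coverage_pipeline(obs, years = yrs, seed = 5,
                                                keep_draws = TRUE))
  idx <- index_uncertainty(fit, 2)
  expect_equal(nrow(idx), length(yrs))
  expect_true(all(idx$lower <= idx$point & idx$point <= idx$upper))

  dr <- attr(idx, "draws")
  comp_mats <- lapply(index_components(), function(ind) {
    m <- fit$draws[[ind]][["2"]]
    if (ind == "underweight") 1 - m else m
  })
  lo <- Reduce(pmin, comp_mats); hi <- Reduce(pmax, comp_mats)
  expect_true(all(dr >= lo - 1e-12 & dr <= hi + 1e-12))
  # variance of an equal-weight mean cannot exceed the largest component
  # variance (components here are near-independent posteriors)
  expect_lt(max(apply(dr, 2, var)),
            max(vapply(comp_mats, function(m) max(apply(m, 2, var)), numeric(1))) + 1e-12)

  fit_nodraws <- suppressWarnings(run_coverage_pipeline(obs, years = yrs, seed = 5))
  expect_error(index_uncertainty(fit_nodraws, 2), "keep_draws")
})

test_that("pearson correlation matches its formula and affine invariances", {
  a <- tibble::tibble(region = 1, year = 1:10, x = rnorm(10))
  b <- dplyr::mutate(a, x = 2 * x + 1)
  expect_equal(pearson_correlation(a, b)$rho, 1)
  expect_equal(pearson_correlation(a, dplyr::mutate(a, x = -x))$rho, -1)

  set.seed(12)
  s1 <- tibble::tibble(region = rep(1:5, each = 10), year = rep(1:10, 5),
                       x = rnorm(50))
  s2 <- tibble::tibble(region = rep(1:5, each = 10), year = rep(1:10, 5),
                       y = rnorm(50))
  got <- pearson_correlation(s1, s2)
  d <- dplyr::inner_join(s1, s2, by = c("region", "year"))
  num <- sum((d$x - mean(d$x)) * (d$y - mean(d$y)))
  den <- sqrt(sum((d$x - mean(d$x))^2)) * sqrt(sum((d$y - mean(d$y))^2))
  expect_equal(got$rho, num / den, tolerance = 1e-12)
  expect_equal(got$n, 50)

  # positive affine transform leaves rho; negative slope flips its sign
  expect_equal(pearson_correlation(dplyr::mutate(s1, x = 3 * x + 2), s2)$rho,
               got$rho, tolerance = 1e-12)
  expect_equal(pearson_correlation(dplyr::mutate(s1, x = -3 * x), s2)$rho,
               -got$rho, tolerance = 1e-12)

  expect_error(pearson_correlation(a[1:2, ], b[1:2, ]), "3 paired")
  expect_warning(pearson_correlation(dplyr::mutate(a, x = 1), b), "zero variance")
})

test_that("a mortality series generated from coverage recovers a negative correlation", {
  set.seed(33)
  g <- make_region_graph(10, "grid", grid_rows = 2)
  world_cov <- true_overall_coverage(list(
    truth = setNames(lapply(index_components(), function(ind) {
      simulate_true_coverage(g, 1990:2011, seed = child_seed(7, ind))
    }), index_components())))
  rho_gen <- -0.9
  x <- scale(world_cov$index)[, 1]
  noise <- rnorm(length(x))
  noise <- residuals(lm(noise ~ x))
  y <- rho_gen * x + sqrt(1 - rho_gen^2) * scale(noise)[, 1]
  mort <- dplyr::mutate(world_cov, q5 = y)
  got <- pearson_correlation(world_cov, mort, value_a = "index", value_b = "q5")
  expect_lt(got$rho, 0)
  mc_se <- (1 - rho_gen^2) / sqrt(nrow(world_cov) - 3)
  expect_lt(abs(got$rho - rho_gen), 3 * mc_se + 1e-6)
})

test_that("league tables rank regions within year", {
  d <- tibble::tibble(region = rep(1:3, 2), year = rep(c(2000, 2001), each = 3),
                      index = c(0.5, 0.7, 0.6, 0.4, 0.4, 0.9))
  lt <- league_table(d)
  expect_equal(lt$rank[lt$year == 2000], c(1, 2, 3))
  expect_equal(lt$region[lt$year == 2000], c(2, 3, 1))
  expect_equal(lt$rank[lt$year == 2001], c(1, 2, 2))
})
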