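#' Simulate a true coverage surface
#'
#' Generates the region x year grid of true indicator values that the
#' survey simulators observe with error and that recovery experiments
#' compare estimates against. Each region follows a four-parameter
#' logistic trend
#' `floor + (ceiling - floor) / (1 + exp(-steepness * (year - midpoint)))`,
#' the canonical shape for intervention scale-up: flat near a historical
#' floor, an adoption ramp around a midpoint year, saturation below a
#' ceiling. Values are strictly inside `(floor, ceiling)`, hence inside
#' `(0, 1)` for proportions.
#'
#' @param graph A `region_graph`; one trend per region.
#' @param years Integer vector of consecutive years (the estimation grid).
#' @param trend_params Data frame with one row per region and columns
#'   `floor`, `ceiling`, `midpoint`, `steepness`. If `NULL`, region
#'   parameters are drawn reproducibly from `seed`: floors in
#'   `[0.05, 0.25]`, ceilings in `[0.55, 0.9]`, midpoints in the middle
#'   three-fifths of the year range, steepness in `[0.15, 0.45]` per year.
#' @param seed Integer seed (used only when `trend_params` is `NULL`).
#' @param scale_tag `"proportion"`, `"positive"`, or `"mortality"`.
#' @return A tibble (`region`, `year`, `truth`) with attribute
#'   `scale_tag`, class `true_surface`.
#' @export
#' @examples
#' g <- make_region_graph(4, "ring")
#' tr <- simulate_true_coverage(g, 1990:2011, seed = 1)
#' dplyr::glimpse(tr)
simulate_true_coverage <- function(graph, years, trend_params = NULL, seed = 1,
                                   scale_tag = "proportion") {
  stopifnot(inherits(graph, "region_graph"))
  years <- as.integer(years)
  stopifnot(all(diff(years) == 1L))
  n <- n_regions(graph)
  if (is.null(trend_params)) {
    trend_params <- with_seed(child_seed(seed, "trend_params"), {
      tibble::tibble(
        region = seq_len(n),
        floor = runif(n, 0.05, 0.25),
        ceiling = runif(n, 0.55, 0.90),
        midpoint = runif(n, quantile(years, 0.2), quantile(years, 0.8)),
        steepness = runif(n, 0.15, 0.45)
      )
    })
  }
  trend_params <- tibble::as_tibble(trend_params)
  assert_df_has(trend_params, c("floor", "ceiling", "midpoint", "steepness"),
                "trend_params")
  stopifnot(nrow(trend_params) == n)
  if (!"region" %in% names(trend_params)) trend_params$region <- seq_len(n)
  if (any(trend_params$ceiling <= trend_params$floor)) {
    rlang::abort("trend ceiling must exceed floor for every region")
  }
  if (scale_tag != "positive" &&
      (any(trend_params$floor <= 0) || any(trend_params$ceiling >= 1))) {
    rlang::abort("floors and ceilings must lie in (0, 1)")
  }
  out <- tidyr::crossing(region = seq_len(n), year = years) |>
    dplyr::left_join(trend_params, by = "region") |>
    dplyr::mutate(truth = .data$floor + (.data$ceiling - .data$floor) *
                    inv_logit(.data$steepness * (.data$year - .data$midpoint))) |>
    dplyr::select("region", "year", "truth")
  attr(out, "scale_tag") <- scale_tag
  class(out) <- c("true_surface", class(out))
  out
}

#' Define a multi-source survey schedule
#'
#' Describes which sources observed which years, with what effective
#' sample size, and whether each source is of the reference (DHS-style)
#' family. Non-reference sources carry a systematic additive shift on the
#' transformed (logit/log) scale, emulating the level discrepancy between
#' survey families that the models must adjust for.
#'
#' @param sources Data frame with columns `source_id`, `is_dhs`,
#'   `years` (list-column of integer vectors), `n_eff`, and `shift`
#'   (transformed-scale additive shift; forced to 0 for DHS sources).
#' @return A long tibble (`source_id`, `is_dhs`, `year`, `n_eff`,
#'   `shift`), class `survey_schedule`.
#' @export
#' @examples
#' sched <- survey_schedule(data.frame(
#'   source_id = c("DHS", "NHS"), is_dhs = c(TRUE, FALSE),
#'   years = I(list(c(1995, 2000, 2006, 2011), c(1999, 2005, 2009))),
#'   n_eff = c(1000, 600), shift = c(0, 0.15)))
survey_schedule <- function(sources) {
  sources <- tibble::as_tibble(sources)
  assert_df_has(sources, c("source_id", "is_dhs", "years", "n_eff", "shift"),
                "sources")
  if (!any(sources$is_dhs)) rlang::abort("at least one DHS-flagged source is required")
  if (any(sources$n_eff <= 0)) rlang::abort("effective sample sizes must be positive")
  out <- sources |>
    dplyr::mutate(shift = ifelse(.data$is_dhs, 0, .data$shift)) |>
    tidyr::unnest_longer(col = "years", values_to = "year") |>
    dplyr::mutate(year = as.integer(.data$year)) |>
    dplyr::select("source_id", "is_dhs", "year", "n_eff", "shift")
  class(out) <- c("survey_schedule", class(out))
  out
}

#' Default demonstration survey schedule
#'
#' Four DHS-style rounds, one malaria-survey round and one national
#' household survey family (non-DHS, shifted), mirroring the cadence of a
#' typical two-decade multi-source record: a handful of survey-years per
#' indicator rather than annual data.
#'
#' @param shift Transformed-scale shift applied to non-DHS sources.
#' @param n_eff_dhs,n_eff_other Per-observation effective sample sizes.
#' @return A `survey_schedule` tibble.
#' @export
default_survey_schedule <- function(shift = 0.15, n_eff_dhs = 1000, n_eff_other = 600) {
  survey_schedule(tibble::tibble(
    source_id = c("DHS", "MIS", "NHS"),
    is_dhs = c(TRUE, TRUE, FALSE),
    years = list(c(1995L, 2000L, 2006L, 2011L), 2009L, c(1999L, 2005L, 2009L)),
    n_eff = c(n_eff_dhs, n_eff_dhs, n_eff_other),
    shift = c(0, 0, shift)
  ))
}

#' Simulate source-specific coverage observations
#'
#' Draws region-year-source survey estimates around the true surface:
#' on the transformed scale each observation is
#' `N(g(truth) + shift * (1 - is_dhs), v)` with sampling variance `v`
#' consistent with the source's effective sample size (for proportions,
#' the delta-method binomial variance `1 / (n_eff * p * (1 - p))`; for
#' positive indicators, `1 / n_eff` on the log scale). The transformed
#' variance is recorded with each observation, as the smoothing models
#' require.
#'
#' @param truth A `true_surface` tibble.
#' @param schedule A `survey_schedule` tibble.
#' @param indicator_id Label stored in the `indicator` column.
#' @param seed Integer seed.
#' @return An observation tibble with columns `region`, `year`, `source`,
#'   `is_dhs`, `indicator`, `estimate`, `se`, `transformed_value`,
#'   `transformed_variance`, `n_eff`.
#' @export
simulate_coverage_observations <- function(truth, schedule, indicator_id = "ind",
                                           seed = 1) {
  scale_tag <- attr(truth, "scale_tag") %||% "proportion"
  stopifnot(all(schedule$year %in% truth$year))
  obs <- tidyr::crossing(region = unique(truth$region),
                         dplyr::as_tibble(schedule)) |>
    dplyr::left_join(tibble::as_tibble(truth), by = c("region", "year"))
  g <- if (scale_tag == "positive") log else logit
  ginv <- if (scale_tag == "positive") exp else inv_logit
  v <- if (scale_tag == "positive") 1 / obs$n_eff
       else 1 / (obs$n_eff * obs$truth * (1 - obs$truth))
  z <- with_seed(child_seed(seed, paste0("coverage_obs:", indicator_id)), {
    rnorm(nrow(obs), mean = g(obs$truth) + obs$shift * (1 - obs$is_dhs), sd = sqrt(v))
  })
  est <- ginv(z)
  se_nat <- if (scale_tag == "positive") sqrt(v) * est else sqrt(v) * est * (1 - est)
  tibble::tibble(
    region = obs$region, year = obs$year, source = obs$source_id,
    is_dhs = obs$is_dhs, indicator = indicator_id,
    estimate = est, se = se_nat,
    transformed_value = z, transformed_variance = v, n_eff = obs$n_eff
  ) |>
    dplyr::arrange(.data$indicator, .data$region, .data$year, .data$source)
}

#' Simulate clustered survey microdata for one indicator
#'
#' Emulates a complex multistage sample: clusters (primary sampling
#' units) within each region, children within clusters, unequal sampling
#' weights, and a cluster-level random effect inducing intra-cluster
#' correlation. Cluster-level coverage probabilities are drawn from a
#' Beta distribution with mean equal to the regional truth (concentration
#' `(1 - icc) / icc`), so the weighted population mean converges to the
#' truth while the design effect exceeds 1 whenever `icc > 0`.
#'
#' @param truth A `true_surface` tibble.
#' @param year Survey year (must be on the truth grid).
#' @param clusters_per_region,children_per_cluster Design counts.
#' @param icc Intra-cluster correlation of the binary indicator in
#'   `[0, 1)`; 0 gives independent children.
#' @param weight_dispersion Standard deviation of log sampling weights
#'   (weights are lognormal, mean 1); 0 gives equal weights.
#' @param age_range_months Children's ages are uniform on this range.
#' @param seed Integer seed.
#' @return A tibble of child records: `region`, `cluster`, `child`,
#'   `weight`, `age_months`, `covered`.
#' @export
simulate_microdata <- function(truth, year,
                               clusters_per_region = 30,
                               children_per_cluster = 20,
                               icc = 0.05,
                               weight_dispersion = 0.3,
                               age_range_months = c(0, 59),
                               seed = 1) {
  stopifnot(clusters_per_region >= 1, children_per_cluster >= 1,
            icc >= 0, icc < 1, year %in% truth$year)
  tr <- dplyr::filter(tibble::as_tibble(truth), .data$year == !!year)
  with_seed(child_seed(seed, paste0("microdata:", year)), {
    purrr::map_dfr(seq_len(nrow(tr)), function(r) {
      p <- tr$truth[r]
      p_c <- if (icc == 0) rep(p, clusters_per_region) else {
        phi <- (1 - icc) / icc
        rbeta(clusters_per_region, p * phi, (1 - p) * phi)
      }
      nc <- clusters_per_region * children_per_cluster
      cl <- rep(seq_len(clusters_per_region), each = children_per_cluster)
      w <- if (weight_dispersion == 0) rep(1, nc) else
        exp(rnorm(nc, -weight_dispersion^2 / 2, weight_dispersion))
      tibble::tibble(
        region = tr$region[r],
        cluster = cl,
        child = seq_len(nc),
        weight = w,
        age_months = runif(nc, age_range_months[1], age_range_months[2] + 1),
        covered = as.integer(runif(nc) < p_c[cl])
      )
    })
  })
}
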