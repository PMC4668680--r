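#' Default age segmentation for under-5 hazards
#'
#' Age-segment boundaries in months, `{0, 1, 6, 12, 24, 36, 48, 60}`,
#' giving the segments 0, 1-5, 6-11, 12-23, 24-35, 36-47 and 48-59
#' months — the synthetic-cohort convention for direct under-5 mortality
#' estimation from complete birth histories.
#'
#' @return Integer vector of 8 segment boundaries.
#' @export
default_age_segments <- function() c(0L, 1L, 6L, 12L, 24L, 36L, 48L, 60L)

# Convert a cohort 5q0 and a vector of death-share proportions per age
# segment into per-segment conditional death probabilities q_a and
# constant monthly hazards m_a. shape sums to 1; the unconditional
# probability of dying in segment a is q5 * shape[a].
segment_hazards <- function(q5, hazard_shape, age_segments) {
  stopifnot(abs(sum(hazard_shape) - 1) < 1e-8,
            length(hazard_shape) == length(age_segments) - 1)
  widths <- diff(age_segments)
  surv <- 1 - q5 * c(0, cumsum(hazard_shape)[-length(hazard_shape)])
  q_a <- ifelse(surv <= 0, 0, (q5 * hazard_shape) / surv)  # extinct cohort: moot
  if (any(q_a > 1 + 1e-12)) {
    rlang::abort("infeasible hazard_shape: implied segment death probability exceeds 1")
  }
  q_a <- pmin(q_a, 1)
  m_a <- ifelse(q_a >= 1, Inf, -log(1 - q_a) / widths)
  list(q = q_a, m = m_a, widths = widths)
}

#' Simulate complete birth histories
#'
#' Generates per-child birth records under piecewise-constant
#' age-specific hazards solved so that the implied cohort 5q0 of a child
#' born in region `i`, year `t` equals the supplied true surface value.
#' Births are spread uniformly over the year grid; children are censored
#' at a simulated survey date. The output feeds `direct_5q0()`.
#'
#' @param truth A `true_surface` with `scale_tag = "mortality"`
#'   (`truth` = cohort 5q0 by region and birth year).
#' @param hazard_shape Proportion of under-5 deaths falling in each age
#'   segment; must sum to 1 and have one entry per segment.
#' @param n_mothers Mothers per region.
#' @param births_per_mother Children are assigned uniformly among
#'   1..`births_per_mother` per mother.
#' @param survey_date Decimal year at which histories are collected;
#'   defaults to one half-year after the end of the truth grid.
#' @param age_segments Segment boundaries in months (see
#'   [default_age_segments()]).
#' @param weight_dispersion SD of log sampling weights (lognormal, mean 1).
#' @param seed Integer seed.
#' @return A tibble of birth records: `region`, `mother_id`, `child_id`,
#'   `birth_date` (decimal year), `weight`, `died` (death observed before
#'   censoring), `death_age_months` (NA if censored before death),
#'   `censor_age_months` (= survey date minus birth date, in months).
#' @export
#' @examples
#' g <- make_region_graph(2, "line")
#' tr <- simulate_true_coverage(g, 2000:2005,
#'   trend_params = data.frame(floor = 0.08, ceiling = 0.2,
#'                             midpoint = 2002, steepness = -0.3)[c(1, 1), ],
#'   scale_tag = "mortality")
#' bh <- simulate_birth_histories(tr, n_mothers = 50, seed = 2)
simulate_birth_histories <- function(truth,
                                     hazard_shape = c(0.30, 0.17, 0.13, 0.18, 0.12, 0.06, 0.04),
                                     n_mothers = 1000,
                                     births_per_mother = 3,
                                     survey_date = NULL,
                                     age_segments = default_age_segments(),
                                     weight_dispersion = 0,
                                     seed = 1) {
  truth <- tibble::as_tibble(truth)
  years <- sort(unique(truth$year))
  survey_date <- survey_date %||% (max(years) + 1.5)
  regions <- unique(truth$region)
  n_seg <- length(age_segments) - 1
  stopifnot(length(hazard_shape) == n_seg, n_mothers >= 1)

  with_seed(child_seed(seed, "birth_histories"), {
    purrr::map_dfr(regions, function(r) {
      tr_r <- dplyr::filter(truth, .data$region == r)
      n_b <- sample.int(births_per_mother, n_mothers, replace = TRUE)
      mother <- rep(seq_len(n_mothers), n_b)
      n_children <- length(mother)
      birth_date <- runif(n_children, min(years), max(years) + 1)
      birth_year <- pmin(floor(birth_date), max(years))
      q5 <- tr_r$truth[match(birth_year, tr_r$year)]
      w_m <- if (weight_dispersion == 0) rep(1, n_mothers) else
        exp(rnorm(n_mothers, -weight_dispersion^2 / 2, weight_dispersion))
      death_age <- vapply(q5, function(q) draw_death_age(q, hazard_shape, age_segments),
                          numeric(1))
      censor_age <- pmax((survey_date - birth_date) * 12, 0)
      died <- !is.na(death_age) & death_age < censor_age
      tibble::tibble(
        region = r,
        mother_id = mother,
        child_id = seq_len(n_children),
        birth_date = birth_date,
        weight = w_m[mother],
        died = died,
        death_age_months = ifelse(died, death_age, NA_real_),
        censor_age_months = censor_age
      )
    })
  })
}

# Draw an under-5 death age in months (NA = survives to 60 months) under
# piecewise-constant hazards calibrated to cohort probability q5.
draw_death_age <- function(q5, hazard_shape, age_segments) {
  if (q5 <= 0) return(NA_real_)
  hz <- segment_hazards(q5, hazard_shape, age_segments)
  for (a in seq_along(hz$q)) {
    if (runif(1) < hz$q[a]) {
      if (!is.finite(hz$m[a])) return(age_segments[a])
      u <- runif(1)
      t_in <- -log(1 - u * (1 - exp(-hz$m[a] * hz$widths[a]))) / hz$m[a]
      return(age_segments[a] + t_in)
    }
  }
  NA_real_
}
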