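#' Simulate a complete multi-indicator benchmarking study
#'
#' Builds the full synthetic world the end-to-end driver and the
#' recovery experiments run on: true logistic scale-up surfaces for the
#' 11 overall-coverage component indicators (underweight declining, the
#' others rising at indicator-specific floors, ceilings and midpoints),
#' a positive-scale socioeconomic series (mean years of maternal
#' education), multi-source survey observations of each under the given
#' schedule, and mortality observations drawn from the hierarchical
#' spatiotemporal model.
#'
#' @param graph A `region_graph` (default [default_region_graph()]).
#' @param years Year grid (default 1990:2011).
#' @param schedule A `survey_schedule` (default
#'   [default_survey_schedule()]).
#' @param mortality_params Generating parameters for the mortality
#'   simulator (default [default_mortality_params()]).
#' @param seed Master seed; every component uses a derived stream.
#' @return A list: `observations` (coverage observation tibble for all
#'   12 indicators), `mortality_observations`, `truth` (named list of
#'   `true_surface` tibbles), `mortality_truth` (region x year matrix of
#'   true logit 5q0 on the DHS scale), `graph`, `years`, `scales`
#'   (named vector of indicator scales).
#' @export
#' @examples
#' world <- simulate_study(make_region_graph(4, "ring"), 1990:1999, seed = 7)
#' dplyr::count(world$observations, indicator)
simulate_study <- function(graph = default_region_graph(), years = 1990:2011,
                           schedule = default_survey_schedule(),
                           mortality_params = default_mortality_params(),
                           seed = 1) {
  n <- n_regions(graph)
  y0 <- min(years); y1 <- max(years)
  schedule <- dplyr::filter(tibble::as_tibble(schedule), .data$year %in% years)
  if (nrow(schedule) == 0) rlang::abort("no schedule years fall on the year grid")
  # indicator-level trend envelopes: lo/hi coverage range and scale-up window
  profiles <- tibble::tribble(
    ~indicator,    ~lo,   ~hi,  ~mid_frac, ~steep, ~direction,
    "itn_or_irs",  0.02, 0.75,  0.75,      0.55,   1,
    "iptp2",       0.02, 0.40,  0.70,      0.35,   1,
    "act",         0.02, 0.60,  0.80,      0.60,   1,
    "ebf",         0.40, 0.70,  0.50,      0.15,   1,
    "bcg",         0.70, 0.95,  0.40,      0.20,   1,
    "measles",     0.55, 0.88,  0.45,      0.18,   1,
    "opv3",        0.55, 0.78,  0.30,      0.10,   1,
    "pentavalent", 0.03, 0.80,  0.70,      0.70,   1,
    "anc4",        0.35, 0.55,  0.50,      0.10,   1,
    "sba",         0.35, 0.70,  0.60,      0.20,   1,
    "underweight", 0.12, 0.28,  0.50,      0.18,  -1
  )
  truth <- list()
  obs <- list()
  scales <- c(setNames(rep("proportion", nrow(profiles)), profiles$indicator),
              edu_years = "positive")
  for (k in seq_len(nrow(profiles))) {
    pr <- profiles[k, ]
    sd_k <- child_seed(seed, paste0("truth:", pr$indicator))
    tp <- with_seed(sd_k, tibble::tibble(
      floor = pmax(0.005, pr$lo * runif(n, 0.7, 1.3)),
      ceiling = pmin(0.995, pr$hi * runif(n, 0.85, 1.1)),
      midpoint = y0 + (y1 - y0) * pmin(0.95, pmax(0.05, pr$mid_frac * runif(n, 0.85, 1.15))),
      steepness = pr$direction * pr$steep * runif(n, 0.8, 1.2)
    ))
    # high-baseline indicators can draw floor/ceiling out of order
    tp$floor <- pmin(tp$floor, tp$ceiling - 0.03)
    truth[[pr$indicator]] <- simulate_true_coverage(graph, years, tp)
    obs[[pr$indicator]] <- simulate_coverage_observations(
      truth[[pr$indicator]], schedule, indicator_id = pr$indicator,
      seed = child_seed(seed, paste0("obs:", pr$indicator)))
  }
  # socioeconomic series: mean years of maternal education (positive scale)
  tp_edu <- with_seed(child_seed(seed, "truth:edu_years"), tibble::tibble(
    floor = runif(n, 1.5, 3), ceiling = runif(n, 5, 8),
    midpoint = runif(n, 1998, 2006), steepness = runif(n, 0.12, 0.3)))
  truth$edu_years <- simulate_true_coverage(graph, years, tp_edu,
                                            scale_tag = "positive")
  obs$edu_years <- simulate_coverage_observations(
    truth$edu_years, schedule, indicator_id = "edu_years",
    seed = child_seed(seed, "obs:edu_years"))

  mort <- simulate_from_mortality_model(graph, years, mortality_params,
                                        schedule,
                                        seed = child_seed(seed, "mortality"))
  list(observations = dplyr::bind_rows(obs),
       mortality_observations = mort$observations,
       truth = truth,
       mortality_truth = mort$theta_grid,
       mortality_effects = mort$effects,
       graph = graph, years = years, scales = scales)
}

#' True overall coverage index of a synthetic world
#'
#' Convenience for recovery experiments: the equal-weight mean of the 11
#' true component surfaces (underweight complemented), per region-year.
#'
#' @param world A [simulate_study()] result.
#' @return Tibble (`region`, `year`, `index`).
#' @export
true_overall_coverage <- function(world) {
  comp <- index_components()
  d <- dplyr::bind_rows(lapply(comp, function(ind) {
    dplyr::mutate(tibble::as_tibble(world$truth[[ind]]), indicator = ind)
  }))
  d |>
    dplyr::mutate(value = ifelse(.data$indicator %in% complemented_components(),
                                 1 - .data$truth, .data$truth)) |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::summarise(index = mean(.data$value), .groups = "drop")
}
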