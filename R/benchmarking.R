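#' Component indicators of the overall coverage index
#'
#' The 11 equal-weight components of the overall intervention coverage
#' index, spanning malaria control (vector control by ITN ownership or
#' IRS; IPTp2; ACT receipt), immunization (BCG, measles, OPV3,
#' pentavalent), maternal services (ANC4, skilled birth attendance),
#' child feeding (exclusive breastfeeding), and nutrition status
#' (underweight prevalence, which enters the index as its complement:
#' the proportion of children *not* underweight).
#'
#' @return Character vector of 11 indicator ids.
#' @export
index_components <- function() {
  c("itn_or_irs", "iptp2", "act", "ebf", "bcg", "measles", "opv3",
    "pentavalent", "anc4", "sba", "underweight")
}

# Indicators whose index contribution is 1 - value.
complemented_components <- function() "underweight"

#' Overall intervention coverage index
#'
#' Equal-weight arithmetic mean of the 11 component indicators per
#' region-year, with underweight prevalence complemented before
#' averaging. Region-years missing any component are dropped with a
#' logged reason (attribute `"dropped"`), never silently imputed.
#'
#' @param estimates Tidy estimate table (`indicator`, `region`, `year`,
#'   `point`), e.g. `tidy()` of a [run_coverage_pipeline()] fit.
#' @param components Component indicator ids (default
#'   [index_components()]).
#' @param complement Ids entering as `1 - value`.
#' @return A tibble (`region`, `year`, `index`) with one row per
#'   region-year having all components, plus component columns.
#' @export
#' @examples
#' est <- tidyr::crossing(indicator = index_components(),
#'                        region = 1, year = 2011)
#' est$point <- 0.64
#' est$point[est$indicator == "underweight"] <- 1 - 0.64
#' overall_coverage(est)
overall_coverage <- function(estimates, components = index_components(),
                             complement = complemented_components()) {
  estimates <- tibble::as_tibble(estimates)
  assert_df_has(estimates, c("indicator", "region", "year", "point"), "estimates")
  d <- estimates |>
    dplyr::filter(.data$indicator %in% components) |>
    dplyr::mutate(component = ifelse(.data$indicator %in% complement,
                                     1 - .data$point, .data$point))
  wide <- d |>
    dplyr::select("region", "year", "indicator", "component") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "component")
  have <- intersect(components, names(wide))
  complete <- stats::complete.cases(wide[, have]) & length(have) == length(components)
  dropped <- wide[!complete, c("region", "year")]
  out <- wide[complete, , drop = FALSE]
  out$index <- rowMeans(out[, components])
  out <- dplyr::select(out, "region", "year", "index", dplyr::all_of(components))
  attr(out, "dropped") <- dropped
  out
}

#' Uncertainty of the coverage index from matched posterior draws
#'
#' Propagates posterior uncertainty into the index: draw `d` of the
#' index is the equal-weight mean of the 11 components' draw `d`
#' (complementing underweight), so cross-indicator correlation induced
#' by shared years is preserved within each draw. Summaries are the
#' median and the 2.5th/97.5th percentiles.
#'
#' @param fit A `coverage_fit` from
#'   `run_coverage_pipeline(..., keep_draws = TRUE)`.
#' @param region_id Region whose draws to combine.
#' @param components,complement As in [overall_coverage()].
#' @return An `estimate_series` tibble (`region`, `year`, `point`,
#'   `lower`, `upper`) with the index draw matrix as attribute
#'   `"draws"`.
#' @export
index_uncertainty <- function(fit, region_id, components = index_components(),
                              complement = complemented_components()) {
  stopifnot(inherits(fit, "coverage_fit"))
  if (is.null(fit$draws)) {
    rlang::abort("run_coverage_pipeline() must be called with keep_draws = TRUE")
  }
  key <- as.character(region_id)
  mats <- lapply(components, function(ind) {
    m <- fit$draws[[ind]][[key]]
    if (is.null(m)) rlang::abort(sprintf("missing draws for component %s", ind))
    if (ind %in% complement) 1 - m else m
  })
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1) {
    rlang::abort("components have mismatched draw counts")
  }
  idx_draws <- Reduce(`+`, mats) / length(mats)
  qs <- apply(idx_draws, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  out <- tibble::tibble(region = region_id, year = fit$years,
                        point = qs[1, ], lower = qs[2, ], upper = qs[3, ])
  class(out) <- c("estimate_series", class(out))
  attr(out, "draws") <- idx_draws
  out
}

#' Pearson correlation between two region-year series
#'
#' Product-moment correlation over paired region-year values, the
#' summary used to relate overall intervention coverage to mortality
#' and socioeconomic trends. By default all region-years are pooled
#' into one pair set; `by = "year"` or `by = "region"` instead
#' averages nothing and returns one coefficient per stratum.
#'
#' @param series_a,series_b Data frames with `region`, `year` and a
#'   value column (the last column, or named by `value_a` / `value_b`).
#' @param value_a,value_b Value column names (default: last column).
#' @param by `"pooled"` (default), `"year"`, or `"region"`.
#' @return A tibble with columns `group` (for stratified variants),
#'   `rho`, `n`.
#' @export
#' @examples
#' a <- data.frame(region = 1, year = 1:5, x = 1:5)
#' b <- data.frame(region = 1, year = 1:5, y = c(2, 4, 6, 8, 10))
#' pearson_correlation(a, b)
pearson_correlation <- function(series_a, series_b,
                                value_a = NULL, value_b = NULL,
                                by = c("pooled", "year", "region")) {
  by <- match.arg(by)
  series_a <- tibble::as_tibble(series_a)
  series_b <- tibble::as_tibble(series_b)
  va <- value_a %||% utils::tail(setdiff(names(series_a), c("region", "year")), 1)
  vb <- value_b %||% utils::tail(setdiff(names(series_b), c("region", "year")), 1)
  d <- dplyr::inner_join(
    dplyr::select(series_a, "region", "year", a = dplyr::all_of(va)),
    dplyr::select(series_b, "region", "year", b = dplyr::all_of(vb)),
    by = c("region", "year"))
  d <- dplyr::filter(d, is.finite(.data$a), is.finite(.data$b))
  one <- function(dd, label) {
    if (nrow(dd) < 3) {
      rlang::abort("at least 3 paired values are required")
    }
    if (sd(dd$a) == 0 || sd(dd$b) == 0) {
      rlang::warn("zero variance in a series; correlation undefined")
      return(tibble::tibble(group = label, rho = NA_real_, n = nrow(dd)))
    }
    tibble::tibble(group = label, rho = cor(dd$a, dd$b), n = nrow(dd))
  }
  out <- switch(by,
    pooled = one(d, "pooled"),
    year = dplyr::bind_rows(lapply(split(d, d$year), function(dd)
      one(dd, as.character(dd$year[1])))),
    region = dplyr::bind_rows(lapply(split(d, d$region), function(dd)
      one(dd, as.character(dd$region[1]))))
  )
  out
}

#' League table of regions by overall coverage
#'
#' Ranks regions within each year by the overall coverage index
#' (rank 1 = highest coverage).
#'
#' @param index_series Tibble (`region`, `year`, `index` or `point`,
#'   optionally `lower`, `upper`).
#' @return The input with a `rank` column, sorted by year then rank.
#' @export
league_table <- function(index_series) {
  d <- tibble::as_tibble(index_series)
  val <- if ("index" %in% names(d)) "index" else "point"
  d |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(rank = rank(-.data[[val]], ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$year, .data$rank)
}
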