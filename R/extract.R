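#' Define an indicator extracted from microdata
#'
#' An indicator definition binds together the numerator and denominator
#' predicates evaluated on child/household records, the age window in
#' months, and the measurement scale. Records outside the age window or
#' failing the denominator predicate are excluded before any estimation —
#' the convention for indicators that are only asked about recent births
#' (antenatal care, skilled attendance) or for immunizations with a
#' recommended dosing schedule, where under-12-month children are
#' excluded.
#'
#' @param indicator_id Short label, e.g. `"measles"`.
#' @param numerator Bare expression on the record columns that is `TRUE`
#'   for covered records (default: `covered == 1`).
#' @param denominator Bare expression selecting the eligible population
#'   (default: all records in the age window).
#' @param age_window Two-element numeric vector of months `[lower, upper)`.
#' @param scale `"proportion"` or `"positive"`.
#' @return An `indicator_definition` object.
#' @export
#' @examples
#' indicator_definition("measles", age_window = c(12, 24))
indicator_definition <- function(indicator_id,
                                 numerator = NULL, denominator = NULL,
                                 age_window = c(0, 60),
                                 scale = c("proportion", "positive")) {
  scale <- match.arg(scale)
  if (age_window[1] >= age_window[2]) rlang::abort("age window lower must be < upper")
  structure(list(
    indicator_id = indicator_id,
    numerator = rlang::enquo(numerator),
    denominator = rlang::enquo(denominator),
    age_window = age_window,
    scale = scale
  ), class = "indicator_definition")
}

#' Design-weighted coverage with Taylor-linearized standard errors
#'
#' Estimates a weighted ratio mean of a binary indicator from clustered
#' survey microdata, with a design-based standard error that treats
#' clusters as primary sampling units (first-order Taylor linearization
#' of the ratio estimator, the standard variance for complex multistage
#' designs when later-stage sampling is absorbed into the PSU totals).
#'
#' For each group, with cluster residual totals
#' `z_c = sum_{k in c} w_k (y_k - p_hat)` over `m` clusters and total
#' weight `W`, the variance is `m / (m - 1) * sum_c z_c^2 / W^2`. With a
#' single cluster the formula degrades gracefully to element-level
#' linearization. An empty denominator yields a flagged missing row
#' rather than an error, so one empty survey cell cannot kill a
#' pipeline run.
#'
#' @param data Microdata records (one row per child/household) with at
#'   least weight, cluster and indicator columns.
#' @param definition Optional [indicator_definition()]; applies its age
#'   window and predicates before estimation.
#' @param value,weight,cluster,age Bare column names (defaults
#'   `covered`, `weight`, `cluster`, `age_months`).
#' @param by Character vector of grouping columns (default `"region"`).
#' @return A tibble per group: `estimate`, `se`, `n`, `n_clusters`,
#'   `n_eff` (Kish effective sample size), `missing` flag.
#' @export
#' @examples
#' g <- make_region_graph(2, "line")
#' tr <- simulate_true_coverage(g, 2005:2006, seed = 3)
#' md <- simulate_microdata(tr, 2005, seed = 3)
#' weighted_coverage(md)
weighted_coverage <- function(data, definition = NULL,
                              value = covered, weight = weight,
                              cluster = cluster, age = age_months,
                              by = "region") {
  data <- tibble::as_tibble(data)
  if (!is.null(definition)) {
    aw <- definition$age_window
    age_q <- rlang::enquo(age)
    data <- dplyr::filter(data, !!age_q >= aw[1], !!age_q < aw[2])
    if (!rlang::quo_is_null(definition$denominator)) {
      data <- dplyr::filter(data, !!definition$denominator)
    }
    if (!rlang::quo_is_null(definition$numerator)) {
      data <- dplyr::mutate(data, ..y.. = as.numeric(!!definition$numerator))
    } else {
      data <- dplyr::mutate(data, ..y.. = as.numeric({{ value }}))
    }
  } else {
    data <- dplyr::mutate(data, ..y.. = as.numeric({{ value }}))
  }
  grp <- dplyr::group_by(data, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::group_modify(grp, function(d, key) {
    wc_one(d$..y.., dplyr::pull(d, {{ weight }}), dplyr::pull(d, {{ cluster }}))
  })
  dplyr::ungroup(out)
}

wc_one <- function(y, w, cl) {
  keep <- !is.na(y) & !is.na(w) & w > 0
  y <- y[keep]; w <- w[keep]; cl <- cl[keep]
  if (length(y) == 0) {
    return(tibble::tibble(estimate = NA_real_, se = NA_real_, n = 0L,
                          n_clusters = 0L, n_eff = NA_real_, missing = TRUE))
  }
  W <- sum(w)
  p <- sum(w * y) / W
  resid <- w * (y - p)
  m <- length(unique(cl))
  if (m > 1) {
    z <- as.numeric(tapply(resid, cl, sum))
    v <- m / (m - 1) * sum(z^2) / W^2
  } else if (length(y) > 1) {
    k <- length(y)
    v <- k / (k - 1) * sum(resid^2) / W^2
  } else {
    v <- 0
  }
  tibble::tibble(estimate = p, se = sqrt(v), n = length(y),
                 n_clusters = m, n_eff = W^2 / sum(w^2), missing = FALSE)
}

#' Transform estimates to the modeling scale
#'
#' Applies the logit transform to proportion-type estimates and the log
#' transform to positive-valued ones, carrying the sampling variance
#' through by the delta method: `var(logit p) = var(p) / (p(1-p))^2` and
#' `var(log x) = var(x) / x^2`. Proportions are first clamped away from
#' the boundary — to `[1/(4 n_eff), 1 - 1/(4 n_eff)]` when the effective
#' sample size is known, else to `[0.001, 0.999]` — since boundary
#' estimates have degenerate transformed variances.
#'
#' When `se` is zero or missing but `n_eff` is available, the binomial
#' fallback `p(1-p)/n_eff` is used on the natural scale; if neither is
#' available the observation is rejected.
#'
#' @param data Data frame with columns named by `estimate`, `se`,
#'   `n_eff` arguments.
#' @param estimate,se,n_eff Bare column names.
#' @param scale `"proportion"` or `"positive"`.
#' @return The input tibble with `transformed_value` and
#'   `transformed_variance` columns added.
#' @export
#' @examples
#' transform_observation(data.frame(estimate = 0.5, se = 0.05, n_eff = 100))
transform_observation <- function(data, estimate = estimate, se = se,
                                  n_eff = n_eff,
                                  scale = c("proportion", "positive")) {
  scale <- match.arg(scale)
  data <- tibble::as_tibble(data)
  p <- dplyr::pull(data, {{ estimate }})
  s <- dplyr::pull(data, {{ se }})
  ne <- tryCatch(dplyr::pull(data, {{ n_eff }}), error = function(e) rep(NA_real_, length(p)))
  bad_se <- is.na(s) | s <= 0
  if (scale == "proportion") {
    pc <- clamp_proportion(p, ne)
    s2 <- ifelse(bad_se, pc * (1 - pc) / ne, s^2)
    if (any(bad_se & (is.na(ne) | ne <= 0))) {
      rlang::abort("non-positive SE with no effective sample size fallback")
    }
    tv <- logit(pc)
    tvar <- s2 / (pc * (1 - pc))^2
  } else {
    if (any(p <= 0)) rlang::abort("positive-scale estimates must be > 0")
    s2 <- ifelse(bad_se, p^2 / ne, s^2)
    if (any(bad_se & (is.na(ne) | ne <= 0))) {
      rlang::abort("non-positive SE with no effective sample size fallback")
    }
    tv <- log(p)
    tvar <- s2 / p^2
  }
  dplyr::mutate(data, transformed_value = tv, transformed_variance = tvar)
}

#' Back-transform a modeled value to the natural scale
#'
#' @param x Transformed-scale values.
#' @param scale `"proportion"` (inverse logit) or `"positive"` (exp).
#' @return Natural-scale values.
#' @export
back_transform <- function(x, scale = c("proportion", "positive")) {
  scale <- match.arg(scale)
  if (scale == "proportion") inv_logit(x) else exp(x)
}

#' Impute transformed variances for point-only observations
#'
#' Some report-extracted sources supply a point estimate with no
#' sampling error. Their transformed variance is imputed as the 90th
#' percentile of the observed transformed variances for the same
#' indicator — deliberately conservative so that low-provenance points
#' cannot dominate the smoothing.
#'
#' @param obs Observation tibble with `indicator` and
#'   `transformed_variance` columns (NA where missing).
#' @return The tibble with missing transformed variances filled and a
#'   logical `variance_imputed` column.
#' @export
impute_transformed_variance <- function(obs) {
  obs |>
    dplyr::group_by(.data$indicator) |>
    dplyr::mutate(
      variance_imputed = is.na(.data$transformed_variance),
      transformed_variance = ifelse(
        is.na(.data$transformed_variance),
        quantile(.data$transformed_variance, 0.9, na.rm = TRUE),
        .data$transformed_variance)
    ) |>
    dplyr::ungroup()
}

#' Read or write an observation table
#'
#' The interchange CSV carries one row per region-year-source-indicator
#' estimate with the documented header `region, year, source, is_dhs,
#' indicator, estimate, se, transformed_value, transformed_variance,
#' n_eff`.
#'
#' @param obs Observation tibble.
#' @param path CSV path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` the tibble.
#' @export
write_observations <- function(obs, path) {
  cols <- c("region", "year", "source", "is_dhs", "indicator", "estimate",
            "se", "transformed_value", "transformed_variance", "n_eff")
  assert_df_has(obs, cols, "observation table")
  readr::write_csv(obs[, cols], path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE)
  assert_df_has(obs, c("region", "year", "source", "indicator", "estimate"),
                "observation file")
  obs
}
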