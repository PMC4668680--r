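#' Predict 5q0 for a region-year from a fitted mortality model
#'
#' Posterior summaries of under-5 mortality on the probability scale.
#' Predictions use the DHS-consistent linear predictor: the non-DHS
#' adjustment `beta2` and the source effects `gamma` are set to zero, so
#' the estimate tracks the reference-source level, not the shifted
#' observations. Quantiles (median, 2.5th, 97.5th) are taken on the
#' theta samples and then inverse-logit transformed — valid because the
#' transform is monotone.
#'
#' @param fit A `mortality_fit`.
#' @param region_id Region index (vectorized).
#' @param year Year on the estimation grid (vectorized, recycled
#'   against `region_id`).
#' @return A tibble: `region`, `year`, `q5` (median), `lower`, `upper`.
#' @export
predict_5q0 <- function(fit, region_id, year) {
  stopifnot(inherits(fit, "mortality_fit"))
  d <- tibble::tibble(region = region_id, year = year)
  n <- n_regions(fit$graph)
  t_idx <- match(d$year, fit$years)
  if (any(is.na(t_idx))) rlang::abort("year outside the estimation grid")
  cols <- (t_idx - 1L) * n + d$region
  qs <- apply(fit$samples$theta[, cols, drop = FALSE], 2, quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  dplyr::mutate(d, q5 = inv_logit(qs[1, ]), lower = inv_logit(qs[2, ]),
                upper = inv_logit(qs[3, ]))
}

#' @export
#' @rdname predict_5q0
#' @param object A `mortality_fit`.
#' @param ... Unused.
predict.mortality_fit <- function(object, ...) {
  grid <- tidyr::crossing(region = seq_len(n_regions(object$graph)),
                          year = object$years)
  predict_5q0(object, grid$region, grid$year)
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf(
    "<mortality_fit: %d regions x %d years, %d observations, %d chains x %d iters (%d kept), max R-hat %.3f>\n",
    n_regions(x$graph), length(x$years), x$n_obs, x$chains, x$iterations,
    nrow(x$samples$beta), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Broom-style summaries of a mortality fit
#'
#' `tidy()` summarizes the fixed effects and variance parameters
#' (posterior median, 95% interval, split-R-hat); `glance()` reports
#' fit-level metadata.
#'
#' @param x A `mortality_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mortality_fit <- function(x, ...) {
  draws <- cbind(x$samples$beta, x$samples$sigma2, x$samples$tau)
  qs <- apply(draws, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  rh <- x$rhat[c("beta0", "beta1", "beta2", "sigma2",
                 "log_tau_u", "log_tau_v", "log_tau_w", "log_tau_delta",
                 "log_tau_gamma")]
  tibble::tibble(term = colnames(draws), estimate = qs[1, ],
                 conf.low = qs[2, ], conf.high = qs[3, ],
                 rhat = as.numeric(rh))
}

#' @rdname tidy.mortality_fit
#' @export
glance.mortality_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_regions = n_regions(x$graph),
                 n_years = length(x$years), chains = x$chains,
                 iterations = x$iterations, kept = nrow(x$samples$beta),
                 max_rhat = max(x$rhat, na.rm = TRUE))
}

#' Plot estimated mortality trends
#'
#' Region-wise posterior median 5q0 trends with 95% credible ribbons.
#'
#' @param object A `mortality_fit`.
#' @param per_1000 Scale 5q0 to deaths per 1,000 live births.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mortality_fit <- function(object, per_1000 = TRUE, ...) {
  d <- predict(object)
  k <- if (per_1000) 1000 else 1
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$q5 * k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower * k,
                                      ymax = .data$upper * k), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "year",
                  y = if (per_1000) "5q0 (per 1,000 live births)" else "5q0") +
    ggplot2::theme_minimal()
}
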