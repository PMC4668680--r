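#' Natural cubic spline basis with one interior knot
#'
#' Builds the two-column smoother basis `h1(t), h2(t)` used by the
#' stage-1 mixed model: a natural cubic spline with a single interior
#' knot (default: the midpoint of the year range) and boundary knots at
#' the range endpoints, so the fitted curve is linear outside the data.
#'
#' @param years Integer grid of at least 3 distinct years.
#' @param knot Interior knot (default: midpoint of the year range).
#' @return A `spline_basis` object; call [eval_basis()] to evaluate it.
#' @export
#' @examples
#' b <- build_spline_basis(1990:2011)
#' head(eval_basis(b, 1990:1995))
build_spline_basis <- function(years, knot = NULL) {
  years <- sort(unique(as.numeric(years)))
  if (length(years) < 3) rlang::abort("need at least 3 distinct years")
  boundary <- range(years)
  knot <- knot %||% mean(boundary)
  if (knot <= boundary[1] || knot >= boundary[2]) {
    rlang::abort("interior knot must lie strictly inside the boundary knots")
  }
  structure(list(knot = knot, boundary = boundary),
            class = "spline_basis")
}

#' Evaluate a spline basis
#'
#' @param basis A `spline_basis`.
#' @param years Years at which to evaluate.
#' @return Numeric matrix with columns `h1`, `h2`.
#' @export
eval_basis <- function(basis, years) {
  stopifnot(inherits(basis, "spline_basis"))
  m <- splines::ns(as.numeric(years), knots = basis$knot,
                   Boundary.knots = basis$boundary)
  m <- unclass(m)[, 1:2, drop = FALSE]
  colnames(m) <- c("h1", "h2")
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis: knot %.1f, boundary [%.0f, %.0f]>\n",
              x$knot, x$boundary[1], x$boundary[2]))
  invisible(x)
}

#' Fit the stage-1 spline mixed model
#'
#' Fits, on the transformed scale, the linear mixed-effects model
#' `g(y_it) = b0 + b1 h1(t) + b2 h2(t) + g0i + g1i h1(t) + g2i h2(t)`
#' with correlated random intercepts and spline slopes per region. The
#' region-specific predicted trends (fixed effects plus best linear
#' unbiased predictions of the random effects) serve as the mean prior
#' for the stage-2 Gaussian process regression.
#'
#' Estimation is by REML via `lme4`, with an automatic fallback chain:
#' REML, then maximum likelihood, then a fixed-effects-only least-squares
#' fit (also used when only one region is present, where region effects
#' are unidentifiable). The fallback used is recorded on the returned
#' object, and a degenerate (singular) random-effect covariance is
#' allowed and flagged rather than treated as an error.
#'
#' @param observations Tibble with columns `region`, `year`,
#'   `transformed_value` (one indicator).
#' @param basis A [build_spline_basis()] object.
#' @return A `stage1_fit` object (supports [tidy()], [glance()] and
#'   [predict_stage1()]).
#' @export
fit_stage1 <- function(observations, basis) {
  observations <- tibble::as_tibble(observations)
  assert_df_has(observations, c("region", "year", "transformed_value"),
                "observations")
  h <- eval_basis(basis, observations$year)
  d <- data.frame(y = observations$transformed_value,
                  h1 = h[, 1], h2 = h[, 2],
                  region = factor(observations$region))
  n_region <- nlevels(d$region)
  if (nrow(d) <= 3) rlang::abort("more observations than fixed effects are required")

  fit <- NULL; method <- NULL; singular <- FALSE
  if (n_region >= 2) {
    for (reml in c(TRUE, FALSE)) {
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(y ~ h1 + h2 + (1 + h1 + h2 | region), data = d,
                     REML = reml,
                     control = lme4::lmerControl(check.conv.singular = "ignore",
                                                 calc.derivs = FALSE))
        )),
        error = function(e) NULL)
      if (!is.null(fit)) {
        conv <- length(fit@optinfo$conv$lme4) == 0
        method <- if (reml) "REML" else "ML"
        singular <- lme4::isSingular(fit, tol = 1e-5)
        if (conv) break
      }
    }
  }
  if (is.null(fit)) {
    fit <- stats::lm(y ~ h1 + h2, data = d)
    method <- "fixed-only"
    if (n_region >= 2) {
      rlang::warn("stage-1 mixed model did not converge; using fixed-effects-only fit")
    }
  }
  structure(list(
    model = fit, basis = basis, method = method, singular = singular,
    regions = levels(d$region),
    residual_sd = stats::sigma(fit)
  ), class = "stage1_fit")
}

#' Predict the stage-1 prior mean for one region
#'
#' Returns the region-specific predicted trend on the transformed scale,
#' including the region's predicted random effects when the region was
#' in the fit; unseen regions (and fixed-effects-only fits) get the
#' fixed-effects curve.
#'
#' @param fit A `stage1_fit`.
#' @param region_id Region identifier.
#' @param years Years at which to predict.
#' @return Numeric vector of prior means.
#' @export
predict_stage1 <- function(fit, region_id, years) {
  stopifnot(inherits(fit, "stage1_fit"))
  h <- eval_basis(fit$basis, years)
  X <- cbind(1, h)
  if (inherits(fit$model, "merMod")) {
    beta <- lme4::fixef(fit$model)
    mu <- drop(X %*% beta)
    re <- lme4::ranef(fit$model)$region
    key <- as.character(region_id)
    if (key %in% rownames(re)) {
      mu <- mu + drop(X %*% as.numeric(re[key, c("(Intercept)", "h1", "h2")]))
    }
    mu
  } else {
    drop(X %*% stats::coef(fit$model))
  }
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("<stage1_fit: %s, %d regions, residual sd %.4f%s>\n",
              x$method, length(x$regions), x$residual_sd,
              if (isTRUE(x$singular)) ", singular RE covariance" else ""))
  invisible(x)
}

#' @rdname fit_stage1
#' @param x A `stage1_fit`.
#' @param ... Unused.
#' @export
tidy.stage1_fit <- function(x, ...) {
  if (inherits(x$model, "merMod")) {
    b <- lme4::fixef(x$model)
    se <- sqrt(diag(as.matrix(stats::vcov(x$model))))
  } else {
    b <- stats::coef(x$model)
    se <- sqrt(diag(stats::vcov(x$model)))
  }
  tibble::tibble(term = c("(Intercept)", "h1", "h2"),
                 estimate = as.numeric(b), std.error = as.numeric(se))
}

#' @rdname fit_stage1
#' @export
glance.stage1_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n_regions = length(x$regions),
                 residual_sd = x$residual_sd, singular = isTRUE(x$singular))
}
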