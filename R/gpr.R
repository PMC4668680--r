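#' Gaussian process regression configuration
#'
#' Hyperparameters for the stage-2 smoother. The Matern smoothness is
#' restricted to the half-integer family with closed forms. When
#' `amplitude` or `nonsampling_var` is `NA` the pipeline fills them from
#' the stage-1 fit using the *non-sampling* residual variance — the
#' excess of the stage-1 residual variance over the observations' mean
#' sampling variance: amplitude = 1.5 x its square root (the prior mean
#' is allowed to be wrong by more than the unexplained scatter),
#' non-sampling variance floor = the excess itself (survey point
#' estimates disagree by more than their sampling errors alone).
#' Deriving both from the excess rather than the raw residual variance
#' avoids counting sampling noise twice.
#'
#' @param nu Matern smoothness, one of 1/2, 3/2, 5/2.
#' @param length_scale Correlation length in years (> 0).
#' @param amplitude Prior standard deviation on the transformed scale.
#' @param nonsampling_var Variance floor added to every observation's
#'   sampling variance.
#' @param n_draws Number of posterior draws (>= 2).
#' @return A `gpr_config` list.
#' @export
#' @examples
#' gpr_config(length_scale = 8)
gpr_config <- function(nu = 3 / 2, length_scale = 10, amplitude = NA,
                       nonsampling_var = NA, n_draws = 1000) {
  if (!isTRUE(any(abs(nu - c(1 / 2, 3 / 2, 5 / 2)) < 1e-12))) {
    rlang::abort("nu must be one of 1/2, 3/2, 5/2")
  }
  stopifnot(length_scale > 0, n_draws >= 2, is.na(amplitude) || amplitude >= 0)
  structure(list(nu = nu, length_scale = length_scale, amplitude = amplitude,
                 nonsampling_var = nonsampling_var, n_draws = as.integer(n_draws)),
            class = "gpr_config")
}

#' Matern covariance between two time points
#'
#' Half-integer Matern kernel in closed form: with `d = |t1 - t2|`,
#' `r = d / length_scale`,
#' * `nu = 1/2`: `a^2 exp(-r)`
#' * `nu = 3/2`: `a^2 (1 + sqrt(3) r) exp(-sqrt(3) r)`
#' * `nu = 5/2`: `a^2 (1 + sqrt(5) r + 5 r^2 / 3) exp(-sqrt(5) r)`
#'
#' @param t1,t2 Numeric vectors of years (recycled).
#' @param config A [gpr_config()]; `amplitude` must be set.
#' @return Covariance values.
#' @export
#' @examples
#' matern_cov(2000, 2010, gpr_config(amplitude = 1))
matern_cov <- function(t1, t2, config) {
  a2 <- config$amplitude^2
  r <- abs(t1 - t2) / config$length_scale
  if (abs(config$nu - 1 / 2) < 1e-12) {
    a2 * exp(-r)
  } else if (abs(config$nu - 3 / 2) < 1e-12) {
    a2 * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
  } else {
    a2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
}

matern_matrix <- function(t1, t2, config) {
  outer(t1, t2, function(a, b) matern_cov(a, b, config))
}

#' Condition the Gaussian process prior on observations
#'
#' Exact Gaussian conditioning of the Matern prior (mean = the stage-1
#' region prediction) on the region's transformed observations. With
#' prior covariance `K` on the year grid, cross-covariance `K*` to the
#' data years, and `D` the diagonal of per-observation total variances
#' (sampling variance + non-sampling floor):
#' `post mean = m + K*' (K_dd + D)^-1 (y - m_d)` and
#' `post cov = K - K*' (K_dd + D)^-1 K*`.
#'
#' Multiple observations in one year are retained as separate
#' heteroskedastic conditioning points. With zero observations the
#' posterior equals the prior. If `(K_dd + D)` is numerically singular a
#' single jitter of 1e-8 is added to its diagonal; if factorization
#' still fails an error is raised.
#'
#' @param prior_mean Numeric vector: prior mean on `years`.
#' @param years Integer year grid.
#' @param observations Tibble with `year`, `transformed_value`,
#'   `transformed_variance` (possibly zero rows).
#' @param config A [gpr_config()] with `amplitude` and
#'   `nonsampling_var` resolved.
#' @param region_id Identifier carried on the result.
#' @return A `posterior_surface`: list with `region`, `years`, `mean`,
#'   `cov`, `config`, `n_obs`.
#' @export
fit_gpr <- function(prior_mean, years, observations, config, region_id = NA) {
  stopifnot(length(prior_mean) == length(years), inherits(config, "gpr_config"),
            !is.na(config$amplitude), !is.na(config$nonsampling_var))
  observations <- tibble::as_tibble(observations)
  K <- matern_matrix(years, years, config)
  if (nrow(observations) == 0) {
    return(structure(list(region = region_id, years = years, mean = prior_mean,
                          cov = K, config = config, n_obs = 0L),
                     class = "posterior_surface"))
  }
  assert_df_has(observations, c("year", "transformed_value", "transformed_variance"),
                "observations")
  if (!all(observations$year %in% years)) {
    rlang::abort("observation years must lie on the estimation grid")
  }
  if (any(is.na(observations$transformed_variance))) {
    rlang::abort("transformed_variance must be present for every observation")
  }
  idx <- match(observations$year, years)
  Ks <- K[, idx, drop = FALSE]
  Kdd <- K[idx, idx, drop = FALSE] +
    diag(observations$transformed_variance + config$nonsampling_var,
         nrow = length(idx))
  ch <- tryCatch(chol(Kdd), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(Kdd + diag(1e-8, nrow(Kdd))), error = function(e) NULL)
    if (is.null(ch)) rlang::abort("(K + D) is singular even after jitter")
  }
  resid <- observations$transformed_value - prior_mean[idx]
  alpha <- backsolve(ch, forwardsolve(t(ch), resid))
  V <- forwardsolve(t(ch), t(Ks))
  post_mean <- prior_mean + drop(Ks %*% alpha)
  post_cov <- K - crossprod(V)
  post_cov <- (post_cov + t(post_cov)) / 2
  structure(list(region = region_id, years = years, mean = post_mean,
                 cov = post_cov, config = config, n_obs = nrow(observations)),
            class = "posterior_surface")
}

#' @export
print.posterior_surface <- function(x, ...) {
  cat(sprintf("<posterior_surface: region %s, %d years, %d observations>\n",
              x$region, length(x$years), x$n_obs))
  invisible(x)
}

#' @rdname fit_gpr
#' @param x A `posterior_surface`.
#' @param ... Unused.
#' @export
tidy.posterior_surface <- function(x, ...) {
  tibble::tibble(region = x$region, year = x$years, mean = x$mean,
                 var = diag(x$cov))
}

#' Draw from the posterior and summarize on the natural scale
#'
#' Draws `n_draws` sample paths from the Gaussian posterior on the
#' transformed scale, back-transforms each elementwise (inverse logit
#' for proportions, exp for positive indicators), and summarizes per
#' year by the median (point estimate) and the 2.5th / 97.5th
#' percentiles (95% interval). Back-transformed draws respect the
#' indicator's domain by construction.
#'
#' @param surface A `posterior_surface` from [fit_gpr()].
#' @param scale `"proportion"` or `"positive"`.
#' @param seed Integer seed for the draws.
#' @param keep_draws Return the draw matrix as attribute `"draws"`
#'   (draw x year, natural scale).
#' @return A tibble (`region`, `year`, `point`, `lower`, `upper`), class
#'   `estimate_series`.
#' @export
draw_and_summarize <- function(surface, scale = c("proportion", "positive"),
                               seed = 1, keep_draws = FALSE) {
  scale <- match.arg(scale)
  stopifnot(inherits(surface, "posterior_surface"))
  n <- length(surface$years)
  nd <- surface$config$n_draws
  draws_t <- with_seed(child_seed(seed, paste0("gpr_draws:", surface$region)), {
    L <- chol_psd(surface$cov)
    z <- matrix(rnorm(nd * n), nd, n)
    sweep(z %*% L, 2, surface$mean, "+")
  })
  draws <- back_transform(draws_t, scale)
  qs <- apply(draws, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  out <- tibble::tibble(region = surface$region, year = surface$years,
                        point = qs[1, ], lower = qs[2, ], upper = qs[3, ])
  class(out) <- c("estimate_series", class(out))
  if (keep_draws) attr(out, "draws") <- draws
  out
}

# Upper-triangular factor L with t(L) %*% L = S for a PSD matrix,
# via eigendecomposition (tolerates zero eigenvalues).
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(lam)))
}
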