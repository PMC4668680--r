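#' Default generating parameters for the mortality simulator
#'
#' Parameter set emulating a high-burden two-decade mortality decline:
#' intercept `logit(0.15)` at the grid midpoint, slope -0.03 per year on
#' the logit scale (roughly a halving of 5q0 over 22 years), a non-DHS
#' source shift of +0.3, regional intercept/slope dispersion, modest
#' non-linear year and region-year structure, and observation noise
#' sd 0.05 on the logit scale.
#'
#' @return Named list of generating parameters (precisions, not
#'   variances, for the random-effect families).
#' @export
default_mortality_params <- function() {
  list(beta0 = logit(0.15), beta1 = -0.03, beta2 = 0.3,
       tau_u = 100, tau_v = 1e4, tau_w = 400, tau_delta = 2500,
       tau_gamma = 400, sigma2 = 0.0025)
}

#' Simulate observations from the hierarchical mortality model
#'
#' Generative twin of [fit_mortality_model()]: draws region intercepts
#' `u` and slopes `v` from intrinsic CAR priors on the graph, a year
#' effect `w` from an RW1 prior, a region-year interaction `delta` from
#' the Kronecker (RW1 x ICAR) prior, and iid region-source effects
#' `gamma`; then
#' `logit(5q0)_{i,t,s} ~ N(beta0 + beta1 t + beta2 I(non-DHS) + u_i +
#' v_i t + w_t + delta_it + gamma_is, sigma2)` with `t` centered at the
#' grid midpoint. Intrinsic draws are taken in the row space of each
#' structure matrix, so all sum-to-zero constraints hold exactly. The
#' latent effects are returned for recovery testing.
#'
#' An infinite precision yields an exactly-zero effect family, and
#' `sigma2 = 0` noiseless observations, so degenerate-truth checks are
#' exact.
#'
#' @param graph A `region_graph`.
#' @param years Integer year grid.
#' @param params Named list as in [default_mortality_params()].
#' @param schedule A `survey_schedule`; each source-year is observed in
#'   every region.
#' @param seed Integer seed.
#' @return A list with `observations` (tibble: `region`, `year`,
#'   `source`, `is_dhs`, `logit_q5`, `q5`), `effects` (list `u`, `v`,
#'   `w`, `delta` (region x year matrix), `gamma` (region x source
#'   matrix)), and `theta_grid` (region x year matrix of the DHS-scale
#'   linear predictor `beta0 + beta1 t + u + v t + w + delta`).
#' @export
simulate_from_mortality_model <- function(graph, years,
                                          params = default_mortality_params(),
                                          schedule = default_survey_schedule(),
                                          seed = 1) {
  stopifnot(inherits(graph, "region_graph"))
  years <- as.integer(years)
  n <- n_regions(graph)
  T_ <- length(years)
  taus <- params[c("tau_u", "tau_v", "tau_w", "tau_delta", "tau_gamma")]
  if (any(unlist(taus) <= 0)) rlang::abort("precisions must be positive")
  t_c <- years - mean(years)
  sources <- unique(tibble::as_tibble(schedule)[, c("source_id", "is_dhs")])
  S <- nrow(sources)

  eff <- with_seed(child_seed(seed, "mortality_effects"), {
    Q <- build_icar_precision(graph)
    R <- build_rw1_precision(T_)
    eigQ <- eigen(Q, symmetric = TRUE)
    eigR <- eigen(R, symmetric = TRUE)
    draw_family <- function(eig, tau) {
      if (!is.finite(tau)) rep(0, nrow(eig$vectors)) else sample_intrinsic(eig, tau)
    }
    u <- draw_family(eigQ, params$tau_u)
    v <- draw_family(eigQ, params$tau_v)
    # w is additionally conditioned to be orthogonal to the linear trend:
    # the global slope belongs to beta1, the year effect to the
    # non-linear deviations (identifiability convention, matched by the
    # fitter)
    w <- if (!is.finite(params$tau_w)) rep(0, T_) else
      sample_intrinsic_constrained(eigR, params$tau_w, t_c)
    delta <- if (!is.finite(params$tau_delta)) matrix(0, n, T_) else {
      eigK <- eigen(kronecker(R, Q), symmetric = TRUE)
      matrix(sample_intrinsic(eigK, params$tau_delta), n, T_)
    }
    gamma <- if (!is.finite(params$tau_gamma)) matrix(0, n, S) else
      matrix(rnorm(n * S, 0, 1 / sqrt(params$tau_gamma)), n, S)
    list(u = u, v = v, w = w, delta = delta, gamma = gamma)
  })

  theta_grid <- outer(eff$u, rep(1, T_)) + outer(eff$v, t_c) +
    outer(rep(1, n), params$beta0 + params$beta1 * t_c + eff$w) + eff$delta
  obs <- tidyr::crossing(region = seq_len(n), tibble::as_tibble(schedule)) |>
    dplyr::mutate(
      t_idx = match(.data$year, years),
      s_idx = match(.data$source_id, sources$source_id),
      theta = theta_grid[cbind(.data$region, .data$t_idx)] +
        params$beta2 * (1 - .data$is_dhs) +
        eff$gamma[cbind(.data$region, .data$s_idx)]
    )
  noise <- with_seed(child_seed(seed, "mortality_noise"), {
    rnorm(nrow(obs), 0, sqrt(params$sigma2))
  })
  observations <- tibble::tibble(
    region = obs$region, year = obs$year, source = obs$source_id,
    is_dhs = obs$is_dhs,
    logit_q5 = obs$theta + noise
  ) |>
    dplyr::mutate(q5 = inv_logit(.data$logit_q5)) |>
    dplyr::arrange(.data$region, .data$year, .data$source)
  list(observations = observations, effects = eff, theta_grid = theta_grid,
       years = years, sources = sources)
}
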