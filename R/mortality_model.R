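#' Fit the hierarchical spatiotemporal under-5 mortality model
#'
#' Bayesian hierarchical model for logit 5q0 observed by multiple
#' sources:
#' `logit(5q0)_{i,t,s} ~ Normal(theta_{i,t,s}, sigma2)` with
#' `theta = beta0 + beta1 t + beta2 I(s not DHS) + u_i + v_i t + w_t +
#' delta_it + gamma_is`, where `u` and `v` are region intercepts/slopes
#' with intrinsic CAR priors on the adjacency graph, `w` is an RW1 year
#' effect, `delta` is the space-time interaction with the Kronecker
#' (RW1 x ICAR) prior, and `gamma` are iid normal region-source effects
#' absorbing within-source autocorrelation. The year covariate is
#' centered at the grid midpoint. Weakly informative priors: normal
#' (sd 31.6) on fixed effects, Gamma(1, 0.01) on all precisions
#' (including the observation precision `1/sigma2`).
#'
#' Inference is by blocked Gibbs sampling: every fixed- and
#' random-effect family has a Gaussian full conditional given the
#' precisions, and the precisions have conjugate gamma updates with
#' degrees of freedom equal to the rank of their structure matrix.
#' Intrinsic effects are sampled directly in the orthogonal complement
#' of their prior null space, so the sum-to-zero constraints
#' (`sum u = sum v = sum w = 0`, row and column sums of `delta` zero)
#' hold exactly at every iteration and the full conditionals stay
#' proper even when many grid years are unobserved. The year effect `w`
#' is additionally constrained orthogonal to linear time: without it the
#' weakly penalized linear component of the random walk is confounded
#' with `beta1` (the simulator applies the same convention). The fixed
#' effects and `gamma` are updated as one joint Gaussian block, since
#' `beta2` and the non-DHS source effects compete for the same level.
#'
#' Convergence is reported as split-R-hat on the monitored scalars
#' (`beta0`, `beta1`, `beta2`, `sigma2`, log precisions); values above
#' 1.1 trigger a warning advising longer chains.
#'
#' @param observations Tibble with columns `region` (1-based index into
#'   the graph), `year`, `source`, `is_dhs`, and `logit_q5` (or `q5`,
#'   which is logit-transformed).
#' @param graph A `region_graph` covering every observed region.
#' @param years Integer estimation grid.
#' @param iterations Gibbs iterations per chain (including burn-in).
#' @param burnin Burn-in iterations discarded per chain (default half).
#' @param chains Number of independent chains (>= 1; 2+ needed for
#'   R-hat).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Master seed; chain `c` uses an independent derived
#'   stream.
#' @param priors List: `beta_sd` (default 31.6), `tau_shape` (1),
#'   `tau_rate` (0.01).
#' @param keep_effects Also store `delta` and `gamma` samples.
#' @return A `mortality_fit` object with elements `samples` (list of
#'   matrices: `beta` S x 3, `sigma2`, `tau` S x 5, `u`, `v`, `w`,
#'   `theta` S x (n*T) DHS-scale linear predictor), `rhat` (named
#'   vector), `graph`, `years`, plus metadata. Methods: [predict_5q0()],
#'   `predict()`, [tidy()], [glance()], [autoplot()].
#' @export
fit_mortality_model <- function(observations, graph, years,
                                iterations = 5000, burnin = floor(iterations / 2),
                                chains = 2, thin = 5, seed = 1,
                                priors = list(beta_sd = 31.6, tau_shape = 1,
                                              tau_rate = 0.01),
                                keep_effects = FALSE) {
  observations <- tibble::as_tibble(observations)
  assert_df_has(observations, c("region", "year", "source", "is_dhs"),
                "observations")
  if (!"logit_q5" %in% names(observations)) {
    assert_df_has(observations, "q5", "observations")
    if (any(observations$q5 <= 0 | observations$q5 >= 1)) {
      rlang::abort("q5 must lie strictly in (0, 1)")
    }
    observations$logit_q5 <- logit(observations$q5)
  }
  if (any(!is.finite(observations$logit_q5))) {
    rlang::abort("non-finite logit(5q0) observation")
  }
  years <- as.integer(years)
  n <- n_regions(graph)
  T_ <- length(years)
  if (!all(observations$region %in% seq_len(n))) {
    rlang::abort("observations reference regions absent from the graph")
  }
  if (!all(observations$year %in% years)) {
    rlang::abort("observation years outside the estimation grid")
  }
  stopifnot(iterations > burnin, chains >= 1, thin >= 1)

  pre <- mortality_precompute(observations, graph, years, priors)
  chain_fits <- lapply(seq_len(chains), function(cc) {
    run_mortality_chain(pre, iterations, burnin, thin,
                        seed = child_seed(seed, paste0("mortality_chain_", cc)),
                        keep_effects = keep_effects)
  })
  samples <- list()
  for (nm in names(chain_fits[[1]]$samples)) {
    samples[[nm]] <- do.call(rbind, lapply(chain_fits, function(f) f$samples[[nm]]))
  }
  monitored <- lapply(chain_fits, function(f) f$monitor)
  rhat <- split_rhat(monitored)
  if (any(rhat > 1.1, na.rm = TRUE)) {
    rlang::warn(paste0(
      "split R-hat exceeds 1.1 for: ",
      paste(names(rhat)[which(rhat > 1.1)], collapse = ", "),
      "; consider lengthening the chains"))
  }
  structure(list(
    samples = samples, rhat = rhat, graph = graph, years = years,
    sources = pre$sources, n_obs = nrow(observations),
    iterations = iterations, burnin = burnin, chains = chains, thin = thin,
    seed = seed, priors = pre$priors
  ), class = "mortality_fit")
}

# Precompute design indices, orthonormal constraint bases, and the
# constant pieces of every full-conditional precision matrix.
mortality_precompute <- function(obs, graph, years, priors) {
  n <- n_regions(graph); T_ <- length(years)
  priors <- utils::modifyList(list(beta_sd = 31.6, tau_shape = 1, tau_rate = 0.01),
                              priors %||% list())
  t_c <- years - mean(years)
  i_idx <- obs$region
  t_idx <- match(obs$year, years)
  sources <- sort(unique(obs$source))
  s_idx <- match(obs$source, sources)
  cell_it <- (t_idx - 1L) * n + i_idx          # region-fastest vec index
  cell_is <- (s_idx - 1L) * n + i_idx
  x_nd <- as.numeric(!obs$is_dhs)
  tt <- t_c[t_idx]
  X <- cbind(1, tt, x_nd)

  Q <- build_icar_precision(graph)
  R <- build_rw1_precision(T_)
  G <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]   # sum-zero basis, n x (n-1)
  F_ <- qr.Q(qr(matrix(1, T_, 1)), complete = TRUE)[, -1, drop = FALSE] # T x (T-1)
  # the year effect is also orthogonal to linear time (beta1 owns the
  # global slope); the interaction only needs the sum-to-zero margins
  Fw <- qr.Q(qr(cbind(1, t_c)), complete = TRUE)[, -(1:2), drop = FALSE] # T x (T-2)
  B <- kronecker(F_, G)                                                  # nT x (n-1)(T-1)
  # joint fixed-effect + source-effect design (beta and gamma are
  # updated as one Gaussian block; they compete for the non-DHS level)
  C <- matrix(0, nrow(obs), n * length(sources))
  C[cbind(seq_len(nrow(obs)), cell_is)] <- 1
  W_ <- cbind(X, C)

  count_by <- function(idx, k, wts = rep(1, length(idx))) {
    out <- numeric(k); tmp <- tapply(wts, idx, sum)
    out[as.integer(names(tmp))] <- tmp
    out
  }
  list(
    y = obs$logit_q5, X = X, XtX = crossprod(X), tt = tt, x_nd = x_nd,
    i_idx = i_idx, t_idx = t_idx, s_idx = s_idx,
    cell_it = cell_it, cell_is = cell_is,
    n = n, T_ = T_, S = length(sources), sources = sources, t_c = t_c,
    G = G, F_ = F_, Fw = Fw, B = B, W_ = W_, WtW = crossprod(W_),
    Qc = crossprod(G, Q %*% G),
    Rc = crossprod(Fw, R %*% Fw),
    Kc = kronecker(crossprod(F_, R %*% F_), crossprod(G, Q %*% G)),
    Du_u = crossprod(G * sqrt(count_by(i_idx, n))),                # G' diag(n_i) G
    Du_v = crossprod(G * sqrt(count_by(i_idx, n, tt^2))),          # G' diag(sum t^2) G
    Dw = crossprod(Fw * sqrt(count_by(t_idx, T_))),
    Dd = crossprod(B * sqrt(count_by(cell_it, n * T_))),
    rank_u = n - 1, rank_w = T_ - 2, rank_d = (n - 1) * (T_ - 1),
    priors = priors
  )
}

# One Gibbs chain. Effects are parameterized as u = G eta_u etc., so the
# sum-to-zero constraints are built into the sampler.
run_mortality_chain <- function(pre, iterations, burnin, thin, seed, keep_effects) {
  with_seed(seed, {
    n <- pre$n; T_ <- pre$T_; S <- pre$S
    N <- length(pre$y)
    pr <- pre$priors
    beta_prec <- 1 / pr$beta_sd^2
    a0 <- pr$tau_shape; b0 <- pr$tau_rate

    # initial values: data-informed fixed effects, unit precisions scaled up
    beta <- c(mean(pre$y), 0, 0)
    eta_u <- rnorm(n - 1, 0, 0.01); eta_v <- rnorm(n - 1, 0, 0.001)
    eta_w <- rnorm(T_ - 2, 0, 0.01); eta_d <- rnorm((n - 1) * (T_ - 1), 0, 0.01)
    gamma <- numeric(n * S)
    taus <- c(u = 10, v = 100, w = 10, delta = 100, gamma = 10)
    sigma2 <- stats::var(pre$y) / 2 + 1e-4

    u <- drop(pre$G %*% eta_u); v <- drop(pre$G %*% eta_v)
    w <- drop(pre$Fw %*% eta_w); delta <- drop(pre$B %*% eta_d)
    part_beta <- drop(pre$X %*% beta)
    part_u <- u[pre$i_idx]; part_v <- v[pre$i_idx] * pre$tt
    part_w <- w[pre$t_idx]; part_d <- delta[pre$cell_it]
    part_g <- gamma[pre$cell_is]

    n_keep <- length(seq(burnin + 1, iterations, by = thin))
    out <- list(
      beta = matrix(NA_real_, n_keep, 3,
                    dimnames = list(NULL, c("beta0", "beta1", "beta2"))),
      sigma2 = matrix(NA_real_, n_keep, 1, dimnames = list(NULL, "sigma2")),
      tau = matrix(NA_real_, n_keep, 5,
                   dimnames = list(NULL, c("tau_u", "tau_v", "tau_w",
                                           "tau_delta", "tau_gamma"))),
      u = matrix(NA_real_, n_keep, n), v = matrix(NA_real_, n_keep, n),
      w = matrix(NA_real_, n_keep, T_),
      theta = matrix(NA_real_, n_keep, n * T_)
    )
    if (keep_effects) {
      out$delta <- matrix(NA_real_, n_keep, n * T_)
      out$gamma <- matrix(NA_real_, n_keep, n * S)
    }
    monitor <- matrix(NA_real_, iterations, 9)
    colnames(monitor) <- c("beta0", "beta1", "beta2", "sigma2",
                           "log_tau_u", "log_tau_v", "log_tau_w",
                           "log_tau_delta", "log_tau_gamma")

    sum_by <- function(x, idx, k) {
      res <- numeric(k)
      agg <- rowsum(x, idx)
      res[as.integer(rownames(agg))] <- agg
      res
    }
    draw_gaussian <- function(P, b) {
      ch <- chol(P)
      mu <- backsolve(ch, forwardsolve(t(ch), b))
      mu + backsolve(ch, rnorm(length(b)))
    }

    keep_row <- 0L
    for (it in seq_len(iterations)) {
      # joint (beta, gamma) block: a flat-ish prior on beta2 plus iid
      # gamma compete for the non-DHS level; updating them together
      # removes the strong cross-correlation a one-at-a-time scan mixes
      # through slowly
      r <- pre$y - part_u - part_v - part_w - part_d
      P <- pre$WtW / sigma2 +
        diag(c(rep(beta_prec, 3), rep(taus["gamma"], n * S)))
      bz <- draw_gaussian(P, crossprod(pre$W_, r) / sigma2)
      beta <- bz[1:3]
      gamma <- bz[-(1:3)]
      part_beta <- drop(pre$X %*% beta)
      part_g <- gamma[pre$cell_is]

      # u (CAR intercepts)
      r <- pre$y - part_beta - part_v - part_w - part_d - part_g
      b <- crossprod(pre$G, sum_by(r, pre$i_idx, n)) / sigma2
      eta_u <- draw_gaussian(taus["u"] * pre$Qc + pre$Du_u / sigma2, b)
      u <- drop(pre$G %*% eta_u); part_u <- u[pre$i_idx]

      # v (CAR slopes)
      r <- pre$y - part_beta - part_u - part_w - part_d - part_g
      b <- crossprod(pre$G, sum_by(r * pre$tt, pre$i_idx, n)) / sigma2
      eta_v <- draw_gaussian(taus["v"] * pre$Qc + pre$Du_v / sigma2, b)
      v <- drop(pre$G %*% eta_v); part_v <- v[pre$i_idx] * pre$tt

      # w (RW1 year effect, orthogonal to constant and linear time)
      r <- pre$y - part_beta - part_u - part_v - part_d - part_g
      b <- crossprod(pre$Fw, sum_by(r, pre$t_idx, T_)) / sigma2
      eta_w <- draw_gaussian(taus["w"] * pre$Rc + pre$Dw / sigma2, b)
      w <- drop(pre$Fw %*% eta_w); part_w <- w[pre$t_idx]

      # delta (space-time interaction)
      r <- pre$y - part_beta - part_u - part_v - part_w - part_g
      b <- crossprod(pre$B, sum_by(r, pre$cell_it, n * T_)) / sigma2
      eta_d <- draw_gaussian(taus["delta"] * pre$Kc + pre$Dd / sigma2, b)
      delta <- drop(pre$B %*% eta_d); part_d <- delta[pre$cell_it]

      # precisions (conjugate gamma; degrees of freedom = structure rank)
      taus["u"] <- rgamma(1, a0 + pre$rank_u / 2,
                          b0 + drop(crossprod(eta_u, pre$Qc %*% eta_u)) / 2)
      taus["v"] <- rgamma(1, a0 + pre$rank_u / 2,
                          b0 + drop(crossprod(eta_v, pre$Qc %*% eta_v)) / 2)
      taus["w"] <- rgamma(1, a0 + pre$rank_w / 2,
                          b0 + drop(crossprod(eta_w, pre$Rc %*% eta_w)) / 2)
      taus["delta"] <- rgamma(1, a0 + pre$rank_d / 2,
                              b0 + drop(crossprod(eta_d, pre$Kc %*% eta_d)) / 2)
      taus["gamma"] <- rgamma(1, a0 + (n * S) / 2, b0 + sum(gamma^2) / 2)

      # observation variance
      rss <- sum((pre$y - part_beta - part_u - part_v - part_w - part_d - part_g)^2)
      sigma2 <- 1 / rgamma(1, a0 + N / 2, b0 + rss / 2)

      monitor[it, ] <- c(beta, sigma2, log(taus))
      if (it > burnin && (it - burnin - 1L) %% thin == 0L) {
        keep_row <- keep_row + 1L
        out$beta[keep_row, ] <- beta
        out$sigma2[keep_row, ] <- sigma2
        out$tau[keep_row, ] <- taus
        out$u[keep_row, ] <- u
        out$v[keep_row, ] <- v
        out$w[keep_row, ] <- w
        # DHS-scale linear predictor on the full grid (beta2, gamma excluded)
        out$theta[keep_row, ] <- as.vector(
          outer(u, rep(1, T_)) + outer(v, pre$t_c) +
            matrix(beta[1] + beta[2] * pre$t_c + w, n, T_, byrow = TRUE) +
            matrix(delta, n, T_))
        if (keep_effects) {
          out$delta[keep_row, ] <- delta
          out$gamma[keep_row, ] <- gamma
        }
      }
    }
    list(samples = out, monitor = monitor[seq(burnin + 1, iterations), , drop = FALSE])
  })
}

# Split-R-hat over a list of per-chain matrices (iterations x scalars).
split_rhat <- function(monitor_list) {
  halves <- list()
  for (m in monitor_list) {
    h <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[seq(h + 1, 2 * h), , drop = FALSE]))
  }
  vapply(seq_len(ncol(monitor_list[[1]])), function(j) {
    seqs <- lapply(halves, function(m) m[, j])
    nn <- length(seqs[[1]])
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, var, numeric(1))
    W <- mean(vars)
    B <- nn * var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }, numeric(1)) |>
    setNames(colnames(monitor_list[[1]]))
}
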