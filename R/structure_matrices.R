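#' Structure matrices for the spatiotemporal priors
#'
#' The hierarchical mortality model uses three improper Gaussian (intrinsic)
#' priors, each defined by a structure matrix `Q` so that the prior density
#' is proportional to `exp(-tau/2 * x' Q x)`:
#'
#' * `build_icar_precision()` — the intrinsic conditional autoregressive
#'   (ICAR) structure on a region graph: the graph Laplacian, with node
#'   degree on the diagonal and -1 for each neighbour pair. Rank
#'   `n - 1` on a connected graph; its null space is the constant vector.
#' * `build_rw1_precision()` — the first-order random-walk structure over
#'   `T` years: the quadratic form is the sum of squared successive
#'   differences. Rank `T - 1`.
#' * `build_interaction_precision()` — the space-time interaction
#'   structure: the Kronecker product `RW1 (x) ICAR`, acting on the
#'   region-fastest vectorization of the region x year effect matrix.
#'   Null-space dimension `n + T - 1`; the sum-to-zero constraints over
#'   regions within each year and over years within each region make the
#'   interaction identifiable.
#'
#' @param graph A `region_graph` (connected).
#' @param n_years Number of years `T >= 2`.
#' @return A base `matrix` (`n x n`, `T x T`, or `nT x nT`).
#' @export
#' @examples
#' g <- make_region_graph(4, "ring")
#' build_icar_precision(g)
#' build_rw1_precision(3)
build_icar_precision <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  if (max(graph_components(graph)) > 1) {
    rlang::abort("ICAR structure requires a connected graph")
  }
  n <- n_regions(graph)
  Q <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[k]; j <- graph$edges$to[k]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
    Q[i, i] <- Q[i, i] + 1
    Q[j, j] <- Q[j, j] + 1
  }
  Q
}

#' @rdname build_icar_precision
#' @export
build_rw1_precision <- function(n_years) {
  stopifnot(n_years >= 2)
  T_ <- as.integer(n_years)
  Q <- matrix(0, T_, T_)
  for (t in seq_len(T_ - 1)) {
    Q[t, t] <- Q[t, t] + 1
    Q[t + 1, t + 1] <- Q[t + 1, t + 1] + 1
    Q[t, t + 1] <- Q[t, t + 1] - 1
    Q[t + 1, t] <- Q[t + 1, t] - 1
  }
  Q
}

#' @rdname build_icar_precision
#' @export
build_interaction_precision <- function(graph, n_years) {
  kronecker(build_rw1_precision(n_years), build_icar_precision(graph))
}

# Draw one sample from the improper Gaussian prior with structure Q and
# precision tau, constrained to the row space of Q (i.e. orthogonal to the
# null space, which imposes the usual sum-to-zero constraints). Uses the
# eigendecomposition of Q; eigenvalues below `tol` are treated as null.
sample_intrinsic <- function(eig, tau, tol = 1e-9) {
  pos <- eig$values > tol * max(eig$values)
  z <- rnorm(sum(pos)) / sqrt(tau * eig$values[pos])
  drop(eig$vectors[, pos, drop = FALSE] %*% z)
}

# As sample_intrinsic, but additionally conditioned on the linear
# constraints A x = 0 (conditioning by kriging with the generalized
# inverse as covariance) — used to keep the RW1 year effect orthogonal
# to the linear trend the fixed effects own.
sample_intrinsic_constrained <- function(eig, tau, A, tol = 1e-9) {
  x <- sample_intrinsic(eig, tau, tol)
  pos <- eig$values > tol * max(eig$values)
  V <- eig$vectors[, pos, drop = FALSE]
  Sigma <- V %*% (t(V) / (tau * eig$values[pos]))
  A <- matrix(A, ncol = length(x))
  SA <- Sigma %*% t(A)
  drop(x - SA %*% solve(A %*% SA, A %*% x))
}
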