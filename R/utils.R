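# Internal helpers: transforms, seed handling, provenance hashing.

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

#' Derive a child seed from a master seed and an operation tag
#'
#' Every stochastic operation in the package draws from its own stream,
#' seeded deterministically from a master seed and a short text tag naming
#' the operation. Reordering or omitting simulations therefore never
#' changes any one simulation's output.
#'
#' The rule: fold the UTF-8 bytes of the tag into a 31-bit integer with a
#' multiply-and-add (FNV-style) recurrence, then combine with the master
#' seed modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the operation (e.g. `"truth"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, "truth")
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 2166136261 %% m
  for (b in utf8ToInt(tag)) h <- (h * 16777619 + b) %% m
  as.integer((h + (as.numeric(seed) %% m) * 2654435761) %% m)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 31-bit FNV-style hash of a character vector, returned as 8 hex digits.
# Used for provenance headers only (not cryptographic).
fnv1a <- function(x) {
  stopifnot(is.character(x))
  h <- 2166136261 %% 2^31
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Clamp a proportion away from {0,1} before the logit transform.
# With a known effective sample size n the clamp is [1/(4n), 1 - 1/(4n)];
# without one it falls back to [0.001, 0.999].
clamp_proportion <- function(p, n_eff = NA_real_) {
  lo <- ifelse(is.finite(n_eff) & n_eff > 0, 1 / (4 * n_eff), 0.001)
  pmin(pmax(p, lo), 1 - lo)
}

`%||%` <- rlang::`%||%`

assert_df_has <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("%s is missing required column(s): %s",
                         what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
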