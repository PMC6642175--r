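# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Run code under a temporary RNG state.
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage substream seed from one master seed.
#'
#' Keeps stage draws independent: adding draws in one stage does not perturb
#' any other stage. Result always fits a 32-bit integer.
#' @noRd
substream_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 27361 + stage * 7919) %% 2147483647L
}

#' Truncated normal sampler via inverse CDF (vectorised).
#' @noRd
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

AA_ALPHABET_20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Squared-distance-free cross distance: all pairwise Euclidean distances
#' between the rows of two coordinate matrices.
#' @noRd
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
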