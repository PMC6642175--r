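# Dispensable interaction content: the Bayesian core.
#
# Missense mutations are assumed effectively neutral (N), mildly deleterious
# (M) or strongly detrimental (S), with literature priors P(N) = 0.27,
# P(M) = 0.53, P(S) = 0.20. Common mutations from healthy individuals stand
# in for N, Mendelian disease mutations for M, and S mutations are assumed
# quasi-null rather than edgetic, so P(E|S) = 0. From class-wise edgetic
# fractions P(E|N) = k_N/n_N and P(E|M) = k_M/n_M:
#
#   P(E)   = P(E|N) P(N) + P(E|M) P(M) + P(E|S) P(S)
#   P(N|E) = P(E|N) P(N) / P(E)
#
# and equivalently 1/P(N|E) = {P(E|M)/P(E|N)} {P(M)/P(N)} + 1, so a
# confidence interval for the ratio of the two proportions transforms
# directly into one for P(N|E). The ratio interval is the Katz log-scale
# interval; note the ratio's lower bound yields the upper bound of P(N|E).

#' Fitness-class priors for new missense mutations
#'
#' @param p_N,p_M,p_S Prior probabilities for a new missense mutation to be
#'   effectively neutral, mildly deleterious, or strongly detrimental.
#'   Defaults are the literature values 0.27 / 0.53 / 0.20.
#' @return Object of class `fitness_priors`.
#' @export
fitness_priors <- function(p_N = 0.27, p_M = 0.53, p_S = 0.20) {
  for (v in list(p_N, p_M, p_S)) {
    assert_that(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1,
                "priors must be probabilities in [0, 1]")
  }
  assert_that(abs(p_N + p_M + p_S - 1) <= 1e-9, "priors must sum to 1")
  structure(list(p_N = p_N, p_M = p_M, p_S = p_S), class = "fitness_priors")
}

#' Edgetic counts for the two mutation classes
#'
#' @param k_N,n_N Edgetic and total non-disease mutation counts.
#' @param k_M,n_M Edgetic and total disease mutation counts.
#' @return Object of class `edgetic_counts`.
#' @export
edgetic_counts <- function(k_N, n_N, k_M, n_M) {
  assert_that(n_N > 0 && n_M > 0, "totals n_N and n_M must be positive")
  assert_that(k_N >= 0 && k_N <= n_N && k_M >= 0 && k_M <= n_M,
              "edgetic counts must satisfy 0 <= k <= n")
  structure(list(k_N = k_N, n_N = n_N, k_M = k_M, n_M = n_M),
            class = "edgetic_counts")
}

#' @export
print.edgetic_counts <- function(x, ...) {
  cat(sprintf("<edgetic_counts> non-disease %d/%d (%.1f%%), disease %d/%d (%.1f%%)\n",
              x$k_N, x$n_N, 100 * x$k_N / x$n_N,
              x$k_M, x$n_M, 100 * x$k_M / x$n_M))
  invisible(x)
}

#' Probability that a new missense mutation is edgetic, P(E)
#'
#' @param counts An [edgetic_counts()] object.
#' @param priors A [fitness_priors()] object.
#' @param p_E_given_S Probability for strongly detrimental mutations to be
#'   edgetic (default 0: they are assumed quasi-null).
#' @return P(E).
#' @export
p_edgetic <- function(counts, priors = fitness_priors(), p_E_given_S = 0) {
  stopifnot(inherits(counts, "edgetic_counts"), inherits(priors, "fitness_priors"))
  (counts$k_N / counts$n_N) * priors$p_N +
    (counts$k_M / counts$n_M) * priors$p_M +
    p_E_given_S * priors$p_S
}

#' Dispensable interaction fraction, P(N|E)
#'
#' The probability that an edgetic mutation is effectively neutral — under
#' the one-disruption-per-edgetic-mutation reading, the fraction of the
#' interactome that is completely dispensable. Computed on exact count
#' fractions, never on rounded percentages.
#'
#' @inheritParams p_edgetic
#' @return P(N|E).
#' @export
p_dispensable <- function(counts, priors = fitness_priors(), p_E_given_S = 0) {
  if (counts$k_N == 0) {
    warning("k_N = 0: estimated dispensable fraction is 0")
    return(0)
  }
  pe <- p_edgetic(counts, priors, p_E_given_S)
  assert_that(pe > 0, "P(E) = 0: dispensable fraction undefined")
  (counts$k_N / counts$n_N) * priors$p_N / pe
}

#' 95% confidence interval for the dispensable fraction
#'
#' Katz log-scale interval for the ratio of two binomial proportions
#' r = P(E|M)/P(E|N): log r +/- z * sqrt(1/k_M - 1/n_M + 1/k_N - 1/n_N),
#' with each ratio bound mapped through 1/P(N|E) = r P(M)/P(N) + 1. The
#' ratio's lower bound yields P(N|E)'s upper bound and vice versa.
#'
#' @inheritParams p_edgetic
#' @param z Normal quantile (default 1.96).
#' @param continuity_correction Add 0.5 to each cell of the 2x2 table when a
#'   zero edgetic count would otherwise make the interval undefined.
#' @return Named vector `c(lo, hi)` on the P(N|E) scale.
#' @export
ci95_dispensable <- function(counts, priors = fitness_priors(), z = 1.96,
                             continuity_correction = FALSE) {
  k_N <- counts$k_N; n_N <- counts$n_N
  k_M <- counts$k_M; n_M <- counts$n_M
  if (k_N == 0 || k_M == 0) {
    if (!continuity_correction) {
      stop("zero edgetic count: interval undefined; set continuity_correction = TRUE for a Haldane-style corrected interval",
           call. = FALSE)
    }
    k_N <- k_N + 0.5; k_M <- k_M + 0.5
    n_N <- n_N + 1; n_M <- n_M + 1
  }
  r <- (k_M / n_M) / (k_N / n_N)
  se <- sqrt(1 / k_M - 1 / n_M + 1 / k_N - 1 / n_N)
  ratio_to_p <- function(rr) 1 / (rr * priors$p_M / priors$p_N + 1)
  c(lo = ratio_to_p(exp(log(r) + z * se)),
    hi = ratio_to_p(exp(log(r) - z * se)))
}

#' Full dispensability estimate
#'
#' Bundles P(E), P(N|E) and the 95% confidence interval, recording the counts
#' and priors used and the calculation variant: `standard` (edgetic counts),
#' `mono_edgetic` (counts are mono-edgetic tallies), or
#' `quasi_null_as_edgetic` (edgetic counts include quasi-null calls).
#'
#' @inheritParams ci95_dispensable
#' @param variant Calculation variant label.
#' @param p_E_given_S Probability for strongly detrimental mutations to be
#'   edgetic (default 0).
#' @return Object of class `dispensability_estimate`.
#' @export
estimate_dispensability <- function(counts, priors = fitness_priors(),
                                    variant = c("standard", "mono_edgetic",
                                                "quasi_null_as_edgetic"),
                                    p_E_given_S = 0, z = 1.96,
                                    continuity_correction = FALSE) {
  variant <- match.arg(variant)
  structure(
    list(p_edgetic = p_edgetic(counts, priors, p_E_given_S),
         p_dispensable = p_dispensable(counts, priors, p_E_given_S),
         ci95 = ci95_dispensable(counts, priors, z = z,
                                 continuity_correction = continuity_correction),
         counts = counts, priors = priors, variant = variant),
    class = "dispensability_estimate"
  )
}

#' @export
print.dispensability_estimate <- function(x, ...) {
  cat(sprintf("<dispensability_estimate> variant: %s\n", x$variant))
  cat(sprintf("  P(E|N) = %d/%d = %.1f%%   P(E|M) = %d/%d = %.1f%%\n",
              x$counts$k_N, x$counts$n_N, 100 * x$counts$k_N / x$counts$n_N,
              x$counts$k_M, x$counts$n_M, 100 * x$counts$k_M / x$counts$n_M))
  cat(sprintf("  P(E)    = %.1f%%\n", 100 * x$p_edgetic))
  cat(sprintf("  P(N|E)  = %.1f%%  (95%% CI %.1f-%.1f%%)\n",
              100 * x$p_dispensable, 100 * x$ci95[["lo"]], 100 * x$ci95[["hi"]]))
  invisible(x)
}
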