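#' Exact degree of fineness of the majority reduction
#'
#' Models the number of erring raters on a case as a Poisson-binomial variable
#' with per-rater error rates `error_rates`; the majority label is wrong when
#' a strict majority errs. The tail probability is computed by the standard
#' Poisson-binomial dynamic programme over raters (O(m^2)), which is
#' mathematically identical to enumerating all error patterns but exponentially
#' cheaper. The degree of fineness is `1 - P(error)`, the expected fraction of
#' majority labels matching the (unknown) truth under independent raters with
#' constant error rates.
#'
#' For an even panel the strict-majority threshold leaves a possible tie;
#' the tie is counted as an error with probability `even_tie_prob`
#' (default 1/2, an indifferent tie-break).
#'
#' @param error_rates numeric vector of per-rater error rates \eqn{\eta_i} in
#'   `[0, 1)`.
#' @param n_cases number of cases (the per-case error is constant; only the
#'   bookkeeping in the result changes).
#' @param even_tie_prob probability that a tie resolves to the wrong label
#'   when the panel size is even; must be supplied (has a default) because the
#'   majority model presumes an odd panel.
#' @return List of class `fineness_result` with `p_error`, `fineness`,
#'   `method = "exact_poisson_binomial"`, `n_raters`, `per_case`.
#' @examples
#' fineness_majority_exact(rep(0.11, 3))$fineness # 0.966362
#' @export
fineness_majority_exact <- function(error_rates, n_cases = 1L,
                                    even_tie_prob = 0.5) {
  eta <- as.numeric(error_rates)
  if (any(eta < 0 | eta >= 1)) stop("error rates must lie in [0, 1)")
  m <- length(eta)
  pmf <- poisson_binomial_pmf(eta)          # P(#errors = 0..m)
  if (m %% 2L == 1L) {
    p_err <- sum(pmf[((m + 1L) / 2L + 1L):(m + 1L)])
  } else {
    if (is.null(even_tie_prob))
      stop("even panel size requires a tie-break probability")
    strict <- if (m / 2L + 1L <= m) sum(pmf[(m / 2L + 2L):(m + 1L)]) else 0
    p_err <- strict + even_tie_prob * pmf[m / 2L + 1L]
  }
  p_err <- min(max(p_err, 0), 1)
  structure(list(p_error = p_err, fineness = 1 - p_err,
                 method = "exact_poisson_binomial",
                 n_raters = m,
                 per_case = rep(p_err, n_cases)),
            class = "fineness_result")
}

# PMF of the number of successes among independent Bernoulli(eta_i) trials,
# by iterative convolution. Returns a vector of length m + 1 (counts 0..m).
poisson_binomial_pmf <- function(eta) {
  pmf <- 1
  for (e in eta) pmf <- c(pmf * (1 - e), 0) + c(0, pmf * e)
  pmf
}

#' @export
print.fineness_result <- function(x, ...) {
  cat(sprintf("Degree of fineness: %.6f (P(error) = %.6f, %s, m = %d)\n",
              x$fineness, x$p_error, x$method, x$n_raters))
  invisible(x)
}

#' Chernoff-style upper bound on the majority error probability
#'
#' Evaluates \eqn{\exp\{-\frac{m+1}{2}\log\frac{m+1}{2\mu}\}} with
#' \eqn{\mu = \sum_i \eta_i}. The bound is vacuous (at or above 1) when
#' \eqn{\mu \ge (m+1)/2}, and because terms were dropped in its derivation it
#' can fall below the exact error probability for small panels; it is reported
#' for reference and never used by the rater-count planner.
#'
#' @inheritParams fineness_majority_exact
#' @return List with `bound`, `mu`, `vacuous`.
#' @examples
#' fineness_majority_bound(rep(0.19, 3))$bound # about 0.0812
#' @export
fineness_majority_bound <- function(error_rates) {
  eta <- as.numeric(error_rates)
  m <- length(eta)
  mu <- sum(eta)
  if (mu == 0) return(list(bound = 0, mu = 0, vacuous = FALSE))
  bound <- exp(-((m + 1) / 2) * log((m + 1) / (2 * mu)))
  list(bound = bound, mu = mu, vacuous = bound >= 1)
}

#' Error probability of the probabilistic reduction (binary labels, 1 resample)
#'
#' For a binary alphabet with observed vote counts `m0` and `m1`
#' (`m0 + m1 = m`) and a common rater error rate `eta`, the probability that a
#' label resampled from the vote shares is wrong is
#' \deqn{p_0 \binom{m}{m_0} \eta^{m_0} (1-\eta)^{m-m_0} +
#'       p_1 \binom{m}{m_1} \eta^{m_1} (1-\eta)^{m-m_1}}
#' with \eqn{p_i = m_i / m}. Only defined for binary alphabets.
#'
#' @param m0,m1 vote counts for the two labels.
#' @param eta common per-rater error rate.
#' @return The single-resample error probability.
#' @examples
#' prob_reduction_error(1, 2, 0.2) # 0.192
#' @export
prob_reduction_error <- function(m0, m1, eta) {
  m <- m0 + m1
  if (m < 1L) stop("at least one vote required")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  p0 <- m0 / m; p1 <- m1 / m
  p0 * choose(m, m0) * eta^m0 * (1 - eta)^(m - m0) +
    p1 * choose(m, m1) * eta^m1 * (1 - eta)^(m - m1)
}

#' Error probability of the resampled-majority probabilistic reduction
#'
#' Resampling the probabilistic reduction `k` times and taking the majority of
#' the resamples yields the binomial tail
#' \deqn{\sum_{i=(k+1)/2}^{k} \binom{k}{i} (P^1)^i (1-P^1)^{k-i}.}
#' For `k = 1` this is the single-resample error. When `P^1 < 1/2` the error
#' decreases in `k` and approaches the exact majority error.
#'
#' @param p1_err single-resample error probability in `[0, 1]`.
#' @param k odd number of resamples.
#' @return The k-resample error probability.
#' @examples
#' prob_reduction_error_k(0.192, 3) # about 0.09644
#' @export
prob_reduction_error_k <- function(p1_err, k) {
  if (k %% 2L == 0L) stop("k must be odd")
  if (p1_err < 0 || p1_err > 1) stop("p1_err must lie in [0, 1]")
  if (k == 1L) return(p1_err)
  stats::pbinom((k + 1) / 2 - 1, k, p1_err, lower.tail = FALSE)
}

#' Smallest odd panel reaching a target degree of fineness
#'
#' Sweeps odd panel sizes m = 1, 3, 5, ... and returns the first for which the
#' exact majority-reduction degree of fineness of m raters with the common
#' `accuracy` reaches `target`. Raters at or below coin-flip accuracy can
#' never reach a non-trivial target; that and targets unreachable within
#' `max_raters` are flagged explicitly.
#'
#' @param accuracy common rater accuracy.
#' @param target required degree of fineness, in `(0, 1)`.
#' @param max_raters hard cap on the sweep (default 99).
#' @return List with `n_raters` (NA when unreachable), `fineness` achieved,
#'   `reachable`.
#' @examples
#' min_raters_for_fineness(0.81, 0.95)$n_raters # 7
#' @export
min_raters_for_fineness <- function(accuracy, target = 0.95,
                                    max_raters = 99L) {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must lie in [0, 1]")
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  if (accuracy <= 0.5 && accuracy < target)
    return(list(n_raters = NA_integer_, fineness = NA_real_,
                reachable = FALSE))
  eta <- 1 - accuracy
  for (m in seq(1L, max_raters, by = 2L)) {
    phi <- fineness_majority_exact(rep(eta, m))$fineness
    if (phi >= target)
      return(list(n_raters = m, fineness = phi, reachable = TRUE))
  }
  list(n_raters = NA_integer_, fineness = phi, reachable = FALSE)
}
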