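# Independent oracles used to cross-check the package implementations.
# Each is written by a different route than the function it checks.

# Majority-reduction error probability by exhaustive enumeration of all 2^m
# error patterns; ties (even panels) count as error with `tie_prob`.
brute_majority_error <- function(eta, tie_prob = 0.5) {
  m <- length(eta)
  p_err <- 0
  for (mask in 0:(2^m - 1)) {
    bits <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    prob <- prod(ifelse(bits, eta, 1 - eta))
    k <- sum(bits)
    if (2 * k > m) p_err <- p_err + prob
    else if (2 * k == m) p_err <- p_err + tie_prob * prob
  }
  p_err
}

# Minimum-cost injective assignment by brute force over all permutations.
brute_assignment_cost <- function(cost) {
  nG <- nrow(cost); nP <- ncol(cost)
  cols <- utils::combn(nP, nG, simplify = FALSE)
  best <- Inf
  for (cset in cols) {
    perms <- perm_all(cset)
    for (p in perms) {
      v <- sum(cost[cbind(seq_len(nG), p)])
      if (v < best) best <- v
    }
  }
  best
}

perm_all <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perm_all(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Fleiss kappa by explicit pair counting per case (vs the category-count
# formula in the package).
oracle_fleiss <- function(labels) {
  n <- nrow(labels); m <- ncol(labels)
  agree <- apply(labels, 1L, function(lab) {
    cnt <- 0L
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (lab[i] == lab[j]) cnt <- cnt + 1L
    cnt / choose(m, 2)
  })
  p_bar <- mean(agree)
  p_j <- table(factor(labels)) / (n * m)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

# Krippendorff alpha (nominal) directly from within-unit pairwise
# disagreement rates (vs the package's coincidence-matrix route).
oracle_alpha <- function(labels) {
  n_units <- nrow(labels)
  vals <- as.vector(labels)
  do_num <- 0; do_den <- 0
  for (u in seq_len(n_units)) {
    lab <- labels[u, ]
    mu <- length(lab)
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i == j) next
      do_num <- do_num + (lab[i] != lab[j]) / (mu - 1)
      do_den <- do_den + 1 / (mu - 1)
    }
  }
  d_o <- do_num / do_den
  ntot <- length(vals)
  d_e <- 0
  for (a in vals) for (b in vals) d_e <- d_e + (a != b)
  d_e <- (d_e - 0) / (ntot * (ntot - 1))  # exclude self-pairs: a==b on them
  1 - d_o / d_e
}

# Degree of concordance by direct triple loop over Eq-style sums (vs the
# package engine and the evidence-theory route).
oracle_sigma <- function(labels, conf) {
  n <- nrow(labels); m <- ncol(labels)
  tot <- 0
  for (x in seq_len(n)) {
    s <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (labels[x, i] == labels[x, j]) s <- s + conf[x, i] * conf[x, j]
    tot <- tot + s / choose(m, 2)
  }
  tot / n
}

# Random complete panel with confidences, for property sweeps.
random_panel <- function(n_cases, m, alphabet = c("A", "B", "C")) {
  labels <- matrix(sample(alphabet, n_cases * m, replace = TRUE), n_cases, m)
  conf <- matrix(stats::runif(n_cases * m), n_cases, m)
  d <- diamond_standard(labels, alphabet = alphabet)
  cm <- confidence_matrix(matrix(1, n_cases, m), scale_min = 0, scale_max = 1)
  cm$corrected <- conf
  list(d = d, conf = cm, labels = labels, conf_mat = conf)
}
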