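#' Simulate a multi-rater annotation panel with known ground truth
#'
#' Generates true labels from a class prior, then lets each rater label each
#' case correctly with their configured accuracy; wrong labels are uniform
#' over the remaining alphabet. Confidence reports are drawn from a scaled
#' Beta conditional on correctness (by default mean 0.8 when correct, 0.6 when
#' incorrect — a moderate confidence-accuracy coupling), so the simulated
#' panel exercises every reliability and fineness metric end-to-end.
#'
#' Error correlation: with probability `rho_err` a case is "shared-difficulty"
#' and all raters judge it against one common latent draw (so raters err
#' together); otherwise errors are independent. Marginal per-rater accuracies
#' are preserved either way, which is exactly the regime where the fineness
#' model's independence assumption fails while its inputs stay correct.
#'
#' Repeated presentations: `n_repeated` cases are re-presented so that each
#' appears `k_rep` times in total, sharing a repetition group; the label is
#' the rater's original call and the reported confidence is jittered per
#' presentation with Gaussian noise of sd `rep_conf_sd` (clipped to `[0,1]`),
#' emulating imperfect self-consistency. The default sd of 0.09 yields an
#' average intra-rater variability near 0.08 at `k_rep = 5`, the
#' self-consistency level typical of trained raters.
#'
#' @param n_cases number of distinct cases.
#' @param accuracies per-rater accuracy vector (length = number of raters).
#' @param alphabet label alphabet (default binary `c("neg", "pos")`).
#' @param prior class prior over the alphabet (default uniform).
#' @param rho_err shared-difficulty probability in `[0, 1)`.
#' @param conf_correct,conf_incorrect `c(mean, precision)` of the Beta
#'   confidence model given a correct / incorrect label.
#' @param n_repeated number of cases receiving repeated presentations.
#' @param k_rep presentations per repeated case (at least 2).
#' @param rep_conf_sd per-presentation confidence jitter sd.
#' @param seed integer seed; the whole draw is reproducible given it.
#' @return List with `truth` (named by case id), `diamond`
#'   (a [diamond_standard()] including the repeated rows), and `confidence`
#'   (the matching [confidence_matrix()] holding corrected values; `raw` holds
#'   the same values quantised onto a 6-level scale).
#' @export
simulate_panel <- function(n_cases, accuracies, alphabet = c("neg", "pos"),
                           prior = NULL, rho_err = 0,
                           conf_correct = c(mean = 0.8, precision = 10),
                           conf_incorrect = c(mean = 0.6, precision = 10),
                           n_repeated = 0L, k_rep = 5L, rep_conf_sd = 0.09,
                           seed = NULL) {
  m <- length(accuracies)
  if (any(accuracies <= 0 | accuracies > 1))
    stop("accuracies must lie in (0, 1]")
  if (rho_err < 0 || rho_err >= 1) stop("rho_err must lie in [0, 1)")
  if (is.null(prior)) prior <- rep(1 / length(alphabet), length(alphabet))
  if (length(prior) != length(alphabet) || abs(sum(prior) - 1) > 1e-9 ||
      any(prior < 0))
    stop("prior must be a probability vector over the alphabet")
  if (n_repeated > 0L && k_rep < 2L)
    stop("repeated cases need at least 2 presentations")

  with_seed(seed, {
    truth <- sample(alphabet, n_cases, replace = TRUE, prob = prior)
    case_ids <- sprintf("case%04d", seq_len(n_cases))
    names(truth) <- case_ids

    # shared vs independent latent draws decide correctness
    shared_u <- stats::runif(n_cases)
    use_shared <- stats::runif(n_cases) < rho_err
    labels <- matrix(NA_character_, n_cases, m)
    correct <- matrix(NA, n_cases, m)
    for (j in seq_len(m)) {
      u <- ifelse(use_shared, shared_u, stats::runif(n_cases))
      ok <- u < accuracies[j]
      correct[, j] <- ok
      wrong <- vapply(truth, function(y) {
        others <- setdiff(alphabet, y)
        if (length(others) == 1L) others else sample(others, 1L)
      }, character(1))
      labels[, j] <- ifelse(ok, truth, wrong)
    }

    rbeta_mp <- function(n, mp) {
      a <- mp[[1]] * mp[[2]]; b <- (1 - mp[[1]]) * mp[[2]]
      stats::rbeta(n, a, b)
    }
    confidence <- matrix(0, n_cases, m)
    confidence[correct] <- rbeta_mp(sum(correct), conf_correct)
    confidence[!correct] <- rbeta_mp(sum(!correct), conf_incorrect)

    repetition_group <- rep(NA_character_, n_cases)
    if (n_repeated > 0L) {
      rep_idx <- sample.int(n_cases, n_repeated)
      repetition_group[rep_idx] <- case_ids[rep_idx]
      extra_rows <- rep(rep_idx, each = k_rep - 1L)
      jitter <- matrix(stats::rnorm(length(extra_rows) * m, 0, rep_conf_sd),
                       ncol = m)
      labels <- rbind(labels, labels[extra_rows, , drop = FALSE])
      confidence <- rbind(confidence,
                          pmin(pmax(confidence[extra_rows, , drop = FALSE] +
                                      jitter, 0), 1))
      case_ids <- c(case_ids, case_ids[extra_rows])
      repetition_group <- c(repetition_group, case_ids[
        (n_cases + 1L):length(case_ids)])
    }

    d <- diamond_standard(labels, alphabet = alphabet, case_ids = case_ids,
                          rater_ids = sprintf("rater%02d", seq_len(m)),
                          repetition_group = repetition_group)
    raw <- round(confidence * 5) + 1  # 6-level ordinal rendering
    cm <- confidence_matrix(raw, scale_min = 1, scale_max = 6, n_levels = 6)
    cm$corrected <- confidence     # keep the exact simulated values
    cm$correction <- "simulated"
    dimnames(cm$raw) <- dimnames(cm$corrected) <- dimnames(d$labels)
    list(truth = truth, diamond = d, confidence = cm)
  })
}

#' Simulate a feature dataset from a Gaussian mixture
#'
#' @param n_instances number of rows.
#' @param means matrix of component means (components x features), or a
#'   vector for a single component.
#' @param covs list of covariance matrices (one per component), a single
#'   matrix recycled to all components, or a scalar variance.
#' @param weights mixture weights (default uniform).
#' @param seed integer seed.
#' @return Numeric feature matrix with a `component` attribute recording each
#'   row's mixture component.
#' @export
simulate_features <- function(n_instances, means, covs = 1, weights = NULL,
                              seed = NULL) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  k <- nrow(means); d <- ncol(means)
  if (is.numeric(covs) && is.null(dim(covs)) && length(covs) == 1L)
    covs <- diag(covs, d)
  if (is.matrix(covs)) covs <- rep(list(covs), k)
  if (length(covs) != k) stop("one covariance per mixture component required")
  for (S in covs) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8)) stop("covariance must be positive semi-definite")
  }
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("weights must be a probability vector")
  with_seed(seed, {
    comp <- sample.int(k, n_instances, replace = TRUE, prob = weights)
    X <- matrix(0, n_instances, d)
    for (g in seq_len(k)) {
      idx <- which(comp == g)
      if (length(idx) > 0L)
        X[idx, ] <- MASS::mvrnorm(length(idx), means[g, ], covs[[g]])
    }
    rownames(X) <- sprintf("i%04d", seq_len(n_instances))
    colnames(X) <- sprintf("f%02d", seq_len(d))
    attr(X, "component") <- comp
    X
  })
}

#' Split a feature dataset into a disjoint pair (P, G)
#'
#' Draws `n_g` rows into `G`; the remainder is `P`. With a fixed seed the
#' split is reproducible.
#'
#' @param X feature matrix.
#' @param n_g size of the smaller subset.
#' @param seed integer seed.
#' @return List with matrices `P` and `G` (disjoint, covering `X`).
#' @export
subset_split <- function(X, n_g, seed = NULL) {
  X <- as_feature_matrix(X)
  if (n_g < 1L || n_g >= nrow(X)) stop("n_g must lie in [1, nrow(X) - 1]")
  with_seed(seed, {
    g <- sort(sample.int(nrow(X), n_g))
    list(P = X[-g, , drop = FALSE], G = X[g, , drop = FALSE])
  })
}
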