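#' Chance-discounted agreement between two raters on one case
#'
#' The genuine-agreement credit for a pair of raters on a case is zero when
#' their labels differ, and the product of their corrected confidences when
#' they match: agreement is only trusted to the extent both raters claim to
#' have decided rather than guessed.
#'
#' @param label_i,label_j the two labels assigned to the case.
#' @param c_i,c_j corrected confidences in `[0, 1]`.
#' @return Numeric agreement value in `[0, 1]`; `NA` if either label is `NA`.
#' @examples
#' pair_agreement("A", "A", 0.8, 0.9) # 0.72
#' pair_agreement("A", "B", 0.8, 0.9) # 0
#' @export
pair_agreement <- function(label_i, label_j, c_i, c_j) {
  if (any(c(c_i, c_j) < 0 | c(c_i, c_j) > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]")
  ifelse(is.na(label_i) | is.na(label_j), NA_real_,
         ifelse(label_i == label_j, c_i * c_j, 0))
}

#' Conditional probability that two agreeing raters are both correct
#'
#' Default model: raters err independently and spread errors uniformly over
#' the remaining labels, so given agreement the probability both are correct is
#' \deqn{\frac{a_i a_j}{a_i a_j + (1-a_i)(1-a_j)/(|Y|-1)}.}
#'
#' @param a_i,a_j rater accuracies.
#' @param n_labels alphabet size (at least 2).
#' @return Probability in `[0, 1]`, vectorised over the accuracy arguments.
#' @examples
#' pair_correct_probability(0.8, 0.8, 2) # 0.64 / 0.68
#' @export
pair_correct_probability <- function(a_i, a_j, n_labels) {
  if (n_labels < 2) stop("n_labels must be at least 2")
  both <- a_i * a_j
  both / (both + (1 - a_i) * (1 - a_j) / (n_labels - 1))
}

# Per-case engine shared by sigma and rho. `pair_weight` is an m x m matrix of
# multipliers (all 1 for sigma). Pairwise-complete: pairs with a missing label
# are dropped from that case's numerator and denominator.
concordance_per_case <- function(d, conf, pair_weight = NULL) {
  m <- d$n_raters
  if (m < 2L) stop("concordance requires at least 2 raters")
  cc <- conf$corrected
  if (!identical(dim(cc), dim(d$labels)))
    stop("confidence matrix shape does not match the Diamond Standard")
  if (is.null(pair_weight)) pair_weight <- matrix(1, m, m)
  vals <- numeric(d$n_cases)
  keep <- logical(d$n_cases)
  for (x in seq_len(d$n_cases)) {
    lab <- d$labels[x, ]
    cx <- cc[x, ]
    acc <- 0; npair <- 0L
    for (i in seq_len(m - 1L)) {
      if (is.na(lab[i])) next
      for (j in (i + 1L):m) {
        if (is.na(lab[j])) next
        npair <- npair + 1L
        if (lab[i] == lab[j])
          acc <- acc + cx[i] * cx[j] * pair_weight[i, j]
      }
    }
    keep[x] <- npair > 0L
    vals[x] <- if (npair > 0L) acc / npair else NA_real_
  }
  list(per_case = vals, keep = keep)
}

#' Degree of concordance (sigma)
#'
#' The mean, over cases, of the pair-count-normalised sum of chance-discounted
#' pair agreements [pair_agreement()]. With a complete panel the normaliser is
#' \eqn{\binom{m}{2}}; with missing annotations only pairwise-complete pairs
#' enter numerator and denominator.
#'
#' @param d a `diamond_standard`.
#' @param conf the accompanying `confidence_matrix`.
#' @return List with `sigma` and `per_case` (per-case contributions).
#' @export
degree_of_concordance <- function(d, conf) {
  eng <- concordance_per_case(d, conf)
  list(sigma = mean(eng$per_case[eng$keep]),
       per_case = eng$per_case)
}

# Normalise the pluggable pair-correctness specification into an m x m matrix.
resolve_pair_correct <- function(pair_correct, panel, n_labels, rater_ids) {
  m <- length(rater_ids)
  if (is.null(pair_correct)) {
    if (is.null(panel)) stop("weighted concordance needs a rater panel or an ",
                             "explicit `pair_correct`")
    a <- panel$accuracy[match(rater_ids, panel$rater_id)]
    if (anyNA(a)) stop("panel is missing accuracies for some raters")
    return(outer(a, a, pair_correct_probability, n_labels = n_labels))
  }
  if (is.matrix(pair_correct)) {
    if (!all(dim(pair_correct) == c(m, m)))
      stop("pair_correct matrix must be m x m")
    return(pair_correct)
  }
  if (is.function(pair_correct)) {
    a <- panel$accuracy[match(rater_ids, panel$rater_id)]
    return(outer(a, a, pair_correct, n_labels))
  }
  if (is.numeric(pair_correct) && length(pair_correct) == 1L)
    return(matrix(pair_correct, m, m))
  stop("pair_correct must be NULL, a constant, a function, or an m x m matrix")
}

#' Degree of weighted concordance (rho)
#'
#' The degree of concordance with every pair agreement additionally weighted by
#' the probability that the agreeing labels are correct (given the agreement).
#' With pair-correctness probabilities at most 1, `rho <= sigma`.
#'
#' @inheritParams degree_of_concordance
#' @param panel a [rater_panel()] supplying per-rater accuracies.
#' @param pair_correct optional override of the pair-correctness model: a
#'   constant, a function `(a_i, a_j, n_labels)`, or an m x m matrix. `NULL`
#'   uses [pair_correct_probability()] on the panel accuracies.
#' @return List with `rho` and `per_case`.
#' @export
degree_of_weighted_concordance <- function(d, conf, panel = NULL,
                                           pair_correct = NULL) {
  w <- resolve_pair_correct(pair_correct, panel, length(d$alphabet),
                            d$rater_ids)
  eng <- concordance_per_case(d, conf, pair_weight = w)
  list(rho = mean(eng$per_case[eng$keep]),
       per_case = eng$per_case)
}

#' Intra-rater variability from repeated case presentations
#'
#' For each rater r and repeated case x presented k times, the intra-rater
#' variability is the half-width-style 95% interval
#' \eqn{irv(x, r) = 1.96\, s_r(x) / \sqrt{k}}, where \eqn{s_r(x)} is the sample
#' standard deviation of the k reported (corrected) confidences. A rater's
#' average irv is the mean over the repeated cases.
#'
#' @param d a `diamond_standard` with a non-trivial `repetition_group`.
#' @param conf the accompanying `confidence_matrix`.
#' @return List of class `intra_rater_variability` with `per_case` (data.frame
#'   rater_id, group, k, irv) and `per_rater` (named numeric vector).
#' @export
intra_rater_variability <- function(d, conf) {
  stopifnot(inherits(d, "diamond_standard"))
  if (is.null(d$repetition_group) || all(is.na(d$repetition_group)))
    stop("no repetition groups declared in this Diamond Standard")
  groups <- unique(stats::na.omit(d$repetition_group))
  rows <- lapply(groups, function(g) {
    idx <- which(!is.na(d$repetition_group) & d$repetition_group == g)
    k <- length(idx)
    if (k < 2L) stop("repetition group '", g, "' has fewer than 2 presentations")
    data.frame(rater_id = d$rater_ids, group = g, k = k,
               irv = vapply(seq_len(d$n_raters), function(j) {
                 1.96 * stats::sd(conf$corrected[idx, j]) / sqrt(k)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  per_rater <- vapply(split(per_case$irv, per_case$rater_id), mean, numeric(1))
  per_rater <- per_rater[d$rater_ids]
  structure(list(per_case = per_case, per_rater = per_rater),
            class = "intra_rater_variability")
}

#' Interval-valued degree of weighted concordance
#'
#' Evaluates rho at the confidence matrices obtained by shifting every
#' confidence of rater r down and up by that rater's average intra-rater
#' variability (clipping into `[0,1]`), giving a robust interval
#' `[rho_lo, rho_hi]` around the point estimate. Because the agreement credit
#' is a product of confidences, the interval midpoint slightly exceeds the
#' point estimate (by the squared shift); both are reported.
#'
#' @inheritParams degree_of_weighted_concordance
#' @param irv an [intra_rater_variability()] result, or a named/numeric vector
#'   of per-rater irv values. `NULL` computes it from the repetition groups.
#' @return List of class `rho_interval` with `lo`, `hi`, `midpoint`, `point`.
#' @export
interval_rho <- function(d, conf, panel = NULL, irv = NULL,
                         pair_correct = NULL) {
  if (is.null(irv)) irv <- intra_rater_variability(d, conf)
  shift <- if (inherits(irv, "intra_rater_variability")) irv$per_rater else irv
  if (length(shift) == 1L) shift <- rep(shift, d$n_raters)
  if (length(shift) != d$n_raters)
    stop("irv must supply one value per rater")
  shift_mat <- matrix(shift, nrow = d$n_cases, ncol = d$n_raters, byrow = TRUE)
  clipped <- function(x) pmin(pmax(x, 0), 1)
  conf_lo <- conf; conf_lo$corrected <- clipped(conf$corrected - shift_mat)
  conf_hi <- conf; conf_hi$corrected <- clipped(conf$corrected + shift_mat)
  lo <- degree_of_weighted_concordance(d, conf_lo, panel, pair_correct)$rho
  hi <- degree_of_weighted_concordance(d, conf_hi, panel, pair_correct)$rho
  pt <- degree_of_weighted_concordance(d, conf, panel, pair_correct)$rho
  structure(list(lo = lo, hi = hi, midpoint = (lo + hi) / 2, point = pt),
            class = "rho_interval")
}

#' @export
print.rho_interval <- function(x, ...) {
  cat(sprintf("rho interval [%.4f, %.4f]; midpoint %.4f; point estimate %.4f\n",
              x$lo, x$hi, x$midpoint, x$point))
  invisible(x)
}

#' Full concordance report for an annotated panel
#'
#' Convenience wrapper computing sigma, rho, the irv-based interval (when
#' repetition groups are present), and per-case contributions in one call.
#'
#' @inheritParams degree_of_weighted_concordance
#' @return List of class `concordance_result` with `sigma`, `rho`,
#'   `rho_interval` (or `NULL`), and a `per_case` data.frame.
#' @export
concordance <- function(d, conf, panel = NULL, pair_correct = NULL) {
  sig <- degree_of_concordance(d, conf)
  rho <- if (!is.null(panel) || !is.null(pair_correct))
    degree_of_weighted_concordance(d, conf, panel, pair_correct) else NULL
  ri <- NULL
  if (!is.null(rho) && !is.null(d$repetition_group) &&
      any(!is.na(d$repetition_group)))
    ri <- interval_rho(d, conf, panel, pair_correct = pair_correct)
  structure(
    list(sigma = sig$sigma,
         rho = if (is.null(rho)) NA_real_ else rho$rho,
         rho_interval = ri,
         per_case = data.frame(case_id = d$case_ids,
                               sigma = sig$per_case,
                               rho = if (is.null(rho)) NA_real_ else rho$per_case,
                               stringsAsFactors = FALSE)),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("sigma = %.4f", x$sigma))
  if (!is.na(x$rho)) cat(sprintf(", rho = %.4f", x$rho))
  cat("\n")
  if (!is.null(x$rho_interval)) print(x$rho_interval)
  invisible(x)
}

#' Baseline agreement coefficients
#'
#' Standard coefficients reported alongside the concordance metrics: the raw
#' proportion of agreeing pairs \eqn{P_o}, Fleiss' kappa, and Krippendorff's
#' alpha (nominal). These discount chance from the observed label distribution
#' rather than from rater-reported confidence, so on confident panels
#' \eqn{P_o} typically far exceeds rho.
#'
#' @param d a `diamond_standard`.
#' @return List with `p_o`, `fleiss_kappa`, `krippendorff_alpha`, and
#'   `degenerate` (TRUE when only one category occurs, in which case the
#'   chance-corrected coefficients are undefined and returned as `NA`).
#' @export
baseline_agreement <- function(d) {
  stopifnot(inherits(d, "diamond_standard"))
  if (d$n_raters < 2L) stop("agreement coefficients require at least 2 raters")
  labs <- d$labels
  cats <- d$alphabet
  # P_o: mean per-case proportion of agreeing pairs (pairwise-complete)
  po_case <- apply(labs, 1L, function(lab) {
    lab <- lab[!is.na(lab)]
    n <- length(lab)
    if (n < 2L) return(NA_real_)
    tab <- tabulate(factor(lab, levels = cats), nbins = length(cats))
    sum(tab * (tab - 1)) / (n * (n - 1))
  })
  p_o <- mean(po_case, na.rm = TRUE)

  counts <- t(apply(labs, 1L, function(lab)
    tabulate(factor(lab[!is.na(lab)], levels = cats), nbins = length(cats))))
  if (length(cats) == 1L) counts <- matrix(counts, ncol = 1L)
  degenerate <- sum(colSums(counts) > 0) < 2L

  # Fleiss kappa: defined for a constant number of ratings per case
  per_case_n <- rowSums(counts)
  fleiss <- NA_real_
  if (!degenerate && length(unique(per_case_n)) == 1L && per_case_n[1] >= 2L) {
    m <- per_case_n[1]
    p_j <- colSums(counts) / sum(counts)
    p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
    p_bar <- mean(p_i)
    p_e <- sum(p_j^2)
    fleiss <- if (p_e < 1) (p_bar - p_e) / (1 - p_e) else NA_real_
  }

  # Krippendorff alpha (nominal) via the coincidence matrix
  alpha <- NA_real_
  if (!degenerate) {
    k <- length(cats)
    coin <- matrix(0, k, k)
    for (i in seq_len(nrow(counts))) {
      mu <- per_case_n[i]
      if (mu < 2L) next
      nv <- counts[i, ]
      pairs <- outer(nv, nv) - diag(nv)
      coin <- coin + pairs / (mu - 1)
    }
    nc <- rowSums(coin)
    ntot <- sum(nc)
    d_o <- sum(coin) - sum(diag(coin))
    d_e <- (sum(outer(nc, nc)) - sum(nc^2)) / (ntot - 1)
    alpha <- if (d_e > 0) 1 - d_o / d_e else NA_real_
  }

  list(p_o = p_o, fleiss_kappa = fleiss, krippendorff_alpha = alpha,
       degenerate = degenerate)
}
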