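#' Construct a Gold Standard
#'
#' A Gold Standard holds one reduced value per case: either a single label
#' from the alphabet or a probability vector over it, together with the name
#' of the reduction that produced it.
#'
#' @param case_ids case identifiers.
#' @param values either a character vector of labels or a numeric matrix of
#'   per-case probability vectors (columns = alphabet).
#' @param alphabet the label alphabet.
#' @param reduction_name name of the reduction that produced the values.
#' @return Object of class `gold_standard`.
#' @export
gold_standard <- function(case_ids, values, alphabet, reduction_name) {
  if (is.matrix(values)) {
    if (ncol(values) != length(alphabet))
      stop("probability matrix must have one column per label")
    if (any(values < -1e-9))
      stop("probability vectors must be non-negative")
    if (any(abs(rowSums(values) - 1) > 1e-9))
      stop("probability vectors must sum to 1")
    colnames(values) <- alphabet
    type <- "distribution"
  } else {
    values <- as.character(values)
    bad <- setdiff(unique(values), alphabet)
    if (length(bad)) stop("labels outside the alphabet: ",
                          paste(bad, collapse = ", "))
    type <- "label"
  }
  structure(list(case_ids = case_ids, values = values, type = type,
                 alphabet = alphabet, reduction_name = reduction_name),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold Standard (", x$reduction_name, " reduction, ",
      length(x$case_ids), " cases, ", x$type, " values)\n", sep = "")
  invisible(x)
}

# Deterministic argmax with the package tie-break chain: largest weight sum,
# then largest confidence sum (when available), then first in the alphabet.
argmax_label <- function(scores, alphabet, conf_scores = NULL) {
  top <- names(scores)[scores >= max(scores) - 1e-12]
  if (length(top) > 1L && !is.null(conf_scores)) {
    cs <- conf_scores[top]
    top <- top[cs >= max(cs) - 1e-12]
  }
  alphabet[min(match(top, alphabet))]
}

#' Majority reduction of one case's votes
#'
#' Returns the modal label. Ties are broken by the configured chain:
#' confidence-weighted sum when confidences are supplied, then alphabet order.
#'
#' @param votes character vector of labels from the raters of one case.
#' @param alphabet the label alphabet.
#' @param confidences optional per-rater confidences used only for tie-breaks.
#' @return A single label.
#' @examples
#' reduce_majority(c("A", "A", "B"), c("A", "B"))
#' @export
reduce_majority <- function(votes, alphabet, confidences = NULL) {
  ok <- !is.na(votes)
  votes <- votes[ok]
  if (!is.null(confidences)) confidences <- confidences[ok]
  if (length(votes) < 1L) stop("at least one vote required")
  counts <- table(factor(votes, levels = alphabet))
  conf_sums <- NULL
  if (!is.null(confidences))
    conf_sums <- vapply(alphabet, function(y)
      sum(confidences[votes == y], na.rm = TRUE), numeric(1))
  argmax_label(stats::setNames(as.numeric(counts), alphabet), alphabet,
               conf_sums)
}

#' Probabilistic reduction of one case's votes
#'
#' Returns the vector of vote shares over the alphabet.
#'
#' @inheritParams reduce_majority
#' @return Named numeric probability vector summing to 1.
#' @examples
#' reduce_probabilistic(c("A", "A", "B"), c("A", "B"))
#' @export
reduce_probabilistic <- function(votes, alphabet) {
  votes <- votes[!is.na(votes)]
  if (length(votes) < 1L) stop("at least one vote required")
  counts <- table(factor(votes, levels = alphabet))
  stats::setNames(as.numeric(counts) / length(votes), alphabet)
}

#' Weighted reduction of one case's votes
#'
#' Returns the label with the maximal summed weight, where weights are either
#' the raters' reported confidences or their estimated accuracies.
#'
#' @inheritParams reduce_majority
#' @param weights numeric vector aligned with `votes` (confidences or
#'   accuracies).
#' @return A single label.
#' @examples
#' reduce_weighted(c("A", "A", "B"), c(0.3, 0.3, 0.9), c("A", "B")) # "B"
#' @export
reduce_weighted <- function(votes, weights, alphabet) {
  if (length(weights) != length(votes))
    stop("weights must align with votes")
  ok <- !is.na(votes)
  votes <- votes[ok]; weights <- weights[ok]
  if (length(votes) < 1L) stop("at least one vote required")
  sums <- vapply(alphabet, function(y) sum(weights[votes == y]), numeric(1))
  argmax_label(stats::setNames(sums, alphabet), alphabet)
}

#' Apply a reduction to a whole Diamond Standard
#'
#' @param d a `diamond_standard`.
#' @param reduction one of `"majority"`, `"probabilistic"`, `"confidence"`,
#'   `"accuracy"`.
#' @param conf `confidence_matrix`, required for the confidence-weighted
#'   reduction (and used for majority tie-breaks when available).
#' @param panel [rater_panel()], required for the accuracy-weighted reduction.
#' @return A [gold_standard()] recording the reduction used.
#' @export
apply_reduction <- function(d, reduction = c("majority", "probabilistic",
                                             "confidence", "accuracy"),
                            conf = NULL, panel = NULL) {
  stopifnot(inherits(d, "diamond_standard"))
  reduction <- match.arg(reduction)
  A <- d$alphabet
  if (reduction == "confidence" && is.null(conf))
    stop("confidence-weighted reduction requires a confidence matrix")
  if (reduction == "accuracy" && is.null(panel))
    stop("accuracy-weighted reduction requires a rater panel")
  if (reduction == "probabilistic") {
    vals <- t(apply(d$labels, 1L, reduce_probabilistic, alphabet = A))
    return(gold_standard(d$case_ids, vals, A, "probabilistic"))
  }
  acc <- if (!is.null(panel))
    panel$accuracy[match(d$rater_ids, panel$rater_id)] else NULL
  labs <- vapply(seq_len(d$n_cases), function(i) {
    v <- d$labels[i, ]
    switch(reduction,
      majority = reduce_majority(v, A,
        confidences = if (!is.null(conf)) conf$corrected[i, ] else NULL),
      confidence = reduce_weighted(v, conf$corrected[i, ], A),
      accuracy = reduce_weighted(v, acc, A))
  }, character(1))
  gold_standard(d$case_ids, labs, A, reduction)
}

#' Write a Gold Standard to CSV
#'
#' Single-label Gold Standards are written as `case_id,label`; distributional
#' ones as `case_id` plus one probability column per label.
#'
#' @param g a `gold_standard`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(g, path) {
  stopifnot(inherits(g, "gold_standard"))
  tab <- if (g$type == "label")
    data.frame(case_id = g$case_ids, label = g$values,
               stringsAsFactors = FALSE)
  else
    cbind(data.frame(case_id = g$case_ids, stringsAsFactors = FALSE),
          as.data.frame(g$values))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
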