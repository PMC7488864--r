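#' Construct a rater panel (per-rater accuracy estimates)
#'
#' Holds, for each rater, the estimated accuracy \eqn{1 - \eta_r} (and hence
#' the constant error rate \eqn{\eta_r} assumed by the fineness model) together
#' with the provenance of the estimate.
#'
#' @param rater_ids character vector of rater identifiers.
#' @param accuracy numeric vector of per-rater accuracies in `[0, 1]`.
#' @param method how the accuracies were obtained: one of
#'   `"external_reference"`, `"majority_of_others"`, `"user_supplied"`.
#' @return An object of class `rater_panel`: a data.frame with columns
#'   `rater_id`, `accuracy`, `error_rate`, plus an `estimation_method`
#'   attribute.
#' @export
rater_panel <- function(rater_ids, accuracy,
                        method = c("user_supplied", "external_reference",
                                   "majority_of_others")) {
  method <- match.arg(method)
  if (length(rater_ids) != length(accuracy))
    stop("rater_ids and accuracy must have the same length")
  if (any(is.nan(accuracy)) ||
      any(accuracy < 0 | accuracy > 1, na.rm = TRUE))
    stop("accuracies must lie in [0, 1]")  # NA = not estimable (kept)
  out <- data.frame(rater_id = as.character(rater_ids),
                    accuracy = as.numeric(accuracy),
                    error_rate = 1 - as.numeric(accuracy),
                    stringsAsFactors = FALSE)
  attr(out, "estimation_method") <- method
  class(out) <- c("rater_panel", "data.frame")
  out
}

#' @export
print.rater_panel <- function(x, ...) {
  cat("Rater panel (", attr(x, "estimation_method"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Estimate rater accuracies against an external reference
#'
#' Each rater's accuracy is the fraction of cases on which their label equals
#' the reference label (e.g. the result of an established diagnostic test).
#'
#' @param d a `diamond_standard`.
#' @param reference either a character vector of labels aligned with the rows
#'   of `d`, or a named vector keyed by case id covering every case.
#' @return A [rater_panel()] with `estimation_method = "external_reference"`.
#' @export
estimate_accuracy_external <- function(d, reference) {
  stopifnot(inherits(d, "diamond_standard"))
  if (!is.null(names(reference))) {
    missing_cases <- setdiff(d$case_ids, names(reference))
    if (length(missing_cases) > 0L)
      stop("reference is missing cases: ",
           paste(utils::head(missing_cases, 5L), collapse = ", "))
    reference <- reference[d$case_ids]
  }
  if (length(reference) != d$n_cases)
    stop("reference must cover all ", d$n_cases, " cases")
  acc <- vapply(seq_len(d$n_raters), function(j) {
    ok <- d$labels[, j] == reference
    mean(ok, na.rm = TRUE)
  }, numeric(1))
  rater_panel(d$rater_ids, acc, method = "external_reference")
}

#' Estimate rater accuracies by agreement with the majority of the other raters
#'
#' For each rater r, accuracy is the fraction of cases where r's label equals
#' the majority label of the remaining raters. Cases where the leave-one-out
#' majority is tied are excluded from r's denominator (no tie-break convention
#' is injected into an accuracy estimate). Requires at least 3 raters.
#'
#' This estimator tends to over-estimate true accuracy on homogeneous panels,
#' with the bias shrinking as the panel grows.
#'
#' @param d a `diamond_standard`.
#' @return A [rater_panel()] with `estimation_method = "majority_of_others"`.
#' @export
estimate_accuracy_majority <- function(d) {
  stopifnot(inherits(d, "diamond_standard"))
  if (d$n_raters < 3L)
    stop("majority-of-others estimation requires at least 3 raters")
  acc <- vapply(seq_len(d$n_raters), function(j) {
    hits <- 0L; denom <- 0L
    for (i in seq_len(d$n_cases)) {
      own <- d$labels[i, j]
      if (is.na(own)) next
      others <- d$labels[i, -j]
      others <- others[!is.na(others)]
      if (length(others) == 0L) next
      tab <- table(others)
      top <- tab[tab == max(tab)]
      if (length(top) > 1L) next  # leave-one-out tie: excluded
      denom <- denom + 1L
      if (own == names(top)) hits <- hits + 1L
    }
    if (denom == 0L) return(NA_real_)
    hits / denom
  }, numeric(1))
  rater_panel(d$rater_ids, acc, method = "majority_of_others")
}
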