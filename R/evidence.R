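#' Mass functions over a label frame
#'
#' A mass function assigns non-negative masses summing to 1 to subsets of a
#' finite frame of discernment (here, the label alphabet). A *simple* mass
#' function puts mass `s` on one focal set and `1 - s` on the whole frame:
#' it models a rater who decided on a label with probability `s` and guessed
#' otherwise, which is exactly the decision-theoretic reading of a corrected
#' confidence report.
#'
#' Focal sets are canonicalised as sorted, `"|"`-joined label strings; the
#' full frame always appears under its own key.
#'
#' @param focal named numeric vector: names are subset keys (labels joined by
#'   `"|"`), values are masses.
#' @param frame character vector of frame elements.
#' @return Object of class `mass_function`.
#' @export
mass_function <- function(focal, frame) {
  frame <- as.character(frame)
  keys <- vapply(strsplit(names(focal), "|", fixed = TRUE), function(els) {
    els <- unique(els)
    if (length(setdiff(els, frame)) > 0L)
      stop("focal set outside the frame: ", paste(els, collapse = "|"))
    paste(sort(els), collapse = "|")
  }, character(1))
  focal <- tapply(as.numeric(focal), keys, sum)
  focal <- stats::setNames(as.numeric(focal), names(focal))
  if (any(focal < -1e-12)) stop("masses must be non-negative")
  if (abs(sum(focal) - 1) > 1e-12) stop("masses must sum to 1")
  structure(list(focal = focal[focal > 0], frame = sort(frame)),
            class = "mass_function")
}

#' @rdname mass_function
#' @param x focal set (character vector of labels) of the simple mass function.
#' @param s mass assigned to the focal set; `1 - s` goes to the frame.
#' @export
simple_mass <- function(x, s, frame) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  key <- paste(sort(unique(as.character(x))), collapse = "|")
  frame_key <- paste(sort(as.character(frame)), collapse = "|")
  focal <- stats::setNames(c(s, 1 - s), c(key, frame_key))
  mass_function(focal, frame)
}

#' @export
print.mass_function <- function(x, ...) {
  cat("Mass function over {", paste(x$frame, collapse = ", "), "}:\n", sep = "")
  for (k in names(x$focal))
    cat(sprintf("  m({%s}) = %.6f\n", gsub("\\|", ", ", k), x$focal[k]))
  invisible(x)
}

# Mass assigned to a specific subset (canonical key), 0 if not focal.
mass_of <- function(m, x) {
  key <- paste(sort(unique(as.character(x))), collapse = "|")
  if (key %in% names(m$focal)) unname(m$focal[key]) else 0
}

key_elements <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

combine_pairwise <- function(m1, m2, set_op) {
  if (!identical(m1$frame, m2$frame)) stop("mass functions on different frames")
  out <- list()
  for (a in names(m1$focal)) for (b in names(m2$focal)) {
    s <- set_op(key_elements(a), key_elements(b))
    key <- paste(sort(s), collapse = "|")
    w <- unname(m1$focal[[a]] * m2$focal[[b]])
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + w
  }
  unlist(out)
}

#' Dempster's rule of combination
#'
#' The normalised conjunctive (orthogonal) sum: masses multiply over
#' intersecting focal sets and the conflict mass (empty intersections) is
#' renormalised away. For two simple masses agreeing on a label `y` this gives
#' \eqn{s_1 s_2 + s_1(1-s_2) + (1-s_1)s_2} on `{y}` — it credits one-sided
#' confidence as agreement, which is why it over-states *genuine* agreement.
#'
#' @param m1,m2 `mass_function`s on the same frame.
#' @return The combined `mass_function`.
#' @export
dempster_combine <- function(m1, m2) {
  raw <- combine_pairwise(m1, m2, function(a, b) intersect(a, b))
  conflict <- sum(raw[names(raw) == ""])
  raw <- raw[names(raw) != ""]
  if (1 - conflict <= 1e-15)
    stop("total conflict: the masses are not combinable")
  mass_function(raw / (1 - conflict), m1$frame)
}

#' Dubois-Prade (disjunctive) rule of combination
#'
#' Masses multiply over unions of focal sets. For two simple masses agreeing
#' on `y` the mass landing on `{y}` is exactly \eqn{s_1 s_2} — the
#' chance-discounted pair agreement credit — which is what makes this rule the
#' right evidential account of genuine agreement.
#'
#' @inheritParams dempster_combine
#' @return The combined `mass_function`.
#' @export
dubois_prade_combine <- function(m1, m2) {
  mass_function(combine_pairwise(m1, m2, function(a, b) union(a, b)),
                m1$frame)
}

#' Mixing (averaging) rule of combination
#'
#' The pointwise average of a list of mass functions: the expected mass over a
#' uniformly chosen source.
#'
#' @param masses non-empty list of `mass_function`s on a shared frame.
#' @return The averaged `mass_function`.
#' @export
mixing_combine <- function(masses) {
  if (length(masses) < 1L) stop("at least one mass function required")
  frame <- masses[[1]]$frame
  acc <- list()
  for (m in masses) {
    if (!identical(m$frame, frame)) stop("mass functions on different frames")
    for (k in names(m$focal))
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + m$focal[[k]]
  }
  mass_function(unlist(acc) / length(masses), frame)
}

#' Degree of concordance through the evidence-theoretic route
#'
#' Independent derivation of the degree of concordance used as an internal
#' oracle: each rater's annotation becomes a simple mass function (focal set =
#' the assigned label, mass = corrected confidence); for every label with at
#' least two supporters the agreeing pairs are Dubois-Prade-combined, the pair
#' results are mixing-combined, and the per-label averages are weighted by
#' their pair counts and normalised by the total number of pairs. The result
#' coincides with [degree_of_concordance()].
#'
#' @inheritParams degree_of_concordance
#' @return List with `sigma` and `per_case`.
#' @export
sigma_via_evidence <- function(d, conf) {
  stopifnot(inherits(d, "diamond_standard"))
  m <- d$n_raters
  if (m < 2L) stop("concordance requires at least 2 raters")
  frame <- d$alphabet
  per_case <- vapply(seq_len(d$n_cases), function(x) {
    lab <- d$labels[x, ]
    cx <- conf$corrected[x, ]
    ok <- !is.na(lab)
    total_pairs <- choose(sum(ok), 2)
    if (total_pairs == 0) return(NA_real_)
    acc <- 0
    for (y in frame) {
      supporters <- which(ok & lab == y)
      ky <- length(supporters)
      if (ky < 2L) next
      pair_masses <- list()
      for (i in seq_len(ky - 1L)) for (j in (i + 1L):ky) {
        mi <- simple_mass(y, cx[supporters[i]], frame)
        mj <- simple_mass(y, cx[supporters[j]], frame)
        pair_masses[[length(pair_masses) + 1L]] <- dubois_prade_combine(mi, mj)
      }
      ga_y <- mass_of(mixing_combine(pair_masses), y)
      acc <- acc + choose(ky, 2) * ga_y
    }
    acc / total_pairs
  }, numeric(1))
  list(sigma = mean(per_case, na.rm = TRUE), per_case = per_case)
}
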