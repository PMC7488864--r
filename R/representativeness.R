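#' Degree of correspondence and representativeness metrics
#'
#' @name representativeness
#' @keywords internal
NULL

# Coerce to a validated numeric feature matrix (instances x features).
as_feature_matrix <- function(X, what = "feature dataset") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (!is.numeric(X)) stop(what, " must be numeric")
  if (any(!is.finite(X))) stop(what, " must contain only finite values")
  if (is.null(rownames(X))) rownames(X) <- sprintf("i%04d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  X
}

check_shared_features <- function(P, G) {
  if (ncol(P) != ncol(G) || !identical(colnames(P), colnames(G)))
    stop("the two datasets must share feature names and order")
}

# Run code under a temporary RNG state seeded with `seed`; NULL = use the
# current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Multiset of pairwise distances within a dataset
#'
#' @param X numeric feature matrix (instances x features).
#' @param metric distance name accepted by [stats::dist()]
#'   (default `"euclidean"`).
#' @return Numeric vector of all `n(n-1)/2` pairwise distances.
#' @export
distance_distribution <- function(X, metric = "euclidean") {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) stop("at least 2 instances required")
  as.numeric(stats::dist(X, method = metric))
}

#' Minimum-cost injective matching of a small dataset into a larger one
#'
#' Matches each instance of `G` with a distinct instance of `P` so that the
#' total pairwise distance is minimal (minimum-cost assignment in an
#' unbalanced bipartite graph, solved exactly in polynomial time).
#'
#' @param P the larger feature matrix.
#' @param G the smaller feature matrix (`nrow(G) <= nrow(P)`).
#' @inheritParams distance_distribution
#' @return List with `pairs` (data.frame `g_index`, `p_index`, `distance`)
#'   and `total_cost`.
#' @export
match_min_cost <- function(P, G, metric = "euclidean") {
  P <- as_feature_matrix(P, "P"); G <- as_feature_matrix(G, "G")
  check_shared_features(P, G)
  if (nrow(G) > nrow(P)) stop("G must not be larger than P")
  D <- as.matrix(stats::dist(rbind(G, P), method = metric))
  cost <- D[seq_len(nrow(G)), nrow(G) + seq_len(nrow(P)), drop = FALSE]
  p_index <- .lap_cpp(cost)
  dists <- cost[cbind(seq_len(nrow(G)), p_index)]
  list(pairs = data.frame(g_index = seq_len(nrow(G)), p_index = p_index,
                          distance = dists),
       total_cost = sum(dists))
}

# ---- deviation statistics on univariate distance multisets ----------------

dev_ks <- function(x, y) .ks_stat_cpp(x, y)

# Jensen-Shannon distance (base 2, in [0,1]) on Freedman-Diaconis-binned
# histograms of the pooled values.
dev_js <- function(x, y) {
  pooled <- c(x, y)
  rng <- range(pooled)
  if (rng[2] - rng[1] < .Machine$double.eps) return(0)
  h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  nb <- if (h <= 0) ceiling(sqrt(length(pooled))) else
    max(1L, ceiling((rng[2] - rng[1]) / h))
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  p <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = nb) / length(x)
  q <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = nb) / length(y)
  mid <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(pmax(0, (kl(p, mid) + kl(q, mid)) / 2))
}

# Maximum mean discrepancy (biased V-statistic, RBF kernel, median-heuristic
# bandwidth). Multisets larger than `max_n` are thinned to evenly spaced
# order statistics to keep the O(n^2) kernel sums tractable; the thinning is
# deterministic.
dev_mmd <- function(x, y, max_n = 1024L) {
  thin <- function(v) {
    if (length(v) <= max_n) return(sort(v))
    sort(v)[round(seq(1L, length(v), length.out = max_n))]
  }
  x <- thin(x); y <- thin(y)
  pooled <- c(x, y)
  bw <- stats::median(stats::dist(matrix(pooled, ncol = 1L)))
  if (bw <= 0) return(0)
  k <- function(a, b) exp(-outer(a, b, `-`)^2 / (2 * bw^2))
  sqrt(pmax(0, mean(k(x, x)) + mean(k(y, y)) - 2 * mean(k(x, y))))
}

deviation_fun <- function(deviation) {
  switch(match.arg(deviation, c("ks", "js", "mmd")),
         ks = dev_ks, js = dev_js, mmd = dev_mmd)
}

# Deviation for one split of the merged dataset, given the precomputed full
# distance matrix. gidx/pidx are 1-based row indices into D. The KS deviation
# takes a fast path: distances among unchanged instances are common to both
# multisets and cancel from the two ecdfs, so only pairs touching a matched
# row are collected (.sub_ks_cpp); the generic path materialises both
# multisets.
delta_for_split <- function(D, gidx, pidx, deviation, devfun) {
  cost <- D[gidx, pidx, drop = FALSE]
  sol <- .lap_cpp(cost)
  if (deviation == "ks") return(.sub_ks_cpp(D, pidx, gidx, sol))
  pprime <- pidx
  pprime[sol] <- gidx
  devfun(.dist_subset_cpp(D, pidx), .dist_subset_cpp(D, pprime))
}

#' Deviation caused by matching-substitution of one dataset into another
#'
#' Builds `P'` by replacing each matched instance of `P` with its partner
#' from `G` (sizes preserved) and returns the deviation between the pairwise
#' distance distributions of `P` and `P'`.
#'
#' @inheritParams match_min_cost
#' @param assignment result of [match_min_cost()]; computed when `NULL`.
#' @param deviation deviation statistic on the two distance multisets:
#'   `"ks"` (two-sample Kolmogorov-Smirnov statistic, default), `"js"`
#'   (Jensen-Shannon distance on binned distances) or `"mmd"` (maximum mean
#'   discrepancy, RBF kernel with median-heuristic bandwidth).
#' @return The deviation `delta >= 0`.
#' @export
substitution_deviation <- function(P, G, assignment = NULL,
                                   metric = "euclidean", deviation = "ks") {
  P <- as_feature_matrix(P, "P"); G <- as_feature_matrix(G, "G")
  check_shared_features(P, G)
  if (is.null(assignment)) assignment <- match_min_cost(P, G, metric)
  devfun <- deviation_fun(deviation)
  Pprime <- P
  Pprime[assignment$pairs$p_index, ] <- G[assignment$pairs$g_index, ]
  devfun(as.numeric(stats::dist(P, method = metric)),
         as.numeric(stats::dist(Pprime, method = metric)))
}

#' Degree of correspondence between two feature datasets
#'
#' Bootstrap p-value that the smaller dataset `G` and the larger dataset `P`
#' come from the same population. The observed deviation `delta` is obtained
#' by minimum-cost matching of `G` into `P`, substituting each matched
#' instance, and comparing the pre- and post-substitution pairwise-distance
#' distributions; the null distribution of deviations is generated by
#' repeating the computation on random size-preserving splits of the merged
#' dataset. The p-value uses the `(1 + #\{delta* >= delta\}) / (1 + n_boot)`
#' small-sample correction, so it lies in `(0, 1]` and equals 1 exactly when
#' `G` is a subset of `P`.
#'
#' Features are z-scored with the mean and standard deviation of `P` before
#' distances are computed (disable with `standardize = FALSE`).
#'
#' @inheritParams substitution_deviation
#' @param n_boot number of bootstrap splits (at least 100; default 999).
#' @param seed integer seed for the bootstrap; `NULL` uses the current RNG
#'   stream.
#' @param standardize z-score features using `P`'s statistics first.
#' @return Object of class `psi_result`: `psi`, `delta`, `boot_deltas`,
#'   `deviation`, `metric`, `matching`, `n_boot`, `seed`.
#' @examples
#' set.seed(1)
#' P <- matrix(rnorm(60), ncol = 2)
#' psi <- degree_of_correspondence(P, P[1:5, ], n_boot = 199, seed = 7)
#' psi$psi # 1: a subset is perfectly represented
#' @export
degree_of_correspondence <- function(P, G, metric = "euclidean",
                                     deviation = "ks", n_boot = 999L,
                                     seed = NULL, standardize = TRUE) {
  P <- as_feature_matrix(P, "P"); G <- as_feature_matrix(G, "G")
  check_shared_features(P, G)
  if (nrow(G) > nrow(P)) stop("G must not be larger than P")
  if (n_boot < 100L) stop("n_boot must be at least 100")
  if (standardize) {
    mu <- colMeans(P)
    sdev <- apply(P, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    P <- sweep(sweep(P, 2L, mu), 2L, sdev, "/")
    G <- sweep(sweep(G, 2L, mu), 2L, sdev, "/")
  }
  nP <- nrow(P); nG <- nrow(G); n <- nP + nG
  D <- as.matrix(stats::dist(rbind(P, G), method = metric))
  if (max(D) <= 0)
    warning("degenerate datasets: all instances identical; psi is 1 by ",
            "construction")
  devfun <- deviation_fun(deviation)

  pidx <- seq_len(nP); gidx <- nP + seq_len(nG)
  cost <- D[gidx, pidx, drop = FALSE]
  sol <- .lap_cpp(cost)
  matching <- data.frame(g_id = rownames(G), p_id = rownames(P)[sol],
                         distance = cost[cbind(seq_len(nG), sol)],
                         stringsAsFactors = FALSE)
  delta <- delta_for_split(D, gidx, pidx, deviation, devfun)

  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    g <- sample.int(n, nG)
    delta_for_split(D, g, seq_len(n)[-g], deviation, devfun)
  }, numeric(1)))

  psi <- (1 + sum(boot >= delta - 1e-12)) / (1 + n_boot)
  structure(list(psi = psi, delta = delta, boot_deltas = boot,
                 deviation = deviation, metric = metric, matching = matching,
                 n_boot = n_boot, seed = seed),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf(
    "Degree of correspondence psi = %.4f (delta = %.5f, %s deviation, %d bootstrap splits)\n",
    x$psi, x$delta, x$deviation, x$n_boot))
  invisible(x)
}

#' Compatibility of a single instance with a dataset
#'
#' [degree_of_correspondence()] with `G` reduced to one instance: the degree
#' to which a new case is represented in the dataset.
#'
#' @param P the reference feature matrix.
#' @param x a single instance (numeric vector or 1-row matrix).
#' @param ... passed on to [degree_of_correspondence()].
#' @return A `psi_result`.
#' @export
instance_compatibility <- function(P, x, ...) {
  P <- as_feature_matrix(P, "P")
  x <- matrix(as.numeric(x), nrow = 1L,
              dimnames = list("new", colnames(P)))
  degree_of_correspondence(P, x, ...)
}

#' Univariate (feature-wise) representativeness
#'
#' Per-feature two-sample tests between `P` and `G` — Kolmogorov-Smirnov for
#' continuous features, chi-squared on observed counts for features declared
#' categorical — aggregated into a single representativeness degree by the
#' mean (default) or the minimum t-norm. Assumes feature independence; the
#' multivariate [degree_of_correspondence()] does not.
#'
#' @inheritParams match_min_cost
#' @param categorical character vector of feature names to test with the
#'   chi-squared test instead of KS.
#' @param aggregate `"mean"` or `"min"`.
#' @return List with `per_feature` (data.frame `feature`, `test`, `p_value`,
#'   `constant`), `aggregate`, `aggregator`.
#' @export
univariate_representativeness <- function(P, G, categorical = character(),
                                          aggregate = c("mean", "min")) {
  P <- as_feature_matrix(P, "P"); G <- as_feature_matrix(G, "G")
  check_shared_features(P, G)
  aggregate <- match.arg(aggregate)
  rows <- lapply(colnames(P), function(f) {
    xp <- P[, f]; xg <- G[, f]
    constant <- stats::sd(c(xp, xg)) == 0
    if (f %in% categorical) {
      lev <- sort(unique(c(xp, xg)))
      tab <- rbind(tabulate(factor(xp, levels = lev), length(lev)),
                   tabulate(factor(xg, levels = lev), length(lev)))
      pv <- if (length(lev) < 2L) 1 else
        suppressWarnings(stats::chisq.test(tab)$p.value)
      test <- "chisq"
    } else {
      pv <- if (constant) 1 else
        suppressWarnings(stats::ks.test(xp, xg)$p.value)
      test <- "ks"
    }
    data.frame(feature = f, test = test, p_value = pv, constant = constant,
               stringsAsFactors = FALSE)
  })
  per_feature <- do.call(rbind, rows)
  agg <- switch(aggregate, mean = mean(per_feature$p_value),
                min = min(per_feature$p_value))
  list(per_feature = per_feature, aggregate = agg, aggregator = aggregate)
}

#' Ratio of model accuracy to degree of correspondence
#'
#' Reported verbatim as accuracy divided by psi. Caveat: the ratio grows
#' without bound as psi approaches 0, i.e. a model evaluated on poorly
#' corresponding data gets a *larger* ratio — interpret it as "how much of
#' the claimed accuracy is unsupported by representative evidence", not as a
#' robustness score to maximise.
#'
#' @param model_accuracy accuracy of the model on a test set.
#' @param psi degree of correspondence (must be positive).
#' @return List with `value` and `caveat`.
#' @export
robustness_ratio <- function(model_accuracy, psi) {
  if (psi <= 0) stop("psi must be positive")
  list(value = model_accuracy / psi,
       caveat = paste("ratio is unbounded as psi approaches 0;",
                      "low psi inflates, not certifies, the score"))
}

#' Maximally divergent train/test split
#'
#' Draws `n_candidates` random splits of `X` at the given test fraction and
#' returns the split whose test-vs-train degree of correspondence is minimal:
#' a stress-test split concentrating distributional difference in the test
#' set.
#'
#' @param X feature matrix.
#' @param test_fraction fraction of instances in the test set, in `(0, 1)`.
#' @param n_candidates number of candidate splits examined.
#' @param n_boot bootstrap count used for each candidate's psi.
#' @param seed integer seed driving both the candidate splits and the
#'   bootstraps.
#' @param ... further arguments to [degree_of_correspondence()].
#' @return List with `train`, `test` (row indices), `psi` of the selected
#'   split, and `candidate_psis`.
#' @export
max_divergent_split <- function(X, test_fraction = 0.2, n_candidates = 25L,
                                n_boot = 199L, seed = NULL, ...) {
  X <- as_feature_matrix(X)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  n_test <- round(nrow(X) * test_fraction)
  if (n_test < 1L || nrow(X) - n_test < 2L)
    stop("dataset too small for the requested split")
  with_seed(seed, {
    cand <- lapply(seq_len(n_candidates), function(i) {
      test <- sort(sample.int(nrow(X), n_test))
      train <- setdiff(seq_len(nrow(X)), test)
      psi <- degree_of_correspondence(X[train, , drop = FALSE],
                                      X[test, , drop = FALSE],
                                      n_boot = n_boot, ...)$psi
      list(train = train, test = test, psi = psi)
    })
    psis <- vapply(cand, `[[`, numeric(1), "psi")
    best <- cand[[which.min(psis)]]
    list(train = best$train, test = best$test, psi = best$psi,
         candidate_psis = psis)
  })
}

#' Read / write a feature matrix as CSV
#'
#' An optional `instance_id` first column becomes the rownames; all other
#' columns must be numeric.
#'
#' @param path CSV path.
#' @return [read_features()]: a numeric matrix. [write_features()]: `path`,
#'   invisibly.
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] == "instance_id") {
    ids <- as.character(tab[[1]])
    tab <- tab[-1]
    X <- as.matrix(tab)
    rownames(X) <- ids
  } else X <- as.matrix(tab)
  as_feature_matrix(X)
}

#' @rdname read_features
#' @param X numeric feature matrix.
#' @export
write_features <- function(X, path) {
  X <- as_feature_matrix(X)
  tab <- cbind(data.frame(instance_id = rownames(X),
                          stringsAsFactors = FALSE),
               as.data.frame(X))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
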