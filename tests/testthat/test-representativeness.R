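col1 <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, "f01"))

test_that("distance distribution enumerates all pairs", {
  expect_equal(sort(distance_distribution(col1(c(0, 1, 3)))), c(1, 2, 3))
  X <- matrix(rnorm(40), 10, 4)
  expect_length(distance_distribution(X), 45)
  Xd <- rbind(X, X[1, ])
  expect_true(any(distance_distribution(Xd) == 0))
  expect_error(distance_distribution(X[1, , drop = FALSE]), "at least 2")
})

test_that("KS deviation kernel agrees with stats::ks.test", {
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(sample(50:500, 1))
    y <- rnorm(sample(50:500, 1), mean = runif(1, -1, 1))
    expect_equal(annoqc:::dev_ks(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("deviation statistics vanish on identical multisets", {
  x <- rnorm(200)
  expect_equal(annoqc:::dev_ks(x, x), 0)
  expect_equal(annoqc:::dev_js(x, x), 0)
  expect_equal(annoqc:::dev_mmd(x, x), 0, tolerance = 1e-7)
  y <- rnorm(200, mean = 3)
  expect_gt(annoqc:::dev_ks(x, y), 0.5)
  expect_gt(annoqc:::dev_js(x, y), 0.3)
  expect_gt(annoqc:::dev_mmd(x, y), 0.1)
})

test_that("minimum-cost matching equals brute force on small instances", {
  mm <- match_min_cost(col1(c(0, 10)), col1(9))
  expect_equal(mm$pairs$p_index, 2L)
  expect_equal(mm$total_cost, 1)

  mm2 <- match_min_cost(col1(c(0, 5, 10)), col1(c(1, 6)))
  expect_equal(mm2$pairs$p_index, c(1L, 2L))
  expect_equal(mm2$total_cost, 2)

  set.seed(12)
  for (rep in 1:15) {
    nG <- sample(2:6, 1); nP <- sample(nG:8, 1); d <- sample(1:3, 1)
    P <- matrix(rnorm(nP * d), nP, d)
    G <- matrix(rnorm(nG * d), nG, d)
    colnames(P) <- colnames(G) <- sprintf("f%02d", 1:d)
    mm <- match_min_cost(P, G)
    D <- as.matrix(stats::dist(rbind(G, P)))[seq_len(nG),
                                             nG + seq_len(nP), drop = FALSE]
    expect_equal(mm$total_cost, brute_assignment_cost(D), tolerance = 1e-10)
  }
  expect_error(match_min_cost(col1(1), col1(c(1, 2))), "larger")
})

test_that("assignment solver agrees with the Hungarian reference implementation", {
  set.seed(271)
  for (rep in 1:12) {
    nr <- sample(2:40, 1); nc <- sample(nr:60, 1)
    cost <- matrix(runif(nr * nc), nr, nc)
    ours <- annoqc:::.lap_cpp(cost)
    ref <- as.integer(clue::solve_LSAP(cost))
    # assignments may differ on ties; total costs must match
    expect_equal(sum(cost[cbind(seq_len(nr), ours)]),
                 sum(cost[cbind(seq_len(nr), ref)]), tolerance = 1e-10)
    expect_equal(anyDuplicated(ours), 0L)
  }
})

test_that("shared-pairs KS fast path equals the full-multiset statistic", {
  set.seed(281)
  for (rep in 1:8) {
    n <- sample(20:60, 1); k <- sample(2:10, 1)
    X <- matrix(rnorm((n + k) * 3), n + k, 3)
    D <- as.matrix(dist(X))
    pidx <- seq_len(n); gidx <- n + seq_len(k)
    sol <- annoqc:::.lap_cpp(D[gidx, pidx, drop = FALSE])
    fast <- annoqc:::.sub_ks_cpp(D, pidx, gidx, sol)
    pprime <- pidx; pprime[sol] <- gidx
    full <- annoqc:::dev_ks(annoqc:::.dist_subset_cpp(D, pidx),
                            annoqc:::.dist_subset_cpp(D, pprime))
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("substitution deviation is zero for subsets and duplicate swaps", {
  set.seed(4)
  P <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f01", "f02")))
  G <- P[c(3, 8, 15), ]
  expect_equal(substitution_deviation(P, G), 0)
  # a duplicated row swapped for its twin leaves the distance multiset intact
  P2 <- rbind(P, P[1, ])
  expect_equal(substitution_deviation(P2, P[1, , drop = FALSE]), 0)
})

test_that("substitution deviation matches a manual pipeline trace", {
  P <- col1(c(0, 2, 5, 9))
  G <- col1(3)
  # manual: nearest instance to 3 is 2 -> P' = (0, 3, 5, 9)
  mm <- match_min_cost(P, G)
  expect_equal(mm$pairs$p_index, 2L)
  dP <- as.numeric(dist(P))
  dPp <- as.numeric(dist(col1(c(0, 3, 5, 9))))
  expect_equal(substitution_deviation(P, G),
               unname(suppressWarnings(ks.test(dP, dPp)$statistic)))
})

test_that("psi is 1 exactly when G is a subset of P", {
  set.seed(9)
  P <- matrix(rnorm(120), 40, 3)
  colnames(P) <- c("f01", "f02", "f03")
  for (dev in c("ks", "js")) {
    res <- degree_of_correspondence(P, P[c(2, 9, 21, 33), ],
                                    deviation = dev, n_boot = 120, seed = 5)
    expect_equal(res$psi, 1)
    expect_equal(res$delta, 0)
  }
})

test_that("psi detects a strong mean shift and respects its seed", {
  P <- simulate_features(80, rep(0, 4), seed = 301)
  G <- simulate_features(25, rep(3, 4), seed = 302)
  r1 <- degree_of_correspondence(P, G, n_boot = 199, seed = 7)
  r2 <- degree_of_correspondence(P, G, n_boot = 199, seed = 7)
  expect_identical(r1$psi, r2$psi)
  expect_identical(r1$boot_deltas, r2$boot_deltas)
  expect_lt(r1$psi, 0.05)
  # psi invariants
  expect_equal(r1$psi,
               (1 + sum(r1$boot_deltas >= r1$delta - 1e-12)) / (1 + 199))
  expect_error(degree_of_correspondence(P, G, n_boot = 50, seed = 1),
               "at least 100")
})

test_that("psi is invariant to feature permutation and rigid translation", {
  P <- simulate_features(60, rep(0, 3), seed = 11)
  G <- simulate_features(20, rep(0.5, 3), seed = 12)
  base <- degree_of_correspondence(P, G, n_boot = 149, seed = 3)$psi
  perm <- c(3, 1, 2)
  Pp <- P[, perm]; Gp <- G[, perm]
  colnames(Pp) <- colnames(Gp) <- colnames(P)[perm]
  expect_equal(degree_of_correspondence(Pp, Gp, n_boot = 149, seed = 3)$psi,
               base)
  shift <- matrix(5, 1, 3)
  expect_equal(degree_of_correspondence(P + shift[rep(1, 60), ],
                                        G + shift[rep(1, 20), ],
                                        n_boot = 149, seed = 3)$psi,
               base)
})

test_that("instance compatibility distinguishes members from far outliers", {
  P <- simulate_features(80, rep(0, 3), seed = 21)
  inside <- instance_compatibility(P, P[5, ], n_boot = 149, seed = 2)
  expect_equal(inside$psi, 1)
  centroid <- instance_compatibility(P, colMeans(P), n_boot = 149, seed = 2)
  expect_gt(centroid$psi, 0.2)
  outlier <- instance_compatibility(P, rep(10, 3), n_boot = 149, seed = 2)
  expect_lt(outlier$psi, 0.05)
})

test_that("univariate representativeness flags the shifted feature only", {
  P <- simulate_features(200, rep(0, 3), seed = 41)
  G <- simulate_features(200, c(5, 0, 0), seed = 42)
  ur <- univariate_representativeness(P, G)
  expect_lt(ur$per_feature$p_value[1], 0.001)
  expect_gt(min(ur$per_feature$p_value[2:3]), 0.01)
  expect_equal(ur$aggregate, mean(ur$per_feature$p_value))
  # identical datasets: all p-values 1
  ur1 <- univariate_representativeness(P, P)
  expect_true(all(ur1$per_feature$p_value == 1))
  # aggregators
  expect_equal(univariate_representativeness(P, P, aggregate = "min")$aggregate, 1)
  # categorical route
  Xc <- cbind(P, cat = rep(c(0, 1), 100))
  Gc <- cbind(P, cat = rep(c(0, 1), c(180, 20)))
  colnames(Xc)[4] <- colnames(Gc)[4] <- "cat"
  urc <- univariate_representativeness(Xc, Gc, categorical = "cat")
  expect_equal(urc$per_feature$test[4], "chisq")
  expect_lt(urc$per_feature$p_value[4], 0.01)
})

test_that("robustness ratio divides accuracy by psi with a guard at zero", {
  expect_equal(robustness_ratio(0.9, 0.9)$value, 1)
  expect_equal(robustness_ratio(0.9, 0.45)$value, 2)
  expect_error(robustness_ratio(0.9, 0), "positive")
  expect_match(robustness_ratio(0.9, 0.5)$caveat, "unbounded")
})

test_that("max divergent split picks the least-corresponding candidate", {
  X <- rbind(simulate_features(40, rep(0, 2), seed = 61),
             simulate_features(40, rep(8, 2), seed = 62))
  rownames(X) <- sprintf("i%04d", 1:80)
  sp <- max_divergent_split(X, test_fraction = 0.25, n_candidates = 15,
                            n_boot = 119, seed = 9)
  expect_equal(sp$psi, min(sp$candidate_psis))
  expect_lte(sp$psi, stats::median(sp$candidate_psis))
  expect_setequal(c(sp$train, sp$test), 1:80)
  expect_length(sp$test, 20)
  # deterministic given the seed
  sp_again <- max_divergent_split(X, test_fraction = 0.25, n_candidates = 15,
                                  n_boot = 119, seed = 9)
  expect_identical(sp$test, sp_again$test)
  # single candidate returns that split
  sp1 <- max_divergent_split(X, test_fraction = 0.25, n_candidates = 1,
                             n_boot = 119, seed = 10)
  expect_equal(sp1$psi, sp1$candidate_psis)
})

test_that("feature CSV round trip", {
  X <- simulate_features(10, rep(0, 3), seed = 77)
  f <- withr::local_tempfile(fileext = ".csv")
  write_features(X, f)
  X2 <- read_features(f)
  expect_equal(unname(X2), unname(X), tolerance = 1e-8,
               ignore_attr = "component")
  expect_equal(colnames(X2), colnames(X))
})
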