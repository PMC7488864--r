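make_panel <- function(labels, conf) {
  d <- diamond_standard(labels,
                        alphabet = sort(unique(as.vector(labels))))
  cm <- confidence_matrix(matrix(1, nrow(labels), ncol(labels)),
                          scale_min = 0, scale_max = 1)
  cm$corrected <- conf
  list(d = d, conf = cm)
}

test_that("pair agreement is the confidence product on matching labels only", {
  expect_equal(pair_agreement("A", "A", 0.8, 0.9), 0.72)
  expect_equal(pair_agreement("A", "B", 0.8, 0.9), 0)
  expect_equal(pair_agreement("A", "A", 1, 1), 1)
  expect_error(pair_agreement("A", "A", 1.2, 0.5), "\\[0, 1\\]")
})

test_that("sigma matches hand enumeration and its boundary cases", {
  p <- make_panel(matrix(c("A", "A", "B"), 1, 3),
                  matrix(c(0.8, 0.9, 1.0), 1, 3))
  expect_equal(degree_of_concordance(p$d, p$conf)$sigma, 0.24)

  unan <- make_panel(matrix("A", 5, 3), matrix(1, 5, 3))
  expect_equal(degree_of_concordance(unan$d, unan$conf)$sigma, 1)

  dist3 <- make_panel(matrix(c("A", "B", "C"), 4, 3, byrow = TRUE),
                      matrix(runif(12), 4, 3))
  expect_equal(degree_of_concordance(dist3$d, dist3$conf)$sigma, 0)

  # unanimity at constant confidence c gives sigma = c^2 exactly
  for (cc in c(0.3, 0.5, 0.9)) {
    p2 <- make_panel(matrix("A", 6, 4), matrix(cc, 6, 4))
    expect_equal(degree_of_concordance(p2$d, p2$conf)$sigma, cc^2)
  }
})

test_that("pair-correctness model behaves at its anchors", {
  expect_equal(pair_correct_probability(1, 1, 2), 1)
  expect_equal(pair_correct_probability(0.8, 0.8, 2), 0.64 / 0.68)
  expect_equal(pair_correct_probability(0.5, 0.5, 2), 0.5)
  expect_error(pair_correct_probability(0.8, 0.8, 1), "at least 2")
})

test_that("rho scales sigma by pair correctness and never exceeds it", {
  p <- make_panel(matrix(c("A", "A", "B"), 1, 3),
                  matrix(c(0.8, 0.9, 1.0), 1, 3))
  expect_equal(
    degree_of_weighted_concordance(p$d, p$conf, pair_correct = 0.9)$rho,
    0.216)
  pan <- rater_panel(p$d$rater_ids, rep(1, 3))
  expect_equal(degree_of_weighted_concordance(p$d, p$conf, pan)$rho,
               degree_of_concordance(p$d, p$conf)$sigma)
  zero <- make_panel(matrix("A", 3, 3), matrix(0, 3, 3))
  expect_equal(degree_of_weighted_concordance(zero$d, zero$conf,
                                              pair_correct = 0.8)$rho, 0)
})

test_that("sigma and rho agree with the direct-sum oracle on random panels", {
  set.seed(421)
  for (rep in 1:20) {
    m <- sample(2:5, 1)
    n <- sample(2:15, 1)
    p <- random_panel(n, m)
    expect_equal(degree_of_concordance(p$d, p$conf)$sigma,
                 oracle_sigma(p$labels, p$conf_mat), tolerance = 1e-12)
  }
})

test_that("rho is monotone in confidences and accuracies", {
  set.seed(99)
  p <- random_panel(12, 4)
  pan <- rater_panel(p$d$rater_ids, c(0.7, 0.8, 0.75, 0.9))
  base <- degree_of_weighted_concordance(p$d, p$conf, pan)$rho
  # raise one confidence entry
  p2 <- p
  p2$conf$corrected[3, 2] <- min(1, p$conf$corrected[3, 2] + 0.2)
  expect_gte(degree_of_weighted_concordance(p2$d, p2$conf, pan)$rho, base)
  # raise one accuracy
  pan2 <- rater_panel(p$d$rater_ids, c(0.7, 0.95, 0.75, 0.9))
  expect_gte(degree_of_weighted_concordance(p$d, p$conf, pan2)$rho, base)
})

test_that("intra-rater variability follows the CI half-width formula", {
  labs <- matrix("A", 4, 2)
  d <- diamond_standard(labs, alphabet = c("A", "B"),
                        case_ids = rep("c1", 4),
                        repetition_group = rep("c1", 4))
  cm <- confidence_matrix(matrix(1, 4, 2), scale_min = 0, scale_max = 1)
  cm$corrected <- cbind(c(0.4, 0.6, 0.4, 0.6), rep(0.5, 4))
  irv <- intra_rater_variability(d, cm)
  expect_equal(irv$per_rater[[1]], 1.96 * sd(c(0.4, 0.6, 0.4, 0.6)) / 2)
  expect_equal(irv$per_rater[[2]], 0)     # identical confidences: zero spread

  # rater average over two repeated cases is the mean of per-case irv
  d2 <- diamond_standard(matrix("A", 4, 1), alphabet = "A",
                         case_ids = c("c1", "c1", "c2", "c2"),
                         repetition_group = c("c1", "c1", "c2", "c2"))
  cm2 <- confidence_matrix(matrix(1, 4, 1), scale_min = 0, scale_max = 1)
  cm2$corrected <- matrix(c(0.2, 0.8, 0.5, 0.5), 4, 1)
  irv2 <- intra_rater_variability(d2, cm2)
  expect_equal(irv2$per_rater[[1]], mean(irv2$per_case$irv))

  expect_error(intra_rater_variability(
    diamond_standard(matrix("A", 2, 1), alphabet = "A",
                     case_ids = c("a", "b")), cm2),
    "no repetition groups")
})

test_that("interval rho brackets the point estimate and matches hand values", {
  d <- diamond_standard(matrix(c("A", "A"), 1, 2), alphabet = c("A", "B"))
  cm <- confidence_matrix(matrix(1, 1, 2), scale_min = 0, scale_max = 1)
  cm$corrected <- matrix(0.5, 1, 2)
  ri <- interval_rho(d, cm, irv = c(0.1, 0.1), pair_correct = 1)
  expect_equal(ri$lo, 0.16)
  expect_equal(ri$hi, 0.36)
  expect_equal(ri$midpoint, 0.26)
  expect_equal(ri$point, 0.25)   # midpoint exceeds it by the squared shift
  expect_true(ri$lo <= ri$point && ri$point <= ri$hi)

  # degenerate interval at zero irv
  ri0 <- interval_rho(d, cm, irv = c(0, 0), pair_correct = 1)
  expect_equal(ri0$lo, ri0$hi)
  expect_equal(ri0$lo, ri0$point)

  # width shrinks to zero as irv shrinks
  widths <- sapply(c(0.2, 0.1, 0.05, 0.01), function(e) {
    r <- interval_rho(d, cm, irv = rep(e, 2), pair_correct = 1)
    r$hi - r$lo
  })
  expect_true(all(diff(widths) < 0))

  # raising any single confidence never decreases the upper endpoint
  set.seed(5)
  p <- random_panel(6, 3)
  pan <- rater_panel(p$d$rater_ids, rep(0.8, 3))
  hi1 <- interval_rho(p$d, p$conf, pan, irv = rep(0.05, 3))$hi
  p$conf$corrected[2, 1] <- min(1, p$conf$corrected[2, 1] + 0.3)
  hi2 <- interval_rho(p$d, p$conf, pan, irv = rep(0.05, 3))$hi
  expect_gte(hi2, hi1)
})

test_that("baseline coefficients match hand counts and independent oracles", {
  labs <- matrix(c("A", "A", "A", "B", "B", "B", "B", "A"), 4, 2,
                 byrow = TRUE)
  d <- diamond_standard(labs, alphabet = c("A", "B"))
  base <- baseline_agreement(d)
  expect_equal(base$p_o, 0.5)

  unan <- diamond_standard(matrix("A", 4, 3), alphabet = c("A", "B"))
  bu <- baseline_agreement(unan)
  expect_equal(bu$p_o, 1)
  expect_true(bu$degenerate)
  expect_true(is.na(bu$fleiss_kappa) && is.na(bu$krippendorff_alpha))

  set.seed(31)
  for (rep in 1:10) {
    labs <- matrix(sample(c("A", "B", "C"), 25, replace = TRUE), 5, 5)
    if (length(unique(as.vector(labs))) < 2) next
    d <- diamond_standard(labs, alphabet = c("A", "B", "C"))
    b <- baseline_agreement(d)
    expect_equal(b$fleiss_kappa, oracle_fleiss(labs), tolerance = 1e-12)
    expect_equal(b$krippendorff_alpha, oracle_alpha(labs), tolerance = 1e-12)
  }
})

test_that("ordering 0 <= rho <= sigma <= P_o <= 1 holds on random panels", {
  set.seed(77)
  for (rep in 1:25) {
    p <- random_panel(sample(3:12, 1), sample(2:5, 1))
    pan <- rater_panel(p$d$rater_ids, runif(p$d$n_raters, 0.5, 1))
    sig <- degree_of_concordance(p$d, p$conf)$sigma
    rho <- degree_of_weighted_concordance(p$d, p$conf, pan)$rho
    po <- baseline_agreement(p$d)$p_o
    expect_true(0 <= rho && rho <= sig + 1e-12 &&
                  sig <= po + 1e-12 && po <= 1)
  }
})

test_that("pairwise-complete handling drops missing pairs, not whole cases", {
  labs <- matrix(c("A", "A", NA,
                   "A", "B", "B"), 2, 3, byrow = TRUE)
  d <- diamond_standard(labs, alphabet = c("A", "B"), allow_missing = TRUE)
  cm <- confidence_matrix(matrix(1, 2, 3), scale_min = 0, scale_max = 1)
  cm$corrected <- matrix(0.8, 2, 3)
  # case 1: one valid pair (agreeing, 0.64); case 2: 3 pairs, one agreeing
  sig <- degree_of_concordance(d, cm)
  expect_equal(sig$per_case, c(0.64, 0.64 / 3))
})
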