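---
title: "Auditing multi-rater annotation quality: concordance, fineness and correspondence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing multi-rater annotation quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoqc)
```

## The problem

Supervised models in high-stakes domains (medical imaging above all) are
trained against a *Gold Standard*: one reference label per case. That label is
almost never "the truth"; it is the output of a *reduction* applied to a
*Diamond Standard* — the full cases-by-raters matrix of independent
annotations. `annoqc` quantifies three distinct quality dimensions of this
pipeline:

* **Reliability** of the raw annotations: how much of the observed agreement
  is genuine rather than chance — the *degree of concordance* \(\sigma\) and
  *degree of weighted concordance* \(\varrho\).
* **Accuracy** of the reduced labels: the *degree of fineness* \(\Phi\), the
  expected fraction of Gold Standard labels matching the (unknown) truth.
* **Representativeness** between feature datasets: the *degree of
  correspondence* \(\Psi\), a bootstrap p-value that a smaller dataset is
  drawn from the same population as a larger one.

Everything is testable without external data through the seeded synthetic
generators (`simulate_panel()`, `simulate_features()`).

## Reliability: confidence-discounted concordance

For cases \(S\), raters \(R\) (\(|R| = m\)) and corrected confidences
\(\hat c_i(x) \in [0,1]\), the genuine-agreement credit of a rater pair on a
case is

\[
GA_x(r_i, r_j) =
\begin{cases} 0 & r_i(x) \ne r_j(x)\\
\hat c_i(x)\, \hat c_j(x) & \text{otherwise,}\end{cases}
\]

the degree of concordance is the pair-normalised case average

\[
\sigma(S,R,C) = \frac{1}{|S|}\sum_{x}\binom{m}{2}^{-1}
  \sum_{i<j} GA_x(r_i,r_j),
\]

and \(\varrho\) multiplies each pair credit by the probability that the
agreeing labels are *correct* given the agreement. The package's default
correctness model assumes independent raters with accuracies \(a_i\) and
errors spread uniformly over the \(|Y|-1\) wrong labels:

\[
P(\text{both correct} \mid \text{agree}) =
 \frac{a_i a_j}{a_i a_j + (1-a_i)(1-a_j)/(|Y|-1)} .
\]

The model is pluggable (`pair_correct` accepts a constant, a function, or a
per-pair matrix) because the correctness-given-agreement term is genuinely a
modelling choice: any monotone alternative preserves the ordering properties
below.

Chance is discounted through the raters' *own* reported confidence, not
through the observed label distribution. This is the key difference from
Fleiss' \(\kappa\) and Krippendorff's \(\alpha\) (provided for side-by-side
reporting by `baseline_agreement()`): on a confident panel the raw proportion
of agreement \(P_o\) far exceeds \(\varrho\), and the package guarantees
\(0 \le \varrho \le \sigma \le P_o \le 1\) whenever pair correctness is at
most 1.

### Confidence correction

Raw ordinal confidence levels (e.g. a 6-point semantic differential) are
mapped onto \([0,1]\) by an affine rescale by default; a `chance_floor`
variant mapping onto \([1/|Y|, 1]\) and arbitrary user functions are
supported, since different elicitation scales warrant different corrections.
The correction must be monotone; nothing else in the pipeline depends on its
exact shape.

### Intra-rater variability and the interval estimate

Hidden repetitions of the same case measure each rater's self-consistency:
with \(k\) presentations and confidence standard deviation \(c^r_\sigma(x)\),

\[ irv(x,r) = 1.96\, c^r_\sigma(x) / \sqrt{k}, \qquad
   irv(r) = \text{mean over repeated cases}. \]

Shifting every confidence of rater \(r\) by \(\pm irv(r)\) (clipped to
\([0,1]\)) gives the interval estimate
\([\varrho(C_*), \varrho(C^*)]\), which `interval_rho()` reports together
with the midpoint *and* the point estimate. The two differ slightly by
construction: the agreement credit is a product of confidences, so
\((c-e)(c-e)\) and \((c+e)(c+e)\) average to \(c^2 + e^2\), not \(c^2\). We
deliberately evaluate the interval verbatim and report both values rather
than forcing the midpoint identity; the sample (\(n-1\)) standard deviation
is used because \(k\) is small.

## Accuracy: the degree of fineness

Under the model of \(m\) independent raters with constant error rates
\(\eta_i\), the number of erring raters on a case is Poisson-binomial. The
majority label is wrong when a strict majority errs, so

\[ P_{maj}(\text{error}) = P\!\left(X \ge \tfrac{m+1}{2}\right),
   \qquad X \sim \text{PoissonBinomial}(\eta_1,\dots,\eta_m), \]

computed exactly by the standard \(O(m^2)\) convolution dynamic programme
(`fineness_majority_exact()`), never by enumerating error patterns — the
enumeration survives only as the brute-force oracle in the test suite. The
degree of fineness is \(\Phi = 1 - P_{maj}(\text{error})\).

Numerical/edge choices:

* **Even panels.** The strict-majority threshold presumes odd \(m\); for even
  \(m\) the tie outcome is counted as an error with probability
  `even_tie_prob` (default 1/2, an indifferent tie-break).
* **Ties in argmax reductions** (`reduce_majority()`, `reduce_weighted()`)
  resolve deterministically: largest confidence sum first, then first label
  in the alphabet. Reproducibility beats elegance here.
* **The exponential bound** (`fineness_majority_bound()`),
  \(\exp\{-\frac{m+1}{2}\log\frac{m+1}{2\mu}\}\) with \(\mu = \sum_i\eta_i\),
  is reported with a vacuity flag. For small panels it can undercut the exact
  error probability (at \(m=3\), \(\eta \equiv 0.19\): bound 0.0812 vs exact
  0.0946) because terms were dropped in its derivation; it is therefore never
  used by the planner, which always sweeps the exact computation.
* **Probabilistic reduction errors** (`prob_reduction_error()`,
  `prob_reduction_error_k()`) follow the binary-alphabet resampling model
  verbatim; multi-class users should estimate via simulation. The
  \(k\)-resample error decreases towards the majority error when the
  single-resample error is below 1/2 — a numerical observation we test at
  that regime, not an enforced invariant, because it fails outside it.

The planner `min_raters_for_fineness()` returns the smallest odd panel whose
exact \(\Phi\) reaches a target. At rater accuracy 0.81 and target 0.95 it
returns 7; at accuracy 0.89 it returns 3. Two consequences worth keeping in
mind when reading model scores: a model measured at 96% accuracy against a
Gold Standard produced by three 89%-accurate raters is at most
\(0.96 \times \Phi_{maj} \approx 93\%\) accurate in truth; with three
81%-accurate raters, 87%.

### What the fineness model assumes

Constant, independent error rates. `simulate_panel(rho_err = ...)` breaks the
independence on demand: with probability `rho_err` a case is judged by all
raters against one shared latent draw, so raters err together while marginal
accuracies stay intact. In that regime the empirical majority-Gold accuracy
falls strictly below \(\Phi\) — the direction of over-estimation one should
expect with human raters, who share difficult cases. The same mechanism
explains the behaviour of `estimate_accuracy_majority()`: under independent
errors the leave-one-out majority is itself fallible and the estimator
*under*-shoots (converging as \(m\) grows), while under shared-difficulty
errors jointly wrong agreements are counted as hits and it *over*-shoots —
which is the pattern observed with real rater panels.

## Representativeness: the degree of correspondence

Given a larger dataset \(P\) and a smaller one \(G\) on the same features:

1. compute the pairwise-distance distribution of \(P\);
2. match each instance of \(G\) to a distinct instance of \(P\) by
   minimum-cost assignment (an exact shortest-augmenting-path solver,
   implemented in C++ because it sits inside the bootstrap loop);
3. substitute each matched instance (sizes preserved) and compute the
   deviation \(\delta\) between the pre- and post-substitution distance
   distributions;
4. repeat on random size-\(|G|\) splits of the merged dataset to build the
   null distribution of deviations;
5. \(\Psi = (1 + \#\{\delta^* \ge \delta\}) / (1 + n_{boot})\).

Design choices and their reasons:

* **Null construction.** Random same-size splits of the merged dataset are
  exactly the exchangeable construction under which the observed \((P, G)\)
  is one draw, so \(\Psi\) is a valid p-value; the \(+1/+1\) correction keeps
  it in \((0, 1]\). \(\Psi = 1\) exactly when \(G \subset P\) (the matching
  cost — and hence \(\delta\) — is 0, and no bootstrap deviation can be
  smaller).
* **Deviation statistics.** The comparison is univariate by construction
  (distance multisets), so the two-sample Kolmogorov–Smirnov statistic is the
  default; a Jensen–Shannon distance on Freedman–Diaconis-binned distances
  and an RBF maximum mean discrepancy (median-heuristic bandwidth) are
  available. The MMD path thins each multiset to at most 1024 evenly spaced
  order statistics — deterministically — because its kernel sums are
  quadratic in the multiset size.
* **Standardisation.** Features are z-scored with \(P\)'s statistics before
  distances are taken (Euclidean by default), making \(\Psi\) invariant to
  feature scaling conventions; disable with `standardize = FALSE`. \(\Psi\)
  is invariant to common feature permutations and rigid translations either
  way.
* **Cost.** The distance stage dominates at
  \(O((|P|+|G|)^2)\) and is computed once; each bootstrap split reuses the
  same matrix. The KS path additionally exploits the fact that distances
  among unchanged instances appear in both multisets and cancel from the two
  empirical cdfs, so only pairs touching a matched row are sorted.

`instance_compatibility()` is the \(|G| = 1\) case: the degree to which a
single new case is represented in a dataset. `univariate_representativeness()`
is the feature-independent alternative (KS or \(\chi^2\) per feature,
aggregated by mean or minimum); it cannot see correlation structure, which is
the reason the multivariate \(\Psi\) exists. `robustness_ratio()` divides a
model's measured accuracy by \(\Psi\) and is reported verbatim with a caveat:
the ratio explodes as \(\Psi \to 0\), so it flags unsupported accuracy claims
rather than certifying robustness. `max_divergent_split()` returns, among
seeded random candidate splits, the one with minimal test-vs-train \(\Psi\) —
a stress split; note it optimises only over the candidates it draws.

## The evidence-theoretic reading of \(\sigma\)

A rater who decided with probability \(\hat c\) and guessed otherwise is a
*simple mass function*: mass \(\hat c\) on their label, \(1-\hat c\) on the
whole frame. Dempster's rule credits one-sided confidence as agreement
(\(s_1 s_2 + s_1(1-s_2) + (1-s_1)s_2\)), so it cannot measure *genuine*
agreement; the Dubois–Prade (disjunctive) rule yields exactly \(s_1 s_2\),
and mixing-averaging the agreeing pairs, weighting by pair counts, reproduces
\(\sigma\) precisely. `sigma_via_evidence()` implements this route through
the actual mass-function machinery and serves as an independent oracle for
`degree_of_concordance()` — the equality is asserted to \(10^{-12}\) on
random panels in the test suite. In the pair-count weighting we use
\(\binom{k_y}{2}\) (the number of agreeing pairs among the \(k_y\) supporters
of label \(y\)), which is the combinatorial factor that makes the two routes
coincide.

## The synthetic generators

`simulate_panel()` emulates a rater study: true labels from a class prior,
per-rater accuracies, wrong labels uniform over the remaining alphabet,
confidence drawn from a scaled Beta conditional on correctness (defaults:
mean 0.8 when correct, 0.6 when incorrect, precision 10 — a moderate
confidence–accuracy coupling), optional shared-difficulty error correlation,
and hidden repeated presentations whose confidences are jittered with sd
`rep_conf_sd = 0.09` (chosen so that the average intra-rater variability at
\(k = 5\) lands near 0.08, the self-consistency level typical of trained
raters). What it does **not** emulate: case-difficulty heterogeneity beyond
the single shared flag, rater-specific bias toward particular labels, label
noise that depends on the true class, or drift over the annotation sequence.
Passing tests on these panels therefore validate the *computations*, not the
realism of any particular clinical dataset.

`simulate_features()` draws Gaussian mixtures with configurable means,
covariances and weights; `subset_split()` produces disjoint \((P, G)\) pairs
for subset scenarios.

## Problem sizes used by the test suite

The suite checks every metric against independent oracles (exhaustive
enumeration for the Poisson-binomial tail up to \(m = 12\); brute-force
assignment up to \(|G| \le 6\), \(|P| \le 8\); direct-sum \(\sigma\); a
second, differently coded route for \(\kappa\) and \(\alpha\)) and exercises
the statistical claims at these scales, chosen to give stable verdicts at
desk scale: accuracy recovery and fineness validation on panels of
\(|S| = 2000\); \(\Psi\) calibration under the null on 200 replicates at
\(|P| = 300\), \(|G| = 60\), \(n_{boot} = 199\) (a KS test must not reject
uniformity of the 200 \(\Psi\) values at \(\alpha = 0.01\)); power against a
3\(\sigma\) mean shift — applied to every feature, as the shift direction is
a free choice — on 50 replicates at \(|P| = 400\), \(|G| = 100\), requiring
rejection at \(\Psi < 0.05\) in at least 95% of them.

## Known limitations

* The fineness model is exactly as strong as its independence and
  constant-error assumptions; treat \(\Phi\) as an optimistic upper bound.
* `prob_reduction_error()` is binary-alphabet only, as defined.
* \(\Psi\) at small \(n_{boot}\) is discrete on a \(1/(n_{boot}+1)\) grid;
  use 999+ bootstraps for reporting, 199 for screening.
* The exact assignment solver is cubic in \(|G|\) for square problems; for
  very large \(G\) consider subsampling — approximate matching is out of
  scope.
* The confidence correction applied to ordinal scales is a declared
  convention, not an estimate; sensitivity to it should be checked with the
  `chance_floor` or a custom correction when conclusions are close.
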