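---
title: "Probability calibration for clinical risk models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability calibration for clinical risk models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calibrisk)
```

## The problem

A risk model for a binary clinical outcome — here, relapse within 3 years
in diffuse large B-cell lymphoma (DLBCL) — must do two different things
well.  *Discrimination* is ranking: patients who relapse should receive
higher scores than patients who do not (measured by the AUC).
*Calibration* is accuracy of the probabilities themselves: among patients
given a risk of 0.30, about 30% should actually relapse.  Many standard
learners discriminate well but produce systematically distorted
probabilities: naive Bayes tends to push scores toward 0 and 1 because
its class-conditional independence assumption fails on correlated
clinical predictors, random-forest voting ratios are compressed away from
the extremes, and an SVM's min–max-normalised decision values are not
probabilities at all.  Probability calibration fits a monotone map
$f : [0,1] \to [0,1]$ from initial scores to corrected probabilities,
estimating $f(s) = P(Y = 1 \mid S(x) = s)$ on held-out predictions.

`calibrisk` implements this programme end to end: a synthetic cohort
generator with a known outcome model, five base learners, three
calibration methods, the evaluation metrics, and a repeated hold-out
experiment driver.  This vignette records the model assumptions, the
tunable parameters and their defaults, the numerical choices, and what
the packaged tests do and do not demonstrate.

## The synthetic cohort generator

The real cohort this design emulates is not publicly available, so the
generator is a first-class module rather than a test fixture.  It draws
each of 15 categorical baseline features independently from published
marginal frequencies of a 510-patient DLBCL cohort (`dlbcl_features()`),
and generates the outcome from a multivariable logistic model whose
log-odds coefficients for seven predictors — sex, stage, IPI, KPS, GCB
subtype, CD10 and rituximab — are the published estimates
(`dlbcl_coefficients()`).  The remaining eight features (age, WBC, LDH,
beta2-microglobulin, ESR, Bcl-6, MUM-1, Ki-67) are generated but carry no
effect, so feature-selection procedures face genuine noise variables.

Three design points deserve emphasis:

* **Feature independence.**  Only marginal frequencies are published, so
  features are sampled independently; the only joint structure in the
  data is the outcome model itself.  This matters for interpretation: on
  real data naive Bayes is miscalibrated largely *because* predictors are
  correlated (IPI, for instance, incorporates stage and performance
  status).  Under the generator, its independence assumption nearly
  holds, and NB is about as well calibrated as logistic regression.
  Passing tests therefore demonstrate the machinery, not the real-data
  pathology of NB.
* **The intercept** is not published.  `solve_intercept()` recovers it by
  exact enumeration of all $2 \cdot 4 \cdot 4 \cdot 2 \cdot 2 \cdot 2
  \cdot 2 = 1024$ level combinations of the causal predictors, weighted
  by their marginal probabilities, and monotone root-finding so that the
  expected event rate equals 181/510 (tolerance `1e-4`; the expected rate
  is strictly increasing in the intercept, so the root is unique).
  Enumeration is preferred over Monte Carlo because it is exact and
  cheap.
* **The score-level testbed.**  `make_score_testbed()` supplies
  (score, label) pairs whose true calibration map is known: true
  probabilities $p \sim U(0.01, 0.99)$, labels Bernoulli, and observed
  scores $s = p^\gamma / (p^\gamma + (1-p)^\gamma)$.  This distortion
  family was chosen because it is monotone, maps $[0,1]$ onto itself,
  has the analytic inverse $f^*(s) = s^{1/\gamma}/(s^{1/\gamma} +
  (1-s)^{1/\gamma})$, and reproduces the two clinically observed failure
  modes: $\gamma > 1$ gives overconfident (NB-like) scores, $\gamma < 1$
  underconfident (SVM-like) ones, and $\gamma = 1$ leaves scores
  perfectly calibrated.

Non-goals: feature–feature correlation, missing data, censoring and
survival time are outside the generator's scope.

## Base models and their protocol

All five learners see the seven causal predictors as categorical inputs
(one-hot encoded for SVM/FFNN, reference-coded dummies for LR, factors
for NB/RF) and output probabilities in $[0,1]$:

| family | probability output | tuned over |
|--------|--------------------|------------|
| NB     | posterior (Laplace smoothing $\alpha = 1$) | — |
| LR     | logistic posterior | — |
| RF     | fraction of trees voting for relapse | trees $\in \{500, 600, \dots, 1500\}$, candidate attributes $\in \{2, 3\}$ |
| SVM    | min–max-normalised decision value | kernel $\in$ {linear, Gaussian}, $C, \gamma \in \{10^{-4}, \dots, 10^4\}$ |
| FFNN   | sigmoid output unit | training epochs (validation early stopping) |

Where the protocol leaves a choice open, the package fixes it as follows:

* **CV selection criterion**: stratified 3-fold cross-validation
  maximising validation AUC, since classification ability is the
  foundation the whole evaluation builds on.  Ties break toward the
  simplest candidate (fewest trees, linear kernel and smallest cost
  first, fewest epochs).
* **FFNN epochs**: the one exception.  An iteration cap chosen by
  validation *AUC* never stops early — validation AUC keeps improving
  while the network grows overconfident — so the epoch cap is chosen by
  validation log-loss, the criterion early stopping actually monitors
  and the reason well-trained networks yield calibrated probabilities.
  The architecture is one hidden layer of logistic units (default 1000)
  with a cross-entropy loss; weight decay defaults to 0.
* **NB smoothing** is Laplace add-one; **RF** grids step by 100 trees.
* **SVM normalisation bounds** are the minimum and maximum decision
  values on the *training* data only (leakage-safe); test values outside
  the bounds clip to $[0,1]$, and degenerate bounds (max = min) map
  everything to 0.5.  Decision values are sign-oriented so that larger
  means higher risk before normalising.

`tune_and_fit()` also returns the validation-fold predictions of the
winning configuration (`$oof`): each training row is predicted exactly
once by a model that did not train on it.  These out-of-fold scores are
the calibration training set, which is what keeps the calibrators
leakage-free.

Two feature-screening analyses accompany the models:
`select_predictors_lr()` fits the full 15-variable logistic model and
keeps variables whose smallest per-dummy Wald p-value is below 0.1
(screening at the variable level, so a multi-level variable survives as a
whole — which is also why a single weak dummy such as an intermediate
stage can legitimately appear among the selected terms), and
`rank_importance_rf()` reports out-of-bag permutation importance and mean
Gini decrease with their rank orders.

## The three calibration maps

**Platt scaling** fits $f(s) = 1/(1 + \exp(As + B))$ by maximum
likelihood.  The binary targets are smoothed — positives become
$(N_+ + 1)/(N_+ + 2)$, negatives $1/(N_- + 2)$ — which regularises the
fit and keeps the loss strictly interior.  The smoothed cross-entropy is
minimised by damped Newton iteration with backtracking, started at
$(A, B) = (-1, 0)$, declared converged when the gradient sup-norm falls
below `1e-8`.  With risk-oriented scores the fitted $A$ is negative.

**Isotonic regression** solves $\min \frac1N \sum_i (f_i - y_i)^2$
subject to $f_1 \le \dots \le f_N$ over the score-sorted calibration set,
by the pair-adjacent-violators algorithm: adjacent blocks whose means
violate monotonicity are pooled into their average until the sequence is
nondecreasing.  Prediction is interval lookup on the resulting step
function; scores outside the training range clamp to the terminal levels
(the natural extension of a step function).  Ties in training scores keep
their input order (stable sort), making fits reproducible.

**Shape-restricted polynomial regression (RPR)** fits
$f(s) = \sum_{l=0}^{k} a_l s^l$ by

$$\min_a \frac1N \sum_n \Big(\sum_l a_l s_n^l - y_n\Big)^2
\quad \text{s.t.} \quad f(\underline{s}) \ge 0,\; f(\bar{s}) \le 1,\;
f'(s) \ge 0 \text{ on } [\underline{s}, \bar{s}],\;
\sum_{l=0}^{k} |a_l| \le \lambda .$$

Numerical choices, in order of consequence:

* The $\ell_1$ budget includes the intercept ($l = 0$), and
  $\lambda \ge 1$ is required since any smaller budget excludes the
  identity map.
* The problem is a convex QP after coefficient splitting
  ($a = u - v$, $u, v \ge 0$, $\sum(u + v) \le \lambda$), solved with
  the dual active-set method of `quadprog` (a ridge of `1e-10` on the
  split Hessian keeps it positive definite).  Active-set solutions
  satisfy their constraints to machine precision.
* The semi-infinite monotonicity constraint is discretised on 201
  equally spaced points, then *audited* on 2001 points; any audit point
  with a negative derivative is appended to the constraint set and the
  QP re-solved (cutting planes, at most 10 rounds).  In practice zero or
  one round suffices and final violations sit at the `1e-12` level —
  discretisation alone leaves dips up to ~`1e-4` between grid points,
  which is why the refinement exists.
* Domain endpoints default to $(0, 1)$ because every base scorer already
  outputs in $[0,1]$; prediction clamps scores into the domain and clips
  the polynomial value to $[0,1]$ as a guard (the constraints already
  bound it there up to solver tolerance).
* Degree and budget are selected by stratified 3-fold CV over
  $k \in \{4, \dots, 20\}$ and $\lambda \in \{4^0, \dots, 4^5\}$,
  minimising validation squared error — the same loss the fit minimises —
  with ties toward smaller $k$, then smaller $\lambda$.  Single-class
  folds are redrawn with a fresh seed, at most five times.
* The raw monomial basis is deliberately retained (rather than an
  orthogonal basis) because the $\ell_1$ constraint is defined on these
  coefficients; the $\lambda$ budget, not the basis, controls the
  conditioning that matters, and fits up to $k = 20$ remain stable.

All three calibrators are monotone, so they cannot improve or damage
discrimination — with one caveat measured honestly below.

## Metrics

Binning: examples are sorted by score (stable) and split into $k$ bins
whose sizes differ by at most one (larger bins first).  $k = 10$ — the
decile convention of the Hosmer–Lemeshow literature — is the default
everywhere and is configurable; reported results should state $k$.

* $\mathrm{ECE} = \sum_i |p_i - o_i| / k$ and
  $\mathrm{MCE} = \max_i |p_i - o_i|$, where $p_i$ is the mean predicted
  risk and $o_i$ the observed event rate of bin $i$.  Both are reported
  ×100, in percentage points, matching how such tables are usually
  printed.
* The Hosmer–Lemeshow statistic
  $C = \sum_i \sum_{c \in \{0,1\}} (O_i^c - P_i^c)^2 / P_i^c$ is referred
  to a chi-square with $k - 2$ degrees of freedom.  Bins whose expected
  count in either class falls below `1e-10` are merged toward the centre
  first (near-deterministic scorers such as NB otherwise divide by
  zero); if fewer than 3 bins survive, the test is undefined and is
  reported as a missing p-value.
* A caution the package's own simulations quantify: the $k-2$ reference
  is derived for probabilities *fitted* on the same data.  For
  externally specified probabilities (scores equal to the true risks,
  as in the generator's null testbed) the statistic behaves like
  chi-square with $k$ df, and the $k-2$ test over-rejects — about 13%
  at $n = 510$, $k = 10$, against a nominal 5%.  "Well-calibrated
  frequency" counts based on p > 0.05 are therefore conservative.
* AUC is the Mann–Whitney statistic with midrank tie handling; the
  Brier score is the mean squared error of the probabilities.

## The experiment protocol

One repetition of `run_repetition()`: (i) stratified split, training
fraction 2/3 with per-stratum rounding (510 rows with 181 events give
exactly 340 training / 170 test); (ii) per family, hyperparameter tuning
by stratified 3-fold CV, refit on the full training set, prediction of
the test set; (iii) per family, Platt, isotonic and RPR calibrators
fitted on that family's own out-of-fold predictions (each algorithm's
calibrator sees that algorithm's scores — pooling scores across
algorithms would break per-model calibration), RPR hyperparameters by CV
on the calibration set within each repetition (the leakage-safe
reading); (iv) evaluation of all 20 score vectors.  Test labels are only
ever touched by the metrics.

Repetition seeds are `seed + 1, ..., seed + R`, so a master seed
reproduces the experiment exactly and per-repetition records are
bitwise stable.  The full protocol uses R = 500 repetitions;
`tidy()` aggregates each metric as median and quartiles (linear
interpolation), `count_well_calibrated()` applies the p > 0.05 rule
(undefined tests count as not well-calibrated), and
`prediction_histogram()` reports median per-interval counts over the
fixed cut points 0.1, 0.2, ..., 1.

**Problem sizes in the packaged runs.**  The test-suite and the
acceptance script exercise the identical protocol at reduced size, the
package's chosen configuration for a single-CPU run: 20–50 repetitions;
RF trees $\{500, 1000\}$; SVM $C \in \{0.1, 1, 10\}$,
$\gamma \in \{0.01, 0.1, 1\}$ (subsets of the full grids); FFNN with 50
hidden units and epoch ladder $\{10, 25, 50\}$ — the BFGS optimiser
behind `nnet` scales superlinearly in the weight count, and at this
cohort size a 50-unit network reaches the same training discrimination
as the 1000-unit default; RPR grids $k \in \{4, 6, 8\}$,
$\lambda \in \{1, 4, 16\}$.  All full-size grids remain the defaults of
`model_spec()` and `experiment_config()`.

## What the tests show — and known limitations

* **Calibrator correctness** is checked against independent oracles:
  PAV against the minimax characterisation of isotonic regression over
  every label pattern up to $n = 8$ (and against `stats::isoreg` on
  random data); Platt against the generating sigmoid parameters and a
  grid audit of local optimality; RPR against random feasible
  polynomials and a dense-grid constraint audit.
* **AUC preservation**: Platt and RPR preserve the AUC exactly in exact
  arithmetic, and the experiment verifies equality at the `1e-12` level
  — with two measured exceptions.  A PAV step function maps distinct
  test scores within one block to a common level, and the midrank AUC
  then typically moves by 0.003–0.03; order is never inverted, but exact
  AUC equality is impossible for a step function.  And in double
  precision, two raw scores about one ulp apart can collapse to the same
  calibrated value under any smooth map (observed roughly once per
  hundred model-repetitions), stepping the AUC by $0.5/(n_1 n_0)$.
* **Generator fidelity has limits.**  Independent features mean naive
  Bayes is nearly well-calibrated here, unlike on real correlated
  predictors; conclusions about *which* base model most needs
  calibration do not transfer from this generator to clinical data.
  What does transfer: the calibrators demonstrably repair distorted
  scores (on the $\gamma = 3$ testbed RPR cuts the ECE by far more than
  half), leakage-free protocol plumbing, and all metric arithmetic.
* The package models neither censoring nor missingness, performs no
  external validation, and implements no further calibration families
  (histogram binning, smoothed isotonic variants, Bayesian binning):
  one parametric, one nonparametric and one flexible shape-restricted
  method span the design space the experiment compares.
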