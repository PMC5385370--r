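---
title: "Transfer recursive feature elimination: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer recursive feature elimination: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfe)
```

## The problem

Emotion classifiers built from EEG are usually subject-specific: every new
user must supply labeled training recordings before the classifier works for
them. The alternative — training on a pool of *source* subjects and applying
the model to a new *target* subject — fails naively because EEG features are
non-stationary and differently distributed across individuals. The package
implements a feature-selection route to cross-subject transfer: find the
features that are discriminative for the valence/arousal classes *and*
geometrically stable between the source pool and the target subject, and
train a linear classifier on those.

Three ingredients cooperate:

1. a **linear least-squares SVM (LSSVM)** whose squared weights score
   feature salience,
2. **recursive feature elimination (RFE)**, which turns those scores into a
   full ranking by repeated retrain-and-drop passes, and
3. the **transfer extension (T-RFE)**, which adds a second score term — the
   source–target class-center distance that would remain after a feature's
   removal — so that elimination prefers features that are both
   non-discriminative and responsible for cross-subject discrepancy.

## Data model and splits

A recording session consists, per subject, of 40 one-minute trials of
32-channel EEG at 128 Hz, each followed by 1–9 self-assessment ratings of
valence and arousal. Each trial is band-pass filtered (Butterworth, order 3,
4–45 Hz, `bandpass_filter()`) and split by `split_trial()` into a 10 s
**validating** segment and a 50 s **working** segment. Validating data drive
every model-selection decision (regularization choice, target-domain
anchoring, subject-specific rankings); working data train and test
classifiers. For a testing subject the validating segments are the small
labeled target-domain sample; their working segments are strictly held out,
which is what keeps the transfer pipeline free of test-set leakage.

### Features

`extract_features()` computes 440 features per segment in a fixed,
documented order (`feature_catalog()`):

* 160 band powers: 32 channels × bands theta (4–8), slow-alpha (8–10),
  alpha (8–12), beta (12–30), gamma (30–45 Hz);
* 56 hemispheric asymmetries: right-minus-left band power over 14 electrode
  pairs in four bands (slow-alpha excluded);
* 224 time-domain statistics: mean, variance, zero-crossing rate, Shannon
  entropy, spectral entropy, kurtosis, skewness per channel.

Band powers come from a single plain-FFT periodogram of the segment (no
windowing — the most literal reading of "power via FFT"; Welch-style
averaging was deliberately not made the default so that a bin-aligned tone
of amplitude $A$ has the exact closed-form power $A^2 n/4$, which the tests
exploit). Band intervals are half-open $[low, high)$ so that theta/alpha and
alpha/beta, whose printed edges touch, never double-count a bin.

Several time-domain statistics are underdetermined by their names; the fixed
conventions are: zero-crossing rate = sign changes / $(n-1)$ with zeros
inheriting the previous sign; amplitude entropy over 16 equal-width
histogram bins with natural logarithm; spectral entropy over the
periodogram normalized on the 4–45 Hz pass-band; kurtosis non-excess
(normal = 3); constant signals yield 0 for all of variance, ZCR, entropies,
kurtosis and skewness rather than an error.

Features are standardized per subject across that subject's trials
(`standardize_by_subject()`), with the **sample** (n−1) standard deviation,
matching R's `sd()` and the usual hand z-score (the column `1,2,3` maps to
`-1,0,1`); zero-variance columns map to 0. Standardizing within subject —
never across — removes per-subject scale and offset so they cannot leak
into cross-subject training.

### Labels

Rather than the conventional fixed cut at 5, per-subject thresholds adapt
to each rater's use of the scale: `fit_thresholds()` runs 2-means (10
seeded restarts, best within-cluster SS kept) on the 2-D rating cloud and
takes the midpoint of the two centers. Ratings **below** the threshold form
the low class, coded `+1`, which is the positive class of every metric
(sensitivity is low-class recall); ratings at or above it form the high
class, `-1`. The boundary convention mirrors the fixed-threshold literature
("low (< 5), high (≥ 5)").

## The LSSVM

Training solves
$$\min_{w,b,\xi}\ \tfrac12 w^\top w + \tfrac12\gamma\sum_i \xi_i^2
\quad\text{s.t.}\quad y_i\,(w\cdot x_i + b) = 1-\xi_i ,$$
whose KKT conditions collapse to one $(n{+}1)\times(n{+}1)$ linear system in
$(b, \alpha)$ with the linear kernel. Two conventions worth stating:

* the ridge block is the $n\times n$ identity scaled by $\gamma^{-1}$ — an
  identity of the *instance* dimension, which is the only dimensionally
  consistent reading of the dual system;
* the slack penalty is squared ($\sum\xi_i^2$); this is what the
  $\gamma^{-1}I$ ridge term corresponds to, and what the package solves.

The system is solved densely with partial pivoting; the reciprocal
condition number is checked, warned about below $10^{-10}$, and a singular
system raises an error carrying the estimate. Prediction is
$\tilde y = \mathrm{sign}(w\cdot x + b)$ with $\mathrm{sign}(0) := +1$,
fixed and tested. The dual expression
$\lVert w\rVert^2 = \alpha^\top(\Psi\Psi^\top)\alpha$ is exposed as
`margin_norm()` and must agree with $\sum_k w_k^2$ to $10^{-8}$.

An equivalent view used only for verification: eliminating the equality
constraints turns the training problem into an unconstrained ridge
regression in $(w, b)$. The test suite solves those normal equations
independently and requires agreement with the dual route to $10^{-6}$ on
random small instances — two genuinely different derivations of the same
optimum.

## Classical RFE

Each iteration trains on the surviving features and scores each survivor by
$w_k^2$, the margin-loss surrogate for the change of $\lVert w\rVert^2$ if
$k$ were removed; the $q$ lowest-scoring features are eliminated (default
$q = 10$, matching the evaluation step length). Ties are broken by lowest
original index, and the within-batch order is defined by successive
arg-min picks, so rankings are fully deterministic. $\gamma$ is held fixed
across iterations.

The surrogate deserves a precise statement. If the dual coefficients are
held fixed while feature $k$ is deleted from the linear kernel, then
$\lvert\,\lVert w\rVert^2-\lVert w_{(k)}\rVert^2\rvert = w_k^2$ *exactly* —
that is the classical fixed-coefficient SVM-RFE argument. After full
retraining the identity still holds exactly whenever the (centered) feature
columns are mutually orthogonal, because the ridge normal equations then
decouple coordinate-wise; on correlated designs retraining can reorder
near-tied features. The oracle-equivalence tests therefore draw decorrelated
instances (QR-orthogonalized against the intercept), where the brute-force
retrain-after-each-removal oracle and the $w_k^2$ path provably coincide;
using $\lvert w_k \rvert$ instead of $w_k^2$ would give identical orderings.

## T-RFE

For a testing subject $i$, the source domain is the pooled working data of
all other subjects and the target domain is subject $i$'s validating data
$V$. Initialization (`trfe_init()`) runs four steps:

1. **Regularization choice** (`select_gamma()`): candidates
   $\gamma_j = 2^{-5+j}$, $j = 1..15$, i.e. $2^{-4}..2^{10}$. Half of $V$
   is selected *evenly* — the odd 1-based positions 1, 3, 5, … — as the
   training half; each candidate is scored by
   $E = \tfrac12(P_{acc} + P_f)$ and the best (arg max, ties toward the
   smallest $\gamma$) is kept. Two deliberate choices here: the printed
   initialization pseudo-code says "arg min E", but selecting the *worst*
   classification performance contradicts the surrounding account of the
   procedure ("the optimal classification performance … yields the best
   value of γ"), so arg max is implemented. And scoring the same half one
   trains on rewards self-fit and tends to saturate at the largest
   $\gamma$; by default the score is computed on the held-out complement
   (`rule = "heldout"`), with the literal train-set scoring preserved
   behind `rule = "literal"` for auditability.
2. **Class centers** (`class_centers()`): means of $V$'s low-class and
   high-class rows, $v_P, v_N$ — computed from all of $V$, not the gamma
   half.
3. **Instance selection** (`select_instances()`): a source instance of
   class $C$ is kept iff its distance to $v_C$ is strictly below the mean
   of those distances over its class. The printed criterion $H_C < 0$
   normalizes the centered distance by a sum of centered terms that is
   identically zero as written; the only reading that makes it a
   non-trivial selector is the numerator's sign, which is what is
   implemented. Strictness at the boundary means the kept fraction is
   always below 1, and "all equidistant" keeps nothing.
4. **Adaptive training set**: $A = V \cup \tilde O$, with duplicates (if a
   synthetic collision puts one row in both) retained — the union is over
   instances, and a repeated row simply counts twice in the least-squares
   fit.

Ranking (`trfe_rank()`) then iterates like RFE on $A$ with $\gamma_o$, but
scores each surviving feature $k$ by
$$\Delta\tilde\Phi(k) = \lambda_1\,\kappa\!\left[w_k^2\right] +
  \lambda_2\,\kappa\!\left[d_P(k)+d_N(k)\right],$$
where $d_C(k)$ is the distance between $v_C$ and the selected-source class
mean over all surviving features *except* $k$, and
$\kappa(s) = (s-\bar s)/\lVert s-\bar s\rVert_2$ centers each term to zero
sum and unit norm (the printed dimensionality factors cancel). A feature
whose removal leaves a small remaining source–target distance is carrying
much of the discrepancy, so small $\Delta\tilde\Phi$ means "neither
discriminative nor domain-stable" and such features go first. Defaults are
$\lambda_1 = \lambda_2 = 0.5$ (equal prior importance of the two terms);
`tune_lambda()` offers the optional validating-set grid search over
$(0.1,0.9)\ldots(0.9,0.1)$ for users who want a data-driven pair.

Numerical details: $d_C(k)$ uses the exact Pythagorean downdate
$d_C(k)^2 = d_C^2 - \delta_k^2$ on the per-feature center gaps
$\delta$, verified against explicit recomputation to $10^{-10}$; centers
and source means are recomputed from the surviving features each iteration;
an all-equal $\kappa$ input (e.g. after a source class empties) becomes the
zero vector so the other term alone drives elimination; and when one
$\lambda$ is zero the ordering is taken from the raw surviving term, which
is the same ordering as its $\kappa$ transform (strictly increasing affine
map) but exact in floating point — this is what makes the
$\lambda_2 = 0$ reduction to classical RFE reproducible bit-for-bit. There
is no randomness anywhere in initialization or ranking.

## Evaluation harness

`loso_evaluate()` reproduces the five-scheme comparison under
leave-one-subject-out: `lssvm-ss` and `rfe-ss` (subject-specific; 10-fold
stratified seeded CV on the subject's working data, the RFE ranking
computed once from the subject's validating data and reused across folds),
`lssvm-sg` and `rfe-sg` (subject-generic; train on the pooled source
working data), and `trfe-sg`. Step $s$ of a curve uses exactly the
$s \cdot q$ top-ranked features; the optimal step per subject maximizes
$P_{acc}$ with ties broken toward fewer features, then higher $P_f$ (the
source account locates a best step but states no tie rule). Undefined
metric ratios (an empty predicted or true class at some step) are reported
as 0 with a flag instead of aborting the sweep.

One interpretation decision: for `trfe-sg` the step classifiers are trained
on the adaptive set $A$ with $\gamma_o$, not on the raw source pool. The
initialization explicitly calls $A$ "the training set", and the instance
selection exists to build a training set adapted to the target; training on
$A$ is the whole-method reading, and it is also where the scheme's accuracy
advantage comes from. The plain-RFE and no-selection generic schemes train
on the full source pool.

## The synthetic population

`make_feature_population()` plants the cross-subject structure the method
is designed to exploit, with defaults that are the package's study
conditions: 8 subjects × 40 trials, $D = 50$ features, 5 *transferable*
discriminative features (class-mean separation 1.5 noise-s.d., same sign
for every subject), 5 *subject-specific* discriminative features (same
separation, class-association sign re-flipped per subject — the simplest
mechanism that makes pooled selection favor them inconsistently), a
per-subject mean shift of s.d. 1.0 on every feature, and equicorrelated
noise ($\rho = 0.2$) within blocks of 10 features, a modest dependence
mimicking band-power features of neighboring channels. Each trial yields
two independent draws (validating and working) around the same trial mean,
emulating the two segments. Every generator is a pure function of
(spec, seed).

What this emulates is the *statistical* transfer structure only; it does
not attempt physiological realism (no 1/f spectra, no volume conduction,
no rating drift), so green tests certify the machinery and its planted-
structure behavior, not performance on recorded EEG.

Two measured properties of this population are worth knowing before
interpreting results on it (both are computed by the acceptance suite, not
asserted folklore): classes are balanced within subject, so per-subject
mean shifts cancel exactly in pooled class-mean differences and pooled RFE
recovers essentially all transferable features in its top ranks; and the
T-RFE distance term, built from class centers estimated on ~20 validating
rows per class, carries enough estimation noise that T-RFE's transferable
recall is *lower* than pooled RFE's, while its classification accuracy at
the optimal step is consistently *higher* — the accuracy gain comes from
the target-adapted training set, not from purer recovery of the planted
transferable set.

## Problem sizes and budgets

The test and acceptance workloads were sized to what the statistical
questions need: oracle equivalences on instances up to $n = 30$, $d = 10$;
identity checks in up to 50 dimensions; the scheme comparison on 10
replicate populations of the default spec with elimination step $q = 5$
(10 steps over $D = 50$). These are the package's chosen study sizes;
everything scales to the full 440-feature catalog through the same code
paths (the full-catalog ranking is exercised directly in the step-count
check).

## Known limitations

* The method requires labeled validating data from the target subject;
  without them there is no target anchor (a semi-supervised variant is out
  of scope).
* The adaptive-threshold values of any particular recorded cohort are not
  reproducible without that cohort's ratings and the clustering
  initialization; only the midpoint construction itself is testable.
* Binary containers for raw trial archives are not provided; trial signals
  enter through in-memory `trial_signal` objects or the CSV interchange
  for feature matrices.
* The instance-selection threshold (the class-mean distance) is fixed, as
  in the source procedure; it is not cross-validated.
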