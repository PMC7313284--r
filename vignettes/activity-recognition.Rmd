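---
title: "Hybrid WSVM-HMM activity recognition: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid WSVM-HMM activity recognition: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiseq)
```

## The model

`actiseq` classifies time-ordered windows of wearable-sensor features into
activities. Windows arrive as rows of a feature matrix $X \in
\mathbb{R}^{T \times p}$ with aligned integer labels $y_t \in \{1, \dots,
N\}$. The fitted object composes four sub-models.

**Range scaling.** Each feature is mapped affinely so its training range
becomes $[-1, 1]$: $x' = 2(x - \min)/(\max - \min) - 1$. Test values outside
the training range are deliberately *not* clipped — clipping would make the
map non-affine and distort kernel distances; a feature constant in training
maps to the midpoint 0.

**PCA.** We eigendecompose the scatter matrix $S = \sum_j (x_j - \mu)(x_j -
\mu)^\top$ (the unnormalized sum; its eigenvectors equal those of the sample
covariance and its eigenvalues are $(T-1)$ times larger, an identity the test
suite asserts). Scores are $(X - \mu) V_{1..k}$. The retained count $k$ is
the smallest reaching a cumulative explained-variance fraction, default
0.95 — a conventional choice, exposed as `variance_fraction` or an explicit
`k` in `hybrid_control()`.

**Weighted SVM.** Frame classification uses a Gaussian-kernel SVM,
$K(x, y) = \exp(-\lVert x-y \rVert^2 / 2\sigma^2)$, trained one-vs-one with
majority voting (the decomposition used by LibSVM-style multiclass SVMs).
Class imbalance is countered by per-class box constraints: with $m_i$
training windows in class $i$ and $m_+ = \max_i m_i$, class $i$'s cost is

$$C_i = \mathrm{round}(C \cdot m_+ / m_i),$$

rounded half away from zero and floored at 1, so a class one tenth the size
of the majority is ten times as expensive to misclassify. In the machine for
the pair $(i, j)$, class-$i$ samples are bounded by $C_i$ and class-$j$
samples by $C_j$. The costs are recomputed from the training split at hand
(including inside every cross-validation fold), since $m_+/m_i$ is a
property of the split, not of the population.

**Supervised HMM.** The label stream of a framewise classifier ignores that
activities persist across windows. We therefore model the sequence as a
hidden Markov chain whose hidden state is the true activity and whose
observation at time $t$ concatenates the PCA score vector with the WSVM's
estimated label. The joint factorizes as
$p(x, y) = \prod_t p(y_t \mid y_{t-1}) \, p(x_t \mid y_t)$,
and prediction maximizes it over state sequences with the Viterbi algorithm,
computed entirely in log space.

## Why out-of-fold label estimates

The HMM's categorical emission $p(\hat{y}_t \mid y_t)$ is precisely the
confusion behavior of the frame classifier. Resubstitution labels would make
that emission look nearly diagonal — far more reliable than the labels the
HMM will see at prediction time — so the smoothing would under-correct.
Training labels are therefore estimated *out of fold*: every training window
is predicted by a model whose training excluded that window's fold (same
fold count as the hyperparameter search, default 5, stratified by class). At
prediction time the labels come from the final full-training WSVM, the only
model available for unlabeled data.

## Emission model for a mixed observation

The observation concatenates a continuous part (scores) with a discrete part
(estimated label). We factorize the emission as a diagonal-covariance
Gaussian over the scores times a categorical over the label, independent
given the state. This keeps maximum-likelihood estimation closed-form (per-
state means/variances and smoothed label frequencies) while staying faithful
to the "concatenated observation" design; a full-covariance Gaussian or a
joint model of scores and label would need far more data per state. For
export and the CLI the discrete part is one-hot encoded (rows of width
$k + N$), but internally the categorical is used directly.

## Numerical choices

* **SMO solver.** Each binary dual is solved by sequential minimal
  optimization with maximal-violating-pair working-set selection, stopping
  when the KKT violation drops below $10^{-3}$ (matching common SVM library
  defaults), with an iteration cap that raises a convergence error reporting
  the remaining gap. Selection uses `which.max`, whose first-index tie rule
  makes runs bit-reproducible. The bias $b$ is the mean over free support
  vectors ($0 < \alpha_i < $ bound), or the midpoint of the KKT interval if
  none are free.
* **Eigenvector signs.** Each principal component's sign is fixed so its
  largest-magnitude entry is positive; eigenvalue ties keep the
  decomposition's output order.
* **Viterbi tie rule.** Ties take the smaller state index at every
  backtracking step. The exhaustive test oracle enumerates candidate
  sequences so that ascending order prefers smaller $y_T$, then $y_{T-1}$,
  and so on — the same total order the backtracking rule induces — and keeps
  the first strict maximum, so both decoders resolve exact ties identically.
* **Smoothing and floors.** Transition and categorical estimates use
  additive smoothing $\alpha = 1$ by default, avoiding $-\infty$ paths from
  unseen transitions; emission variances are floored at $10^{-6}$ (a state
  with a single observation gets the floor and a warning). With smoothing 0
  an impossible transition yields a log-joint of $-\infty$, not an error.
* **Cost rounding.** `round()` in R rounds half to even; the cost rule
  instead rounds half away from zero (2.5 → 3) and floors at 1, so every
  class keeps a positive box constraint.
* **Metrics.** Reported recall/precision are unweighted per-class (macro)
  means, the F-measure is the harmonic mean of those two averages, and all
  derived values are computed from unrounded internals; display rounding is
  one decimal, half away from zero. (Captions elsewhere sometimes call such
  averages "micro"; arithmetically they are macro averages, which is what
  this package implements and names.)
* **Grid search.** CV accuracy is maximized; ties prefer the smaller $C$,
  then the smaller $\sigma$ (less regularization pressure and a smoother
  kernel are the more conservative choices). Folds are stratified per class
  with a user-suppliable seed; the same seed reproduces fold assignment,
  hence the whole fit, bit for bit.

## The synthetic generator

`simulate_activity_data()` emulates the structure that makes this pipeline
interesting: a sticky first-order Markov chain over $N$ activities
($A = s I + (1 - s)\mathbf{1}w^\top$, whose stationary distribution is
exactly the normalized weight vector $w$ — imbalance is induced through the
chain rather than by subsampling, preserving realistic transitions), and
spherical Gaussian features around class means $d \cdot e_i$, so the
separation $d$ is the single difficulty knob. Note the realized
self-transition probability is $s + (1 - s) w_i$, slightly above $s$.

Defaults (6 classes, $p = 12$, $s = 0.9$, $d = 2$, unit noise, uniform
weights) mirror a typical six-activity recognition setting where runs last
tens of windows. The generator does **not** emulate raw tri-axial signals,
the correlated/heavy-tailed features real extraction pipelines produce,
postural-transition labels, or sensor drift — so green tests show the
pipeline's mechanisms work (imbalance handling, temporal smoothing, exact
decoding), not that any particular accuracy carries over to a real dataset.

## Problem sizes used by the tests and acceptance script

Experiments are sized to demonstrate each property clearly while keeping the
whole suite fast: smoothing-benefit runs use 3 classes, 6 features, training
and test sequences of 300 windows, stickiness 0.95, separation 1.5 (a
moderate-overlap regime where framewise errors leave clear smoothing
headroom) over 10 replicate seeds;
imbalance runs use a 95:5 two-class Gaussian toy (200 training, 400 test
windows) over 10 seeds; transition recovery uses a 20 000-window chain with
4 states; the Viterbi oracle check enumerates all state sequences for 100
random models with $N \le 4$, $T \le 8$.

## Limitations

* Supervised estimation only: the HMM is fitted from labeled sequences; no
  Baum-Welch, forward-backward posteriors, or unsupervised adaptation.
* The SMO solver precomputes the kernel matrix, so memory is $O(n^2)$ per
  binary subproblem — appropriate for the tens of thousands of windows of
  typical HAR feature sets, not for millions.
* One Gaussian per state: multimodal activities (e.g. a class pooling
  distinct postures) are modeled coarsely.
* Viterbi decodes a whole subject's stream at once; this is an offline
  smoother, not a streaming recognizer.
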