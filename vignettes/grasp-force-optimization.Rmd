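---
title: "Optimal sEMG feature and measurement-position selection for grasp-force estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal sEMG feature and measurement-position selection for grasp-force estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgforce)
```

## The estimation problem

Controlling the grip of a myoelectric prosthetic hand requires a continuous
estimate of the force the user intends to exert, decoded from surface EMG of
the residual forearm. More electrodes and more features generally help, but
each added input enlarges the regression model that must run on an embedded
controller. `semgforce` treats this as a statistical selection problem: run
the estimator on *every* combination of electrode measurement-position sets
(MPSs) and time-domain feature sets (FSs), and find the cheapest combination
whose accuracy is statistically indistinguishable from the best.

With six positions and four features the search space is exactly
$63 \times 15 = 945$ combinations — small enough for exhaustive evaluation,
which avoids the path-dependence of greedy subset selection.

## Pipeline and models

### Segmentation

Recordings alternate ~1 s grasp actions with relaxation. Actions are
detected on the force channel: samples above 5% of the recording's maximum
force form candidate spans, sub-threshold gaps shorter than 100 ms are
bridged, and spans shorter than 200 ms are dropped. The detection criterion
is ours — subjects in a live experiment are prompted and the apparatus knows
the boundaries, but a force-threshold detector is faithful for data where
rest means full relaxation, and it avoids the ambiguities of EMG-onset
detection. Each action span of length $T_2$ keeps $\lfloor T_2/4 \rfloor$
samples of flanking relaxation on each side ($T_1 = T_3 = T_2/4$); flanks
are clipped at recording edges and truncated at the midpoint between
adjacent actions. `floor()` resolves lengths not divisible by four — at
1 kHz the off-by-one is immaterial, and determinism matters more.

### Features

Four time-domain features are computed on 200 ms windows with 50% overlap
(N = 200 samples, step 100 at 1 kHz): VAR $(1/N)\sum x_j^2$, IEMG
$\sum |x_j|$, ZC (sign changes whose amplitude step exceeds 30 µV) and WAMP
(adjacent differences exceeding 150 µV). The thresholds suppress baseline
instrumentation noise: at a ~10 µV noise floor adjacent-sample differences
rarely exceed 30 µV at rest, so rest windows score ZC ≈ WAMP ≈ 0 while
active windows (envelope > 150 µV) score highly. Windows are constrained to
lie inside one segment — allowing a window to straddle a segment boundary
would mix relaxation data into action windows. The force target of a window
is the mean force over the same samples; the mean is the standard choice
for a regression target over a window and smooths sensor noise.

### GRNN

The estimator is a general regression neural network: one-pass
Nadaraya–Watson regression with a Gaussian kernel,
$\hat y(x) = \sum_i y_i w_i / \sum_i w_i$ with
$w_i = \exp(-d_i^2 / 2\sigma^2)$. Two implementation choices are ours,
since the estimator's usual presentation leaves them open:

* **Standardization.** Features are centered and scaled on the training
  fold before distances are computed. Without this, IEMG (thousands of
  µV-samples) dominates the Euclidean metric and ZC/WAMP (counts < 200)
  become irrelevant regardless of their information content.
* **Spread selection.** No single $\sigma$ suits input dimensions from 1 to
  24, so by default $\sigma$ is chosen per training fold from a logarithmic
  grid $10^{-2} \ldots 10^{1}$ (7 points, standardized units) by an inner
  action-wise hold-out; `run_config(grnn_spread = <number>)` fixes it
  instead. Ties take the first grid entry.

Numerically, squared distances are shifted by their per-query minimum
before exponentiation, so a tiny $\sigma$ degrades gracefully to
nearest-neighbor prediction instead of 0/0. Predictions are convex
combinations of training targets and therefore always lie within the
training-target range.

### Splitting and metrics

Trials split *actions*, not windows: 4/5 of actions train, 1/5 test,
repeated 10 times. Overlapping windows from one action are strongly
dependent, so a window-wise split would leak test information into
training. Each (spec, repeat) trial derives its RNG stream deterministically
from the master seed and its indices, making results independent of
execution order.

Accuracy is scored by NRMS (root-mean-square error with an $N-1$ divisor,
normalized by the force range), NMAE (mean absolute error, same
normalization) and the Pearson correlation CC. The normalizing range
$f_{max} - f_{min}$ is taken over the whole experiment's captured force,
not per test fold, so all 945 data sets share one scale.

### Selection

For a fixed MPS, the 15 FSs are compared by one-way fixed-effects ANOVA on
the per-repeat metric values ($\alpha = 0.05$). When significant, levels
are grouped into Tukey HSD *homogeneous subsets*: level means are ordered
best-first and maximal runs whose range stays below
$q_{1-\alpha,k,df}\sqrt{MS_w/n_h}$ form subsets (harmonic-mean $n_h$ under
unbalance, with a warning). This is the convention of mainstream
statistical packages' post-hoc tables, which the field's reports follow;
base R's `TukeyHSD` provides pairwise intervals only, so the grouping is
implemented here on top of `qtukey`/`ptukey`. Within the best subset the
*minimal-cardinality rule* picks the level with the fewest
positions/features; ties are broken by the better mean, then by name order
(logged). When the ANOVA is not significant the grouping and pick are still
produced but flagged — the selection question is then moot, and the flag
says so rather than erroring a 63-row report.

A balanced two-way ANOVA with interaction (`two_way_anova`) tests whether
position and feature choices interact, which they do whenever channel
informativeness is uneven.

## The simulator

`generate_recording()` emulates the experimental conditions the pipeline
assumes: 60 grasp actions of 1 s at strength levels 25/50/75/100% of a
250 N maximum, 15 actions per level in random order, separated by
relaxation of 0.5–1.5 s (uniform). Burst shape is a ramp–plateau–ramp with
10% raised-cosine edges — smooth enough that onset detection is a real
task. A lognormal amplitude jitter ($\sigma = 0.08$) reproduces
within-level spread: subjects only *roughly* hit a prompted level. Each EMG
channel is Gaussian white noise band-passed to 10–500 Hz (4th-order
zero-phase Butterworth; an upper edge at Nyquist becomes a high-pass, since
it constrains nothing) and amplitude-modulated so its instantaneous
standard deviation is
$\text{noise\_floor} + g_c\,(f/f_{max})^{e}\,\text{envelope\_scale}$ —
10 µV floor, 150 µV envelope scale and exponent 1 by default. Channel gains
$g_c$ plant the ground truth: a zero-gain channel is pure noise, and
selection results can be scored against the gains.

What the simulator does **not** model: motor-unit structure, inter-channel
crosstalk or correlation given force, electrode shift, fatigue, or
force-dependent spectral changes. Passing tests on simulated data therefore
demonstrate that the pipeline recovers planted statistical structure — not
that any particular electrode site is optimal for real muscles.

## Problem sizes used in the tests

The test suite and the acceptance script exercise the full 945-combination
enumeration, but run the heavier stochastic studies at reduced size: the
planted-structure study uses 20 actions (5 per level), 5 repeats and the
feature grid {I, W, IW} over all 63 MPSs, across 10 simulation seeds; the
full-factorial trial count is demonstrated on an 8-action recording with a
fixed spread. These sizes keep a complete run in minutes while leaving
every code path identical to a full-scale analysis.

## Known limitations

* The force-threshold segmenter assumes rest means near-zero force; it is
  not suitable for isometric baselines or co-contraction without rest.
* Tukey grouping semantics assume (near-)balanced replicates; heavily
  unbalanced results fall back to the harmonic-mean approximation.
* Degenerate trials (e.g. a constant-feature channel predicting a constant)
  have undefined correlation; they are recorded as `NA` and excluded from
  CC rankings, with levels dropped from a comparison only when fewer than
  two defined repeats remain.
* Subjects are pooled; there is no per-subject stratification of splits and
  no random-effects treatment of subject identity.
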