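---
title: "Weighted composite multiscale fuzzy entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted composite multiscale fuzzy entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcmfe)
```

## The problem

Motor-imagery EEG (MI-EEG) is the electrical brain activity recorded while a
subject imagines moving a limb. Imagining left- or right-hand movement
modulates the mu rhythm (8–12 Hz) over the sensorimotor cortex: the
band power drops over the contralateral hemisphere (event-related
desynchronisation, ERD) and typically rises over the ipsilateral one (ERS).
On the standard electrode pair C3 (left hemisphere) / C4 (right hemisphere)
this produces opposite, class-dependent changes in signal regularity, which
entropy statistics can quantify without any stationarity assumption.

This package turns that observation into a complete two-class decoding
pipeline: entropy-based feature extraction, a small neural-network
classifier under repeated cross-validation, and a statistical procedure for
comparing two feature-extraction methods by their cross-validated
accuracies.

## Fuzzy entropy

For a sequence $y(1),\dots,y(N')$ and embedding dimension $m$, form the
centred templates
$Y_i = \{y(i),\dots,y(i+m-1)\} - \bar y(i)$, where $\bar y(i)$ is the
window mean. Template similarity is measured by the Chebyshev distance
$d_{ij}$ and mapped through a fuzzy membership function
$\exp(-d_{ij}^{\,n}/r_{\mathrm{abs}})$, with boundary gradient $n$ and
tolerance $r_{\mathrm{abs}}$. With
$\Phi^m$ the mean membership over all ordered pairs $i \ne j$, fuzzy
entropy is

$$\mathrm{FE}(m, n, r, N') = -\ln\frac{\Phi^{m+1}}{\Phi^m}.$$

Conventions fixed in this implementation:

* **Template count.** The embedding yields $N'-m+1$ templates but the pair
  sums run over $i,j = 1,\dots,N'-m$; we use exactly $N'-m$ templates for
  both dimension $m$ and $m+1$, the usual SampEn/FE convention that keeps
  the two pair populations comparable. The last template of dimension $m$
  is therefore unused.
* **Pair enumeration.** The ordered-pair mean is computed from the upper
  triangle and doubled; the kernel is symmetric so this is exact.
* **Tolerance.** $r_{\mathrm{abs}} = r \cdot \mathrm{SD}(X)$, where the SD
  is the *population* standard deviation (divide by $N$) of the cropped
  original channel signal, computed once per channel per trial and shared
  by all scales and all coarse-grained sequences of that channel. This is
  the dominant multiscale-entropy convention; recomputing the SD per
  coarse-grained sequence is available via `r_scope = "sequence"`.
* **Degenerate inputs.** A constant sequence is perfectly regular and
  returns 0 exactly, short-circuiting the (then zero) relative tolerance;
  an explicitly supplied `r_abs <= 0` is an error. If $\Phi^{m+1}$
  underflows to zero the function warns and returns `+Inf` rather than
  failing.
* **Scale behaviour.** With the membership $\exp(-d^n/r_{\mathrm{abs}})$
  and a relative tolerance, the statistic is amplitude-invariant for
  $n = 1$ exactly; for general $n$ invariance requires rescaling
  $r_{\mathrm{abs}}$ by $a^n$. This is a property of the membership
  function itself, inherited from the original fuzzy-entropy definition.

Defaults $m = 2$, $n = 2$, $r = 0.15$ follow the parameter study behind the
method: $m = 2$ maximises the between-class gap of the channel-difference
statistic, larger $n$ discards information while $n = 1$ inflates its
spread, and $r$ trades template-matching difficulty against noise
sensitivity.

## Weighted coarse-graining and WCMFE

Multiscale analysis reduces the signal at scale $\tau$ by aggregating
windows of $\tau$ consecutive samples. The *composite* variant (CMFE)
computes the fuzzy entropy of all $\tau$ window offsets and averages them,
which stabilises the estimate on short records. The *weighted* variant
(WCMFE) replaces the plain within-window mean by a symmetric weighted mean

$$A_{\tau,h} = \Big[\tfrac{h}{10},\ \underbrace{\tfrac{5-h}{5(\tau-2)},
\dots}_{\tau-2},\ \tfrac{h}{10}\Big], \qquad h \in \{1,2,3,4\},\ \tau > 2,$$

whose coefficients are positive, sum to 1, and are symmetric — i.e. each
scale's coarse-grainer is a linear-phase FIR low-pass whose cut-off is
controlled by $h$. `filter_frequency_response()` exposes exactly this view
(DC gain 1, constant group delay $(\tau-1)/2$).

Further conventions:

* **Scales 1 and 2.** The rule requires $\tau > 2$; `make_weights()` falls
  back to $[1]$ and $[0.5, 0.5]$ there, so every scale of a profile is
  defined. $\tau = 1$ is the identity: WCMFE reduces to plain fuzzy
  entropy.
* **Normalisation.** The printed form of the weighted coarse-grained value
  carries both a $1/\tau$ prefactor and weights summing to one; stacking
  the two would shrink every sequence by $\tau$ relative to CMFE's plain
  mean and break the uniform-weights equivalence. The coarse-grained value
  is therefore the weighted mean alone; the stacked form is available via
  `literal_scaling = TRUE` for comparison.
* **Tail handling.** Offset $k$ keeps only full windows,
  $\lfloor (H-k+1)/\tau \rfloor$ of them, so offsets can differ in length
  by one sample; each offset's entropy uses its own length.
* **Equivalence.** CMFE is WCMFE with uniform weights through the same code
  path, so the baseline is recovered bit-for-bit — a tested invariant.

## Interval selection and feature fusion

A trial is cropped to the sample interval where the two classes differ
most. The reference layout (9 s at 128 Hz, 1152 samples) ships with the
default interval $[450, 900]$ (1-based inclusive, $H = 451$), which covers
the imagery period. For data-driven selection, `mean_entropy_curve()`
slides a 1-s window (step 1 sample) along each trial, computes the
scale-2 CMFE per window, and averages within class;
`select_interval()` then returns the window of requested length maximising
the mean absolute difference between the two class curves (ties to the
earliest start). The published procedure picks the interval by visual
inspection of those curves; the maximisation is this package's explicit,
deterministic stand-in, and the shipped default reproduces the reference
choice for the standard layout.

Features fuse scale-major: for channels $1..n_C$ and scales
$1..\tau_{\max}$,
$F = [F_1, \dots, F_{\tau_{\max}}]$ with
$F_\tau = [\mathrm{WCMFE}_\tau^{1}, \dots, \mathrm{WCMFE}_\tau^{n_C}]$ —
length $n_C \times \tau_{\max}$, i.e. 14 for C3/C4 at $\tau_{\max} = 7$.
Defaults $\tau_{\max} = 7$ (coarse-grained differences between scales 6 and
7 are already small) and $h = 3$ (best recognition in the weight-mode
comparison).

`dwc_stats()` implements the parameter-study statistic: the per-trial
difference $\mathrm{WCMFE}_{C3} - \mathrm{WCMFE}_{C4}$, summarised per
class by its mean (MWC) and population SD (SDWC). Opposite signs of MWC
across classes, with small SDWC, indicate separability.

## The synthetic generator

`simulate_mi_eeg()` makes the full pipeline testable without external
recordings. Each channel is Gaussian noise band-limited to 0.5–30 Hz by a
zero-phase 4th-order Butterworth (mimicking the pre-filtered band of
typical recordings) plus a narrowband mu component (band-pass filtered
noise, 8–12 Hz, rescaled to `mu_amp`). During the imagery window
(3.5–7 s, i.e. samples 449–896 at the defaults, matching the shipped crop
interval) the mu component of the class-contralateral channel is multiplied
by $1-$`erd_depth` and the ipsilateral one by $1+$`erd_depth`. The gain
touches only the mu component, so the contrast is band-specific as in real
ERD, and with `erd_depth = 0` the classes are distributionally identical —
the null used to check that the pipeline reports chance accuracy.

Defaults: `fs = 128`, `duration_s = 9`, two channels, `mu_band = c(8, 12)`,
`erd_depth = 0.5`, `noise_sd = 1`, `mu_amp = 1`. Sampling rate, duration,
channel pair, band and window mirror the reference recording layout; the
mu-to-broadband ratio of one is a deliberate, fixed choice giving a
prominent mu rhythm as seen over sensorimotor sites. A step gain (rather
than a smooth ramp) keeps the inside/outside power ratio exactly
$(1\pm\texttt{erd\_depth})^2$, which the tests verify spectrally.

What the generator does *not* emulate: 1/f background structure, eye-blink
and muscle artifacts, inter-trial nonstationarity, volume conduction
between channels, and subject idiosyncrasy. Passing tests therefore show
the pipeline recovers a band-specific regularity contrast of realistic
size — not that any particular accuracy transfers to real recordings,
where class contrasts are weaker and noisier than this construction.

## Classifier and cross-validation

The classifier is a single-hidden-layer feed-forward network — input
dimension $n_C \tau_{\max}$ (14), six sigmoid hidden units, two identity
outputs — trained on one-hot targets with mean-squared-error loss by
error back-propagation. The reference description fixes the architecture
and the loss but not the training regime, so this package fixes one
deterministically: full-batch gradient descent, learning rate 0.05
(default), at most 2000 epochs, early stop when the loss improves by less
than $10^{-6}$ over 50 epochs, uniform $[-0.5, 0.5]$ weight initialisation
from a seed, and internal feature standardisation by training-set
statistics. All of these are exposed as arguments.

`repeated_cv()` runs the 10×10-fold protocol: per repetition a fresh
stratified fold assignment (per-class proportions within one trial of the
global ones), a fresh network per training split, and held-out accuracy in
percent — 100 values whose population is the unit of statistical
comparison. Fold seeds and model seeds derive from the master seed;
held-out indices are retained in the result for fold-disjointness
auditing. Ties in the output layer resolve to the first class level.

## Statistical comparison

`compare_cv()` chains the published validation sequence on two accuracy
populations:

1. **Lilliefors normality** per group (`lilliefors_test()`, delegating to
   the standard table-interpolated implementation in *nortest*);
2. **variance homogeneity** (`equal_variance_test()`): Bartlett's test —
   the default of the classical grouped-data equal-variance procedure —
   with Levene's test selectable for robustness;
3. the **pooled two-sample t-test** (`pooled_t_test()`), implemented
   directly from the pooled-variance formula with $n_1 + n_2 - 2$ degrees
   of freedom.

Two decisions were genuinely open. The decision rule is printed one-sided
in the source procedure, yet its reported $p$ for $t = 3.01$ is consistent
with a two-sided test; the default here is two-sided with `alternative`
exposed. And the degrees of freedom are printed as $n-1$ in one place
while the pooled variance implies $n_1+n_2-2$; the latter is implemented.
Sample sizes are always taken from the data. Degenerate inputs
(zero pooled variance) return $t = 0, p = 1$ for equal means and
$t = \pm\infty, p \to 0$ otherwise.

A companion helper, `pooled_summary()`, reports per-group and pooled
counts/means as such comparisons are tabulated.

## Problem sizes and verification

The test-suite sizes are the package's own choices for a thorough but
quick verification: brute-force loop oracles for the entropy stack on 50
random sequences of length 20–60 (tolerance $10^{-10}$); CMFE/WCMFE
equivalence on 20 signals across scales 1–7 ($10^{-12}$); $10^4$
null replicates for the t-test's type-I calibration ($0.05 \pm 0.01$ at
$n = 15$ per group); and an end-to-end run of 70 synthetic trials per
class through feature extraction and 10×10-fold CV, with its
`erd_depth = 0` null required to stay inside the 95% binomial band around
50%. The command-line front end (`inst/cli/wcmfe.R`) is exercised on a
small simulated set.

## Known limitations

* Only symmetric (linear-phase) weight rules are provided; the weight
  values themselves are fixed by the $h$-rule rather than optimised.
* Two classes and two channels end-to-end; `extract_features()` accepts
  any channel count, but the generator and classifier target the
  C3/C4 left/right setting.
* The entropy kernel is $O(N'^2)$ per sequence (C++ inner loop); very long
  windows at scale 1 dominate runtime.
* No artifact rejection, re-referencing or band-pass preprocessing: inputs
  are assumed pre-filtered, as in the reference recordings.
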