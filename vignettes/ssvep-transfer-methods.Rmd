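---
title: "Within-subject SSVEP transfer decoding: models, alignment and evaluation"
author: "ssvepAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-subject SSVEP transfer decoding: models, alignment and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepAlign)
```

## The problem

A steady-state visual evoked potential (SSVEP) speller presents a grid of
targets, each flickering at its own frequency/phase pair (joint
frequency-phase modulation, JFPM).  Gazing at a target entrains
occipito-parietal EEG at the stimulus fundamental and its harmonics, so a
decoder can identify the attended target from a short multichannel
window.  Supervised decoders (eCCA, TRCA) need a calibration session;
for a long-term user that calibration is repeated every day and every
time the headset changes (wet gel electrodes vs dry electrodes).  The
package implements the within-subject *transfer* setting: reuse data
recorded on a previous day, possibly with the other electrode type, so
that today's session needs zero calibration, and bridge the resulting
domain shift by explicit alignment (the ALPHA decoder).

## Signal model of the synthetic generator

No public recordings accompany this problem setting, so the package
ships a seeded generator whose draws stand in for a subject.  A trial of
class $k$ with stimulus frequency $f_k$ and phase $\phi_k$ is

$$x(t) = A \sum_{h=1}^{H} a_h \sin\!\big(2\pi h f_k (t - \tau) + h\phi_k\big)\, \mathbf{p} + \mathbf{n}(t),$$

with visual latency $\tau$ (default 0.14 s, the standard population
value), harmonic amplitudes $a_h = h^{-1.25}$ (mirroring the filter-bank
weight decay), a fixed unit-norm spatial mixing pattern $\mathbf{p}$,
and amplitude scale $A$ in µV.  The noise $\mathbf{n}$ is AR(1) in time
(coefficient 0.9, the simplest colored-noise surrogate for the 1/f EEG
background) and spatially mixed by the Cholesky factor of an SPD
covariance (unit channel variance, 0.3 exponential inter-channel
correlation).  The default design is the 40-target grid: 8–15.8 Hz in
0.2 Hz steps, phases cycling 0, 0.5π, π, 1.5π.

A recording *domain* is a (day, electrode type) pair.  Relative to the
reference domain (day 1, wet) the generator plants:

* an orthogonal channel rotation of the mixing pattern, built by QR
  orthogonalisation of $I + \theta \cdot \mathrm{antisym}$, with
  $\theta = 0.2$ per new day and an additional independent
  $\theta = 0.5$ rotation for every dry session (electrode
  repositioning is physically larger than day-to-day drift);
* for dry sessions, a noise-covariance gain of 3 and an amplitude gain
  of 0.8 (dry electrodes are noisier and attenuate the signal; no
  quantitative values are published, these are fixed package choices).

The amplitude scale is the one free SNR dial.  It is fixed once at
$A = 0.9$ µV against the unit-variance noise, chosen so the simulated
transfer experiment operates in the regime the real studies report:
aligned wet-to-dry transfer in the mid-80s percent at 1.2 s windows,
above the fully calibrated dry decoder minus a small margin, with the
training-free CCA clearly weakest.  With the dry noise gain fixed at 3,
a single dial cannot simultaneously reproduce the published *within-day
wet* CCA accuracy; the within-day wet regime here is easier than in real
data (see Limitations).

What the generator does **not** emulate: eye-blink/EMG artifacts,
within-block nonstationarity, per-harmonic topography differences
(the planted signal is spatially rank-1), latency or phase drift across
domains, and photic-driving nonlinearities.  Passing tests therefore
demonstrate correctness of the estimators and the expected qualitative
ordering of methods under spatial domain shifts — not performance claims
about real EEG.

## Preprocessing and filter bank

Epochs are band-passed 6–90 Hz (zero-phase 4th-order Butterworth,
forward–backward with odd-reflection padding) and mains-notched at 50 Hz
(zero-phase constant-Q biquad, Q = 35); recordings above 250 Hz are
decimated by an integer factor after an anti-alias low-pass.  The IIR
type and order are not prescribed by the protocol; zero-phase Butterworth
is standard SSVEP practice and avoids latency distortion.  Decoding
windows skip the 0.14 s visual latency after stimulus onset.

The filter bank decomposes a trial into up to five sub-bands with edges
$[(n \times 8) - 2,\ 90]$ Hz.  Per-sub-band class scores $\rho^{(n)}_k$
are fused as

$$\tilde\rho_k = \sum_n v(n)\, \big(\rho^{(n)}_k\big)^2,\qquad v(n) = n^{-1.25} + 0.25.$$

Template-based scores can be negative (sign carries information through
the pooled features), so by default the square preserves the sign
(`signedSubbands = TRUE`); squaring as printed discards it, and the
switch documents that ambiguity.

## Decoders

**CCA / FBCCA.** The training-free baseline: the canonical correlation
between the trial $X$ and the sine–cosine reference
$Y_k = [\sin 2\pi f_k t;\ \cos 2\pi f_k t;\ \dots]$ ($t$ starting at
$1/f_s$; five harmonics by default — unspecified by the protocol, chosen
to match the five sub-bands below 90 Hz), maximised over filter pairs
and argmaxed over classes.  Rank-deficient within-set covariances are
ridge-regularised ($\varepsilon = 10^{-9}\,\mathrm{tr}/d$) with a
warning.  Ties break to the lowest class index everywhere.

**eCCA.** With class templates $\bar X_k$ (arithmetic means of training
trials), three correlation features per class: the trial and template
projected through the template–reference CCA filter; the same pair
through the trial–reference CCA filter; and the plain trial–reference
canonical correlation.  Features pool by the sign-preserving squared sum
$\rho_k = \sum_i \mathrm{sign}(r_{k,i})\, r_{k,i}^2$.  **ttCCA** is the
same computation with templates from another domain, no alignment.

**TRCA.** Per class, the spatial filter maximising inter-trial
reproducibility: $\max_w\, w'Sw / w'Qw$ with $S$ the sum of cross-trial
covariances ($i \neq j$) and $Q$ the aggregated covariance over all
pairs, as printed (some implementations use the concatenated-data
covariance instead; since $Q = S + \sum_i \mathrm{Cov}(X_i, X_i)$, the
argmax filter is the same).  All covariances use per-trial,
per-channel mean-centred data.  The class filters form the ensemble
matrix $W$; a test trial is classified by Pearson-correlating the
flattened projections $X_t'W$ and $\bar X_k'W$ (the alternative —
correlating per column of $W$ and fusing — also appears in the
literature; flattening was chosen and is fixed here).  Eigenvector sign
is fixed by making the largest-magnitude coefficient positive.

## The ALPHA decoder

ALPHA transfers a source-domain model (templates and filters) to an
unlabelled target domain in three steps: subspace decomposition,
subspace alignment, subspace pooling.  The original description defers
the concrete decomposition to its antecedent method; the package fixes
the following scheme, per sub-band:

1. **Decomposition.**  Per class, three source filters: the
   template–reference CCA filter, the trial–reference CCA filter
   (accumulated over the class trials), and the TRCA filter — mirroring
   the eCCA feature triple.  In addition one *shared* rank-1 task
   subspace filter per domain, estimated by stacking the per-class
   whitened trial–reference cross-covariances and taking the leading
   left singular direction.
2. **Align Covariance (AC / CORAL).**  Per class, the covariance map
   $Q_c = C_s^{-1/2} C_t^{1/2}$ (symmetric PSD roots; ridge
   $\varepsilon = 10^{-6}\,\mathrm{tr}/d$ only when needed), where
   $C_s$ is the class's concatenated-source covariance and $C_t$ the
   pooled unlabelled-target covariance (target labels do not exist, so a
   per-class $C_t$ is not estimable).  $Q_c$ maps the three class
   filters; the mapped filters score the target trial against the
   source template.
3. **Align Spatial Pattern (ASP).**  Orthogonal Procrustes
   $P = UV'$ from the SVD of $A_1'A_2$ aligns the spatial patterns
   ($A = W^{-T}$, pseudo-inverse-transpose when non-square) of the
   shared source and target subspaces, and the aligned filter is
   $W_2 P'$.

The target-side subspace is the crux: it must be estimated without
labels.  Estimating per-class target filters from CCA of *pooled*
unlabelled trials against each reference — the most direct label-free
route — is unidentifiable at realistic SNR: only 1/40 of the pooled
trials carry the class frequency, and neighbouring targets 0.2 Hz away
are separated by only ~0.24 cycles within a 1.2 s window, so they leak
into every reference.  In simulation the patterns estimated this way
correlated below 0.2 with the true rotated pattern and the resulting
features scored at chance, while the same stacked estimator with known
labels recovers the pattern almost perfectly.  The package therefore
uses self-training: the AC + reference-CCA stage (steps 1–2, which need
no target labels) first classifies the unlabelled target trials; those
pseudo-labels then drive the stacked subspace estimator on the target
side.  Moderately accurate pseudo-labels suffice because the estimator
accumulates signal coherently across all trials while errors average
out.  For the rank-1 shared subspace the Procrustes map reduces to a
sign; because the inner product of patterns across a strongly rotated
domain pair can be uninformative, the decoder fixes the sign by
consensus — the raw subspace correlation at the pseudo-labelled class
must be positive on average.  Classification pools, per class and
sub-band: the three AC-aligned template correlations, the
aligned-subspace template correlation, and the training-free reference
canonical correlation, via the sign-preserving squared sum, then fuses
sub-bands with $v(n)$.

Alignment is computed per sub-band (filters are band-specific), and the
AC and ASP families are pooled as parallel features rather than composed
— composing the two maps would apply a source-to-target correction to a
filter that is already target-domain.

## Evaluation protocols

* **Transfer directions.**  Within-day tasks (wet→wet a, dry→dry b,
  wet→dry c) and all ordered cross-day pairs (wet→wet d, dry→dry e,
  wet→dry f); three days give six cross-day directions.
* **Cross-validation.**  Supervised decoders use leave-one-block-out
  (six-fold with six blocks); transfer decoders train on the full
  source session and classify every target trial.
* **ITR.**  Wolpaw throughput
  $\mathrm{ITR} = \big(\log_2 N_f + P\log_2 P + (1-P)\log_2\frac{1-P}{N_f-1}\big)\cdot 60/T$
  bits/min with $T$ = window length + 1 s gaze shift.  $P = 1$ uses the
  analytic limit; $P \le 1/N_f$ is clamped to 0 (the formula is negative
  or undefined below chance; the protocol is silent there).
* **Training-block curves.**  For each block count $n$, six distinct
  random subsets of source blocks are drawn without replacement; when
  source and target are the same session the held-out blocks form the
  test set, otherwise the full target session does.
* **Similarity analysis.**  Per block, the channel topography of
  spectral amplitudes at each trial's fundamental (nearest DFT bin —
  "amplitude" is otherwise undefined), averaged over the block's trials
  and max-normalised; or per-trial covariance matrices, vectorised as
  the upper triangle including the diagonal (a fixed package choice).
  Pairwise Pearson correlations are bucketed WDWE / WDCE / CDWE / CDCE
  (within/cross day × within/cross electrode).
* **Statistics.**  The planned paired two-sided t-test
  ($t = \bar d/(s_d/\sqrt n)$, $n-1$ df).  Repeated-measures ANOVA is
  out of scope.  Summary tables print per-subject rows plus Mean and
  *both* dispersion statistics with explicit labels, because published
  summary rows labelled "SD" are numerically the standard error
  SD/$\sqrt n$ — emitting both avoids the ambiguity.

## Numerical choices

* Zero-phase filtering pads by odd reflection (12× the filter order,
  capped at the epoch length); epochs shorter than three filter orders
  raise a too-short error.
* All Gram/covariance Cholesky factorisations fall back to a ridge
  ($10^{-9}\,\mathrm{tr}/d$, warning) on failure; CORAL uses
  $10^{-6}\,\mathrm{tr}/d$ before the inverse square root, applied only
  when the spectrum requires it so that exact SPD inputs are aligned to
  machine precision.
* Eigenvector/filter signs: largest-magnitude coefficient positive.
* Ties in every argmax resolve to the lowest class index.
* Windowing before filtering vs filtering before windowing differ by
  filter edge effects only; the package filters the windowed trials
  (epochs are already cut) and the two orders agree on interior samples.
* The epoch container stores float32 (EEG dynamic range is far below
  single precision); a first round trip is exact to float32 resolution
  and subsequent round trips are bit-identical.

## Problem sizes in the test suite

The unit tests run reduced geometries (4–10 classes, 4–8 channels,
widened frequency steps) so the suite stays fast; the end-to-end
transfer property runs the full 40-class, 8-channel, 6-block
configuration (`inst/extdata/acceptance_transfer.yaml`) at a 1.2 s
window over 20 simulation seeds, and the training-block property runs
the same configuration's dry session over 20 seeds.  These sizes are the
package's fixed study conditions for those properties.

## Known limitations

* The generator's signal is spatially rank-1 and temporally identical
  across domains; real cross-day shifts also move latency, harmonic
  phases and per-harmonic topographies, which is precisely where raw
  template transfer (ttCCA) loses most in practice.  The planted purely
  spatial shift is therefore a conservative setting for alignment.
* CORAL can only express shifts visible in second-order statistics; in
  the generator the noise covariance does not rotate with the signal
  pattern, so at low SNR the covariance map carries little of the
  rotation — one motivation for the pseudo-labelled ASP stage.
* The single SNR dial cannot reproduce every published operating point
  simultaneously (see the signal-model section).
* Pseudo-label self-training can fail at SNRs where the stage-1 decoder
  is itself near chance; the aligned-subspace feature then adds noise
  rather than signal (it is one pooled feature among five, bounding the
  damage).
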