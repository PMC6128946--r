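---
title: "Methods: NIRS calibration of cartilage and subchondral bone properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIRS calibration of cartilage and subchondral bone properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the synthetic-data generator, the
numerical choices and the known limitations of `arthronirs`. It is the
package's own account of its methods; every number quoted here is
either a package default or an input condition, not an empirical claim
— empirical behaviour is established by the test suite and
`scripts/acceptance.R`.

## The estimation problem

An arthroscopic NIRS probe records diffuse reflectance spectra of the
cartilage surface; the goal is to calibrate a regression from those
spectra to nine reference tissue properties: cartilage equilibrium
modulus $E_{eq}$ (kPa) and dynamic modulus $E_{dyn}$ (MPa), subchondral
plate bone volume fraction (%), mineral density (g/cm³) and thickness
(µm), and trabecular bone volume fraction, mineral density, thickness
and structure model index. The study design is hierarchical: ponies
(repair group with surgically created and treated chondral lesions, and
healthy controls) → joints (2 per pony) → measurement locations (12 per
joint, at four distance classes from the repair site). Spectra come
from two spectrometer arms — 0.35–1.1 µm at 0.6 nm and 1.0–2.5 µm at
6.4 nm — both arthroscopically (15 repeats per location) and in vitro
(3 repeats).

## The regression model

The calibration model is a single-hidden-layer network
$\hat y = w_{out}^\top \tanh(Wx + b_h) + b_{out}$ with at most 8 hidden
neurons, trained by full-batch Levenberg–Marquardt: each epoch solves
$(J^\top J + \mu I)\,\Delta w = J^\top e$ where $J$ is the residual
Jacobian, accepting the step only if the training SSE decreases
(otherwise $\mu \times 10$, up to a cap of $10^{10}$; on acceptance
$\mu \times 0.1$). LM is a damped Gauss–Newton method, so "iteration"
is read as a full-batch epoch. Defaults $\mu_0 = 10^{-3}$, factor 10
up / 0.1 down are the classic Marquardt settings.

Design choices:

* **Scaling.** Inputs and target are min–max scaled to $[-1, 1]$ using
  the calibration set only, which controls tanh saturation and
  prevents leakage of validation/test statistics into training.
* **Early stopping.** Training halts once the validation SSE has
  failed to reach a new minimum for 6 consecutive epochs; the weights
  from the best validation epoch are kept, not the last ones.
* **Initialisation and restarts.** Nguyen–Widrow-style scaled uniform
  initialisation, seeded. The number of restarts is a configuration
  knob (default 3 for standalone fits, 2 for final refits inside
  selection, 1 during candidate search); the restart with the lowest
  validation SSE wins. Whether the original analysis used restarts is
  unknowable from its description, so this is declared, not inferred.
* **Hidden width.** Chosen by grid search (1–4 by default inside the
  pipeline, extensible to the cap of 8) on validation SSE; no
  selection rule beyond the cap is documented for the emulated study.
* **Degenerate targets.** A zero-variance target yields a constant
  predictor with a warning rather than an error.

## Wavelength selection

Greedy forward selection over the processed channel grid: at each
round every remaining candidate channel is scored by training a
reduced-budget network (default: hidden width 2, ≤ 15–20 epochs, one
restart) on the candidate subset and evaluating the variant criterion;
the best candidate is appended. Additions continue until the budget is
reached or `patience` consecutive additions fail to improve the best
criterion; the best-so-far prefix is retrained with the full budget.

The three variants mirror the emulated study:
Model 1 (0.75–1.90 µm) scores candidates by the arithmetic mean of the
test-set NRMSE and the arthroscopic NRMSE — the mean is the package's
choice of combination rule (scale-free, equal weight), as only the two
sets, not the rule, are documented; Models 2 and 3 (0.75–1.90 and
0.40–1.90 µm) use the test-set NRMSE alone. Using the test set inside
selection reproduces the emulated analysis faithfully but is
optimistic: the "test" metrics of selected models are not fully
independent. Arthroscopic spectra are never used for weight fitting —
only inside Model 1's criterion and in final evaluation.

Candidate stride defaults to 4 (adjacent channels are redundant after
smoothing); the orchestrated pipeline uses stride 8 with a budget of
10 variables and patience 3, which keeps a full nine-parameter,
three-variant run on one CPU in the minutes range. These are runtime
choices, not study conditions; stride 1 and budget 220 are supported.

## Preprocessing

* **Savitzky–Golay smoothing**, order 3; windows 25 (arm a) and 13
  (arm b) points for cartilage-parameter models, 45 and 13 for bone.
  Edge handling fits the polynomial on the shrunken window of
  available points rather than padding — no data are fabricated at the
  arm boundaries. (`signal::sgolayfilt` differs at edges, which is why
  the operator is implemented here; interior points agree with the
  per-window polynomial-fit definition.)
* **Region handling.** Channels ≥ 1.9 µm are always discarded (water
  saturation); the arms are merged at 1.0 µm with arm a supplying
  channels below and arm b at or above, so each wavelength has exactly
  one source; the overlap 1.0–1.1 µm is resolved in favour of arm b.
* **Contact-quality area statistic.** The straight line through the
  smoothed spectrum's values at the channels nearest 0.42 and 0.75 µm
  is subtracted and the absolute deviation integrated (trapezoid rule)
  over that window. Absolute rather than signed deviation is a
  documented choice — the original description is ambiguous — as is
  computing it on smoothed intensities. The best 8 of 15 arthroscopic
  repeats (smallest areas, ties to earlier repeats) are retained;
  in-vitro repeats are simply averaged, since no exclusion is
  described for them.
* **Contamination flagging.** A location is flagged when the median
  retained area exceeds median + 3·MAD of the pooled arthroscopic
  per-spectrum areas. The reference distribution is arthroscopic, not
  in-vitro, because every arthroscopic spectrum carries a baseline
  arthroscope-light contribution: an in-vitro-anchored threshold would
  flag all locations, whereas a robust arthroscopic anchor is immune
  to the handful of heavily contaminated locations it is meant to
  catch.
* **Coefficient of variation** between the mean arthroscopic and mean
  in-vitro spectrum of a location (0.75–1.9 µm) uses the population SD
  of the two paired values per channel, $|x - y|/2$, divided by their
  mean, averaged over channels, in percent.

## The synthetic-study generator

The generator exists so that every stage has testable ground truth. A
latent state per location — water fraction (0.6–0.85), collagen,
proteoglycan and mineral densities (arbitrary units, centred at 1),
scattering slope — drives both the reference properties and the
spectra; recovery of properties from spectra is therefore possible in
principle and the pipeline's job is to achieve it.

* **Properties.** Monotone affine maps with a softplus positivity
  clamp, centred for controls at the healthy-population means
  ($E_{eq}$ 579 kPa, $E_{dyn}$ 7.25 MPa, plate BV 98.4%, plate BMD
  1.00 g/cm³, plate thickness 174 µm, trabecular BV 30.5%, BMD
  0.247 g/cm³, thickness 169 µm, SMI 0.367). Stiffness increases with
  proteoglycan and collagen and decreases with water; bone
  density/structure follow mineral (SMI decreasing); small Gaussian
  measurement noise on top.
* **Repair effect.** Latent shifts at distance class 1 of +0.05 water,
  −0.25 proteoglycan, −0.15 collagen, −0.12 mineral, +0.05 scattering,
  scaled by the effect size (default 1) and decaying linearly over
  classes (1, 0.75, 0.5, 0.25) — the graded-with-distance profile is a
  package choice; only gradedness, not its shape, is documented for
  the emulated study. Effect 0 makes the groups exchangeable by
  construction.
* **Spectra.** Scattering baseline $1.1\,e^{-s(\lambda - 0.35)}$ with
  slope tied to mineral, minus Gaussian absorption bands: water OH at
  0.97/1.45/1.93 µm (widths 0.030/0.045/0.060 µm), CH at
  0.90/1.18/1.73 µm, NH at 1.00/1.50 µm; band positions follow the
  standard overtone assignments, widths were fixed once for visual
  plausibility. Channels ≥ 1.9 µm are clipped at 95% of the detector
  full scale with 5× noise — only the region's unusability matters,
  since preprocessing discards it. Arthroscope light adds a smooth
  bump with support exactly 0.42–0.75 µm (level 0.03 ordinarily; 0.6
  at 4 heavily contaminated locations per study). Per-repeat
  arthroscopic contact quality is Beta-distributed with mode 0.85
  (concentration 8); contact below 1 attenuates band depths and
  inflates the additive noise (SD 0.004 in vitro, 0.008
  arthroscopic). The four arthroscopically unreachable locations are
  drawn at random within repair ponies and removed from both
  modalities; the per-repeat contact model motivates the
  best-8-of-15 rule but is a stand-in, not an inference — no
  per-repeat variance is documented for the emulated study.

What the generator does *not* emulate: radiative transfer or photon
migration, instrument response functions, wavelength-dependent
penetration depth, repair-tissue (hydrogel) spectra, and any
correlation structure within ponies or joints — latent states are
independent across locations. Consequently, passing tests demonstrate
that the pipeline recovers structure *under this forward model*, not
that it would achieve the same accuracy on real arthroscopic data; and
group-comparison calibration holds exactly because locations are
exchangeable under the null, which real within-pony correlation would
violate.

## Splitting and evaluation

Splits are at pony level (fractions 0.6/0.3/0.1): the test pony is
drawn from the repair group (preferring ponies with all locations
reachable, so the test set has its full complement of locations), and
control ponies are distributed over calibration and validation only.
NRMSE is normalised by the measured range pooled over all sets — the
"reference parameter range" is not set-scoped anywhere in the emulated
description, and pooling keeps the denominator identical across sets.
RPIQ uses type-7 (linear interpolation) quantiles; reliability is
RPIQ ≥ 2. Arthroscopic location predictions average the non-negative
per-spectrum predictions of the 8 retained repeats; an all-negative
location is reported missing and excluded, not clamped to zero.
Spearman p-values are exact for $n \le 9$ without ties and use the
t-approximation otherwise (a full permutation null beyond that size is
not what any standard implementation does); the Mann–Whitney U test is
two-sided with exact small-sample p-values and tie-corrected normal
approximation otherwise; the Shapiro–Wilk gate is informational — the
pipeline's group comparisons are nonparametric regardless, matching
the emulated analysis.

## Mechanics reference module

The indentation simulator is a standard linear (Zener) solid with
relaxation modulus $E_{eq} + (E_{inst} - E_{eq})e^{-t/\tau}$ driven by
the protocol strain history, integrated by an exact exponential-kernel
recursion. The analysis recovers $E_{eq}$ as the slope of equilibrium
stress (mean force over the final 10% of each hold, divided by the
indenter area) versus applied strain over the *linear region* — the
contiguous subset of ≥ 2 steps maximising $R^2$, preferring longer
subsets within numerical tolerance — converted with $\nu = 0.1$;
$E_{dyn}$ is the stress/strain amplitude ratio of a least-squares
sinusoid fit at 1.0 Hz (phase-invariant), converted with $\nu = 0.5$.
The Hayes-type aspect-ratio correction $\kappa$ is a pluggable scalar
with default 1: the published correction tables are not reproduced
here, and simulator and analyser apply $\kappa/(1-\nu^2)$ consistently
so round-trip recovery is exact up to noise.

## Problem sizes and determinism

The test suite and acceptance script run the default study design
(10 ponies, 236 measured locations, 3 168 acquisitions) for end-to-end
checks, with selection at stride 8 and budget 10; statistical
calibration uses 1 000 null and 200 alternative replicates of the
reference-property model only (no spectra needed); mechanics
round-trips use shortened 60 s holds, which the relaxation time
constant (4 s) still completes. Every stochastic step is seeded:
identical configuration and seed give byte-identical reports, and all
sub-seeds are derived from the single global seed.

## Known limitations

* Latent states are independent across locations; real studies have
  pony- and joint-level correlation, which would widen uncertainty and
  complicate the group comparison.
* The forward spectral model is additive-Gaussian in band space;
  scatter effects are reduced to one baseline slope parameter, so
  scatter-correction preprocessing (deliberately out of scope) is
  untested here.
* Model "test" metrics are optimistic whenever the test set
  participates in selection (all three variants, by design fidelity).
* The per-repeat contact model and the light-contamination levels are
  plausible stand-ins chosen once; they are conditions of the
  synthetic study, not estimates of any real acquisition process.
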