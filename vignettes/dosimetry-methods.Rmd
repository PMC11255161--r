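---
title: "Methods: reference and simplified dosimetry for Lu-177 radioligand therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference and simplified dosimetry for Lu-177 radioligand therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rltdosim)
```

## The dosimetry model

Absorbed dose to a source region follows the MIRD formalism restricted to
self-dose. For a region of mass $m$ (grams) containing time-integrated
activity $\tilde A$ (MBq·h), the absorbed dose is

$$ D = \tilde A \cdot S(m), \qquad
   S(m) = \frac{3.6\times 10^{9}\,\frac{\text{decays}}{\text{MBq·h}} \cdot E_e}{m}, $$

where $E_e$ is the mean energy of all electron emissions per decay
(default 147.9 keV for Lu-177: beta, conversion and Auger electrons,
ICRP 107 yields) and complete local absorption of electrons is assumed.
This is the standard sphere-model approximation for Lu-177 at organ and
lesion sizes: the electron range (≲2 mm) is small against the region
dimensions, and the photon self-dose is a few percent at most. A photon
term can be switched on by supplying a `(mass, fraction)` table to
`radionuclide()`; it is off by default because it is small for Lu-177 and
no generally applicable tabulation is assumed. With $E_e$ in keV and $m$
in grams, $S(m) = 0.5768 \cdot E_e / m$ mGy/(MBq·h); at 1 g this gives
85.31 mGy/(MBq·h). Units are fixed package-wide: time h, activity MBq,
TIA MBq·h, mass g, dose mGy, normalized dose mGy/MBq, cumulated totals Gy.

Kidneys are treated as a single paired region of combined mass with the
same mass-scaled self-dose factor as spheres; at this level of
abstraction a phantom kidney scaled to patient mass and a sphere of equal
mass coincide (electron local deposition), and any residual geometry
difference is absorbed into the configurable photon term. Salivary glands
use ICRP reference masses (parotid 25.0 g, submandibular 12.5 g); lesion
masses come from volumes with densities 1.92 g/cm³ (bone, as cortical
bone) and 1.03 g/cm³ (soft tissue); kidney volume converts at 1.06 g/cm³.

## Time-activity curve fitting

The reference method fits each TAC by least squares on untransformed
activities (log-linear regression is used only for initialization and for
exact two-point fits): organ and lesion TACs are typically 4 points, and
untransformed least squares matches what clinical dosimetry suites do.
The cascade in `select_fit()` is:

1. If the first sample lies below the second and ≥4 points exist, an
   uptake biexponential $A_0(e^{-\lambda_{eff}t} - e^{-\lambda_{up}t})$
   is attempted (initialized from a post-peak monoexponential and an
   uptake half-life of 1 h; rejected when $\lambda_{up}/\lambda_{eff} <
   1.05$, i.e. the two phases are not separable).
2. Otherwise a monoexponential is fitted — to all points when the TAC is
   monotone decreasing, else from the peak onward.
3. If fitting fails or the residual RMS exceeds 20% of the peak
   activity, the TAC is integrated trapezoidally with a monoexponential
   tail fitted to the last 2 or 3 points (3 when the last three
   activities decrease monotonically — the excretion phase started
   earlier — else 2).

Numerical choices: clearance rates are bounded to effective half-lives in
[0.5, 1000] h; a fit pinned at a bound (e.g. non-decaying data) is
returned flagged rather than silently accepted. The 20% residual
threshold and the tail-point rule are fixed, documented constants — the
operational reading of "a fit to all data points was not possible". Both
are deliberate package choices; no universal criterion exists. Inputs are
sorted internally, so fits are invariant to sample order. Integration
runs from injection at $t=0$: analytically for exponential models
($A_0/\lambda_{eff}$, resp. $A_0(1/\lambda_{eff} - 1/\lambda_{up})$), and
for the trapezoid route as a linear rise from zero to the first sample
(the conventional conservative choice for the unobserved 0–2 h segment),
trapezoids between samples, and an $A_{last}/\lambda_{tail}$ tail.
Fits are unweighted; weighting is not exposed because the generator's
noise model (constant CV) would make $1/A^2$ weighting optimal in a way
real data would not honour.

## Simplified methods

For cycles after the first, three estimators avoid repeated full imaging:

* **SM1** assumes the pharmacokinetics of cycle 1 and rescales its fitted
  curve through one measured point: $f = A_{meas}(t_1)/\hat A_1(t_1)$,
  $\tilde A_i = f\,\tilde A_1$. Rescaling the analytic TIA by the
  activity ratio at the observation time is equivalent to rescaling the
  whole fitted TAC; for a monoexponential it also equals re-fitting with
  the cycle-1 half-life fixed. Observation times are restricted to
  (0, 400] h; the "72–168 h" option uses each cycle's own last scan time,
  mirroring the heterogeneous fourth imaging point of the emulated
  protocol, not a fixed 72 h.
* **SM2**: $D_i = (D_1/A_1)\,A_i$.
* **SM3**: $D_i = \tfrac12(D_1/A_1 + D_2/A_2)\,A_i$.

SM2/SM3 are refused for lesions: tumor uptake declines across cycles, so
an injected-activity extrapolation is biased upward by construction.
When totalling over cycles, the cycles a method extrapolates *from* are
taken from the reference method (cycle 1; for SM3 also cycle 2), so
cumulated totals compare like with like.

## Agreement analysis

`bland_altman()` reports the mean percent difference (bias) and
1.96 × sample SD limits of agreement; `rmse()` the root mean square error
in input units. The percent-difference denominator defaults to the
reference value (with the Bland–Altman mean-of-pair denominator as an
option): the comparisons are against a designated reference method, not
between two arbitrary raters. Lesion agreement is summarised both per
individual lesion and per patient-mean lesion (`sm1_comparison_table()`).
Pooled comparisons weight per record, not per patient.

The between-cycle comparison (`between_cycle_test()`) is a
repeated-measures permutation test: the statistic is the variance of
per-cycle means, and cycle labels are permuted within each
patient/region, tolerating missing cells (dropped lesions). It is a
design-based stand-in for a parametric mixed-effects repeated-measures
analysis; its p-values are not expected to match such a model's, only its
qualitative verdicts (the test suite checks a flat profile gives p = 1,
a strong lesion decline gives p < 0.05, and the type-I error holds its
nominal level).

## What the synthetic cohort emulates — and what it does not

The generator works backwards from published per-cycle summary targets:
for each region kind and cycle it holds a target normalized dose and
effective half-life (defaults in `default_organ_kinetics()` /
`default_lesion_kinetics()`), inverts them into true kinetics via
`kinetics_from_targets()` (so forward dosimetry returns the target
exactly), and then perturbs:

* **Inter-patient spread**: one lognormal, mean-one multiplier per
  region for dose and one for half-life, shared across cycles, with CV
  taken as the kind's mean SD/mean ratio across its cycle rows. A single
  shared patient effect cannot carry four different per-cycle CVs; using
  the mean CV keeps the per-cycle cohort means unbiased while the
  patient-level correlation across cycles — the assumption SM1 lives on —
  is preserved.
* **Inter-cycle jitter**: an independent lognormal multiplier per cycle
  (CV 0.10 by default) on amplitude and, for organs, half-life. Lesion
  half-lives are held constant across cycles: the emulated study found
  tumor dose decline to be uptake-driven, with similar half-lives between
  cycles. The 0.10 default reproduces single-time-point limits of
  agreement of the observed order; it is a free knob, not an inferred
  quantity, because between-cycle kinetic correlation is not published.
* **Measurement noise**: i.i.d. multiplicative lognormal, mean one,
  CV 0.05 per sample — the typical quantitative-SPECT repeatability
  scale.
* **Injected activity**: truncated normal, centre 6.2 GBq, SD 0.5,
  range [5.0, 6.7] GBq (the published centre ± spread and range; a
  truncated normal reproduces both the central value and the range).
* **Imaging schedule**: 2/24/48 h plus a last point drawn from
  {72, 96, 120, 144, 168} h with weights (0.12, 0.15, 0.20, 0.24, 0.29),
  chosen once so the mean last time point is ~130 h as in the emulated
  protocol (only the support and the mean are published; the weights are
  the package's own resolution of that constraint).
* **Lesions**: 90 lesions (70 bone, 19 lymph node, 1 local recurrence),
  at most 10 per patient, with per-kind per-cycle dose targets whose
  ratios encode the uptake decline, and dropout hitting the analyzable
  counts 90/87/79/67 exactly (dropped lesions stay dropped). Dropout is
  independent of dose level, which keeps per-cycle means interpretable
  but ignores that low-uptake lesions are likelier to become invisible.
* **Lesion kinetics default to monoexponential.** With the first scan at
  2 h and an uptake half-life around 1 h, the uptake phase is largely
  unobservable at this schedule; a biexponential truth would add a
  parameter the 4-point data barely constrain. `lesion_model =
  "uptake_biexp"` (uptake half-life 1 h) exercises the biexponential
  branch and is covered by the recovery tests at a looser tolerance.

The generator does **not** simulate images: no VOI segmentation, partial
volume or spill-out, no count statistics, no registration error. Its
noise is uncorrelated across time points, whereas segmentation biases in
real data persist within a patient. Passing round-trip tests therefore
demonstrates that the pipeline's estimators are consistent and unbiased
under the stated statistical model — not that real-world accuracy equals
the simulated one.

## Validation problem sizes

The test suite validates closed forms exactly; analytic TIA against
adaptive quadrature on 1000 random kinetics (≤0.1%); monoexponential
recovery over 500 noisy TACs (bias < 1%, median |error| < 5% at 5%
noise); cohort-level round-trips over 32 seed replicates of the default
16-patient cohort (organ and lesion means and half-lives recovered within
5–7%); and the protocol orderings (organ agreement best at 24/48 h,
lesion agreement better late than early, SM3 tighter than SM2 over 100
replicates). `scripts/acceptance.R` reports the pooled cohort quantities
over 20 replicates. These sizes keep the full suite in a few minutes on
one core while holding Monte-Carlo error near or below the asserted
tolerances.

## Known limitations

* Self-dose only; cross-dose between regions is out of scope, as is red
  bone marrow dosimetry and voxel/Monte-Carlo dosimetry.
* The sphere model with local electron deposition is accurate to a few
  percent for organ-sized masses but is not a re-implementation of any
  specific dose-factor software; exact agreement with such tools is not
  certifiable and not attempted.
* Fitted-parameter uncertainty is summarised by residual RMS only; no
  covariance or Bayesian propagation.
* The permutation test replaces, and does not reproduce, parametric
  mixed-model inference.
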