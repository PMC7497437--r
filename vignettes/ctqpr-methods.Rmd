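---
title: "Stenosis-related CT perfusion ratios: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stenosis-related CT perfusion ratios: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctqpr)
```

## The problem

Absolute myocardial blood flow (MBF, mL/g/min) from dynamic contrast-enhanced
cardiac CT varies substantially between individuals even in normal myocardium,
which frustrates any universal MBF cutoff for detecting hemodynamically
significant coronary disease (invasive fractional flow reserve, FFR ≤ 0.80).
The quantitative perfusion ratio (QPR) divides each voxel's MBF by a
*reference* MBF extracted from the same heart, so per-patient global factors —
cardiac output, microvascular tone, calibration of the MBF estimator itself —
cancel. Combined with a Voronoi allocation of the left-ventricular (LV)
myocardium to coronary branches, the mean QPR over the myocardium *distal to a
stenosis* ("stenosis-related QPR") is a vessel-specific, scale-free index that
can be compared against FFR.

`ctqpr` implements this chain end to end — MBF by regularized deconvolution,
Voronoi territories, histogram reference, stenosis-related regional values,
and the vessel-level diagnostic statistics — plus a synthetic phantom and
vessel-table generator, because no patient data are distributed with the
package. Everything below is computed by the package's own tests; no empirical
claim here goes beyond what they run.

## Perfusion model

Tissue enhancement follows the indicator-dilution convolution model
$$C(t) = \frac{\mathrm{MBF}}{60}\,\rho\,(\mathrm{AIF} \otimes R)(t),$$
with $\rho = 1.05$ g/mL tissue density (the perfusion convention; MBF in
mL/g/min, hence the factor 60) and $R$ the impulse residue function. The
forward simulator uses a plug-flow box residue, $R(t) = 1$ for $t <
\mathrm{MTT}$ and 0 after: it is the simplest residue for which the maximum of
the flow-scaled residue equals $\mathrm{MBF}\rho/60$ exactly, making recovery
checkable to machine precision. The arterial input is a peak-normalized
gamma-variate
$$a(t) = A\left(\frac{t-t_0}{\alpha\beta}\right)^{\alpha}
e^{\,\alpha-(t-t_0)/\beta}, \quad t > t_0,$$
with defaults $A = 300$ HU, $t_0 = 6$ s, $\alpha = 3$, $\beta = 1.5$ s —
a first-pass aortic bolus peaking at $t_0 + \alpha\beta = 10.5$ s. Frames are
spaced 0.73 s apart by default (one acquisition per heartbeat at the ~82 bpm
stress heart rate the acquisition emulates), 30 frames, so the 21 s window
covers the first pass.

Voxel-wise MBF is recovered by discrete deconvolution: the lower-triangular
convolution matrix $M_{ij} = \Delta t\, a_{i-j+1}$ is pseudo-inverted by
truncated SVD (singular values below a fraction of the largest are zeroed),
and $\widehat{\mathrm{MBF}} = \max_t \hat h(t) \cdot 60/\rho$, clamped at
zero, where $\hat h$ is the recovered flow-scaled residue. Non-uniform
per-heartbeat frame times are first linearly resampled to the median frame
interval; HU curves are converted to enhancement by subtracting the mean of
the first `baseline_frames` (default 4) pre-contrast frames.

### The truncation threshold, and why two regimes need different values

The spectrum of $M$ is determined entirely by the AIF. With a 6 s bolus onset
the first ~9 frames of the AIF are zero, so $M$ is rank-deficient: its
normalized spectrum decays smoothly to about $1.2\times10^{-3}$ and then drops
to numerical zero (the delay-induced null space). Two consequences, both
measured by the test suite:

* **Noiseless data.** Truncating only the numerical-zero block
  (`regularization_fraction = 1e-3`) makes the inversion exact for box
  residues — recovery errors below 0.01% across MBF 0.5–2.5 mL/g/min and MTT
  4–12 s. Any *stronger* truncation discards informative components of the
  sharp residue edge and produces a systematic Gibbs overshoot of the residue
  maximum of about +8–9%, essentially independent of MBF and MTT.
* **Noisy data.** At realistic CT noise the near-null components amplify
  noise catastrophically (orders of magnitude at `1e-3`); the standard
  bolus-deconvolution choice `regularization_fraction = 0.15` keeps the
  median bias under 10% at noise of 5% of the tissue peak.

The package therefore ships `deconv_config(regularization_fraction = 0.15)`
as the clinical-noise default, and the noiseless-inversion tests use `1e-3`:
truncation exists solely to damp noise, and there is no single value that is
simultaneously exact on clean data and robust on noisy data. The +8%
overshoot of the noisy-regime default is *linear* in the tissue curve, so it
cancels exactly in every QPR — which is precisely the argument for preferring
the ratio over absolute MBF, and the package's scale-invariance tests verify
it to floating-point tolerance.

A per-voxel moving-median over time (`temporal_smooth`, default window 3) is
the package's stand-in for the vendor temporal despiking filter; it is the
only noise filter applied, and spatial filtering and elastic registration are
deliberately out of scope (grids are assumed co-registered).

## Territories and the stenosis-related region

Each LV voxel is assigned to the branch of the coronary tree minimizing the
Euclidean distance (world mm) from the voxel center to the branch centerline,
with the polyline resampled at half the smallest voxel dimension to
approximate continuous-curve distance. Coordinate conventions are fixed so
the engine is exactly checkable: 0-based voxel indices, voxel-center world
coordinates `index * spacing`, per-point squared distances accumulated in a
fixed order, and exact distance ties broken toward the lowest branch id. The
test suite demands bit-exact agreement with a naive per-voxel brute-force
search on random phantoms up to 32³.

The *stenosis-related* territory of a seed point is the myocardium of the
subtree distal to it: the seed's branch from the seed vertex onward (a voxel
of that branch counts as distal when its nearest centerline point lies at or
beyond the seed's arc-length position) plus every descendant branch attaching
at or beyond the seed, in full. Moving a seed distally can only shrink the
region, and when one vessel carries several seeds the most proximal one
(smallest root arc length; ties to the lower branch id) is the culprit. CTA
significance follows the ≥ 50% luminal-reduction rule, with un-assessable
calcified segments counted as significant.

## Reference MBF and QPR

The reference MBF is the mode of the LV-wide MBF histogram: Freedman–Diaconis
bin width, highest-count bin (ties to the lowest bin), refined as the mean of
values within one bin width of that bin's center. The mode — rather than a
mean or median — is what makes the reference robust to a hypoperfused
minority; it assumes normal myocardium is the single largest coherent
perfusion level, and will mislead when nearly the whole LV is hypoperfused
(severe three-vessel disease), an acknowledged failure mode of any
same-heart reference. Whether stenotic territories should be excluded from
the histogram is an open design point; the package uses the whole LV.

QPR is the voxel-wise ratio to this reference; stenosis-related MBF and QPR
are arithmetic means over the stenosis-related mask (the mean, not the
median, is fixed by declaration for reproducibility). Global rescaling of the
MBF map multiplies stenosis-related MBF by the same factor and leaves every
stenosis-related QPR unchanged — the mechanism behind the smaller coefficient
of variation of QPR.

## Synthetic data: what it emulates, and what it does not

`make_phantom` builds an ellipsoidal-shell LV on a small grid (default 24³ at
2 mm), lays 3–4 branch polylines on the epicardial surface (LAD with a
diagonal, LCX, RCA), labels ground-truth territories with an independent
brute-force implementation of the same nearest-branch rule, and simulates one
stenosis seed per root vessel. Each seed draws an FFR (prevalence 20/39 of
significant vessels, uniform within (0.5, 0.8] / (0.8, 1.0]); territories
distal to FFR ≤ 0.8 seeds are dimmed by a factor drawn from the significant
QPR component (0.71 ± 0.08), while territories of FFR-negative vessels remain
at the normal reference level of 1.95 mL/g/min — the level back-computed from
the printed group pairs (1.38/0.71 ≈ 1.74/0.86 ≈ 1.95–2.0). Dimming only the
FFR-positive territories keeps hypoperfusion in one-to-one correspondence
with hemodynamically significant vessels and preserves a normal majority for
the histogram mode; the milder group statistics of non-significant vessels
(1.74 ± 0.35, 0.86 ± 0.07) are treated as *measurement-level* distributions
and are generated by `simulate_vessel_table`, which feeds the diagnostic
statistics.

`simulate_vessel_table` draws the two groups from the printed normal
components truncated at zero, and couples FFR to both indices through a
shared standard-normal latent variable per vessel (Gaussian copula,
correlation 0.7), giving tunable Spearman correlations of the kind reported
clinically without asserting a generative model the study never stated.
Vessels are treated as independent; the within-patient correlation among a
patient's vessels is unknown and not modeled.

The phantom deliberately omits CT physics (beam hardening, scatter,
recirculation), cardiac motion, transmural flow gradients and AIF
partial-volume effects. Passing tests therefore demonstrate the correctness
of the *computational chain* under its stated model, not clinical accuracy
on real scanners.

## Diagnostic statistics

The vessel-level evaluation reproduces the standard battery: Spearman
correlation of each index with FFR (mid-ranks), pooled-variance two-sided
t test between FFR groups, empirical ROC with the Mann–Whitney AUC (ties
count ½; pair counting provably equals the trapezoidal area, and the suite
checks the identity on 1,000 random instances), Youden-index cutoff (ties
resolved toward higher sensitivity, then the lower threshold; the returned
cutoff is the midpoint to the next observed value so re-applying it
reproduces the operating point), sensitivity/specificity/PPV/NPV with
truncated Wald 95% CIs on the percent scale, the DeLong placement-value test
for two correlated AUCs (the package's reading of the study's unnamed
correlated-ROC method), ICC(2,1) from the two-way mean-squares decomposition,
and the coefficient of variation with the large-sample CI
$\mathrm{se}(\mathrm{CV}) = \mathrm{CV}\sqrt{\tfrac{1}{2(n-1)}}
\sqrt{1+2\,\mathrm{CV}^2}$. Wald rather than Wilson/exact intervals are used
because the truncated Wald form reproduces the published interval style for
proportions near the boundary (95% on n = 20 → 85–100); note that published
PPV/NPV intervals of this style are not generally reproducible from raw
counts by any simple Wald computation, and the package makes no attempt to
guess an alternative. Lower index values indicate disease for both MBF and
QPR throughout; tests are two-sided at 0.05.

## Numerical choices and degenerate inputs

* All randomness is explicitly seeded; one seed per generator call, and the
  pipeline derives stage seeds by fixed offsets from the run seed.
* Negative MBF estimates are clamped to zero (physical constraint).
* An all-zero AIF, an empty mask or tree, a single-class vessel table, a
  constant vector fed to the Spearman or ICC routines, and an empty PPV/NPV
  denominator all raise errors or flagged `NA`s rather than silent results.
* A constant MBF map short-circuits the histogram (bin width 0) to its mean.
* `classify_cta` requires a percent only for assessable segments.

## Problem sizes

The shipped tests run phantoms at 16³–24³ with one 32³ engine-vs-oracle
check, 30-frame acquisitions, vessel tables at the study size (20 + 19) and
at n = 10,000 per group for distributional checks — sizes chosen so the whole
suite exercises every stage, including the end-to-end smoke run, in well
under a minute of CPU on a laptop-class core.

## Known limitations

* The deconvolution default carries the +8% systematic MBF overshoot
  discussed above; absolute MBF values from the noisy-regime default should
  be read with that calibration in mind, while QPR is unaffected.
* CT noise biases the residue maximum upward, more strongly at low flow, so
  noisy runs compress QPR contrast toward 1; territory means and orderings
  remain stable in the shipped configurations.
* The histogram reference fails by design when no normal majority exists.
* The Voronoi rule ignores vessel caliber and uses centerline distance only,
  and no registration between CTA and CTP frames is modeled.
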