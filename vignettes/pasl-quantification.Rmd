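---
title: "Quantifying perfusion from pulsed ASL: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perfusion from pulsed ASL: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paslcbf)
```

## The measurement and its model

Pulsed arterial spin labeling (PASL) inverts the magnetization of
arterial blood water below the imaging slab and images the brain twice —
once with labeling, once with a control that matches everything except
the inversion. The control-minus-label difference is proportional to the
amount of labeled blood delivered to each voxel, i.e. to perfusion. The
difference signal is small (well under 1% of the static tissue signal),
so a series of label/control pairs is acquired and averaged, and the
quantitative chain has to be careful about everything that can bias a
sub-percent signal: subject motion, intravascular label still in transit,
relaxation of the label, slice-timing differences, and partial-volume
averaging at tissue boundaries.

`paslcbf` models the difference signal with the three-phase single blood
compartment model. Labeled blood arrives after an arterial transit time
`att` (Δt), flows in for the bolus duration `tau` (τ), and decays
throughout with the longitudinal relaxation time of blood `t1b`:

$$
\Delta M(t) =
\begin{cases}
0 & t < \Delta t\\
2\alpha M_{0b}\, f\,(t-\Delta t)\,e^{-t/T_{1b}} & \Delta t \le t < \Delta t+\tau\\
2\alpha M_{0b}\, f\,\tau\, e^{-t/T_{1b}} & t \ge \Delta t+\tau
\end{cases}
$$

with labeling efficiency $\alpha$, blood equilibrium magnetization
$M_{0b}$, and perfusion $f$. The model assumes a single well-mixed
compartment, plug flow of the bolus (no dispersion), and decay with the
blood T1 (no exchange-driven transition to tissue T1). These assumptions
are simplifications — two-compartment and dispersed-bolus models exist —
but the three-phase form is the standard operating model for PASL
quantification and is what this package implements (`delta_m`).

All times are handled internally in milliseconds and perfusion in
mL/g/ms; CBF crosses the API boundary in the field's reporting unit,
mL/100 g/min, via the single conversion factor $6\times10^6$. Keeping one
internal unit system and converting only at the surface avoids silent
factor errors, which unit mixtures in this formula invite.

## Two quantification routes

**Multi-inversion-time fitting** (`fit_kinetic`). Sampling
$\Delta M(t)$ over a ladder of inversion times (the package default is
the 12-step 50, 300, 600, ..., 3300 ms ladder) constrains `cbf`, `att`
and `tau` jointly. The fit is bounded Levenberg–Marquardt least squares
(via `minpack.lm`), with bounds `cbf` ∈ [0, 300] mL/100 g/min, `att` ∈
[0, 3000] ms, `tau` ∈ [100, 3000] ms, starting values (50, 700, 1000),
cost tolerances $10^{-12}$, and at most 500 iterations — deterministic
given data and start. The signal amplitude is calibrated with the
measured $M_{0b}$ rather than freed: amplitude and perfusion enter the
model only as a product, so freeing both would make the fit
unidentifiable. Where a fourth parameter is wanted, `free_t1b = TRUE`
frees the blood T1 instead, which is identifiable through the curve
shape. The model is continuous but has breakpoint kinks in `att`/`tau`;
evaluating it as a continuous clamped-ramp expression keeps
finite-difference Jacobians stable across the breakpoints.

**Single-subtraction mapping** (`cbf_single_subtraction`, `cbf_map`).
With the bolus truncated at a known width TI1 (Q2TIPS saturation) and an
inversion time long enough that the full bolus has arrived
($TI_2 \ge \Delta t + TI_1$), the plateau-phase expression inverts to

$$
\mathrm{CBF} = \frac{\lambda\,\Delta M}{2\alpha M_0\, TI_1\, e^{-TI_2/T_{1b}}},
\qquad M_{0b} = M_0/\lambda .
$$

This is applied voxelwise with the slice's effective inversion time
$TI_2 = TI_{2,\mathrm{base}} + k\,\Delta t_{\mathrm{slice}}$ (ascending
acquisition, default 30 ms increment), which compensates the
longitudinal-relaxation difference between slices. Negative differences
are deliberately preserved in the map — they are the signature of
subtraction errors and feed the QC metrics — and voxels with
non-positive $M_0$ yield `NA` rather than an error.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `ti1` | 800 | ms | temporal bolus width (saturation cutoff) |
| `ti2_base` | 1800 | ms | inversion time of first slice |
| `slice_dt` | 30 | ms | per-slice acquisition increment |
| `alpha` | 0.95 | — | inversion efficiency of the labeling pulse |
| `t1b` | 1664 | ms | blood T1 at 3 T |
| `lambda` | 0.9 | mL/g | blood/tissue water partition coefficient |
| trim fraction | 0.05 | — | per-tail trim of ROI voxel signals |
| motion thresholds | 1 mm/1°, 2 mm/2° | | correct / exclude tiers |
| probability threshold | 0.75 | — | tissue mask inclusion |
| re-binarization cut | 0.9 | — | conservative cut for interpolated masks |

The blood T1 deserves a note: quantified CBF scales with
$e^{TI_2/T_{1b}}$, and reasonable literature values at 3 T differ by
several percent. The default of 1664 ms is a common 3 T value; it is
exposed in `acq_params()` and the run config precisely so users can
check the sensitivity of their numbers to it rather than inherit a
hidden constant.

Statistical conventions: the trimmed mean removes `floor(trim * n)`
voxels per tail, so small ROIs are never emptied (19 voxels at 5%
trimming keep all 19); all standard deviations are sample (n − 1)
deviations, which is what reconstructs the published five-subject table
cells (`cerebellum_cbf_reference`) to their printed precision; the
coefficient of variation is 100·sd/mean; paired method comparisons use
the classical two-tailed paired t-test with df = n − 1.

Masking resolves GM/WM conflicts (both probabilities above threshold) in
favor of the higher probability, ties to GM, so the masks are disjoint
by construction. Raising any threshold can only remove voxels, and the
cascade is idempotent — both properties are under test.

## The digital phantom

`phantom_spec()`/`build_phantom()` render a two-tissue phantom: a
grey-matter ellipsoidal shell (CBF 45 mL/100 g/min, Δt 700 ms, τ 900 ms,
M0 1000) around a white-matter core (27, 800 ms, 1000 ms, 1150), on a
32 × 32 × 12 grid of 3.48 × 3.48 × 6 mm voxels. The truth values sit
inside the transit-time (550–1000 ms) and bolus-duration (800–1500 ms)
windows reported for cerebellum at 3 T, and the GM/WM ratio of 1.67
brackets published ratios near 1.6. Probability maps are boxcar-smoothed
indicator functions, so boundary voxels take intermediate values as real
interpolated segmentation maps do. `simulate_series()` forward-models
the acquisition: control = M0 baseline + Gaussian thermal noise (default
sd 10, i.e. 1% of GM M0, so the difference SNR after 90 pairs is in the
range of a well-behaved 3 T session), label = baseline − ΔM with
per-slice inversion times and the bolus truncated at TI1.

Three deliberate imperfections make the screening logic testable:

* **Vessel hyperintensities** — compact clusters in the inferior slices
  whose difference-signal amplitude (80 units at zero delay) decays
  exponentially (time constant 1000 ms) and is identically zero at or
  beyond the 1000 ms extinction delay. These parameters were chosen so
  that, with 30 pairs per delay as in a typical optimization session,
  the artifact's contribution dominates the delay dependence of the
  spatial coefficient of variation up to extinction: the sweep
  (`emulate_delay_sweep`) then shows spatial variability falling
  monotonically to a minimum at the 1000 ms delay and rising slowly
  after it as SNR decays — the decision pattern by which the optimal
  postlabeling delay is identified.
* **A partial-volume rim** — the one-voxel boundary shell has M0
  attenuated (factor 0.6) and perfusion attenuated more strongly
  (factor 0.35), emulating volume averaging with surroundings that are
  proton-rich but unperfused. This produces the boundary-restricted
  positive CBF-vs-M0 correlation that the QC module
  (`cbf_m0_correlation`, `low_intensity_filter`) detects and removes.
  Because the rim deliberately biases ROI CBF low, truth-recovery
  identities are stated on the rim-free phantom; the rim-enabled phantom
  is the QC fixture. This mirrors real data, where boundary
  partial-volume voxels depress GM CBF means unless screened.
* **Method profiles** — a `"picore"` profile adds alternating per-slice
  difference offsets (a magnetization-transfer mismatch surrogate) and
  random venous-inflow spikes in inferior slices. This is an emulation,
  not pulse-sequence physics: it exists so that the comparative claims
  (higher interslice and temporal variability for asymmetric labeling)
  can be exercised as directional tests.

All randomness flows from the single spec seed through private RNG
streams, so a spec reproduces its dataset bit for bit. What the phantom
does **not** emulate: realistic anatomy, EPI distortion or susceptibility
physics, bolus dispersion, physiological (cardiac/respiratory) noise,
and rotational motion resampling — passing tests on the phantom
therefore validate the arithmetic and decision logic of the pipeline,
not its robustness to those real-data effects.

## Motion handling

Motion parameter *estimation* is out of scope — the trace (3
translations, 3 rotations per volume) is an input, produced by any
registration tool, or by the simulator as ground truth. The screening
rule is two-tier: any translation above 1 mm or rotation above 1° flags
a volume for correction; above 2 mm or 2° the volume is excluded, and
exclusion always removes the whole label/control pair, because a
difference image with one corrupted member is worthless. Correction
inverts the recorded translation by trilinear interpolation; rotations
drive decisions but are not resampled, since series with rotations large
enough to matter fall under the exclusion rule.

## Validation strategy and problem sizes

The test-suite works outward from oracles: closed-form spot values of the
kinetic model checked against independent one-line evaluations;
trimmed-mean, correlation and variability statistics checked against
brute-force sort-and-slice and covariance formulas; and then
self-consistency loops — noiseless simulate → subtract → quantify
returns the phantom truth to 10⁻⁸ relative, and noiseless curves refit
to 10⁻⁶ relative from deliberately wrong starting values. Stochastic
behavior is pinned with fixed-seed Monte-Carlo at moderate sizes chosen
to keep the full suite in tens of seconds: 200 noisy twelve-point curves
for parameter recovery (median absolute errors ~2–4%), a seven-delay
sweep at 30 pairs per delay, and 90-pair end-to-end runs on the
32 × 32 × 12 grid. The five-subject reference table is reconstructed
cell by cell, with tolerance of one unit in the last printed digit
(published derived rows were rounded from unrounded intermediates, so
exact re-rounding can differ by one digit in the last place).

## Known limitations

* The single blood compartment model ignores dispersion and
  blood-to-tissue water exchange; fitted `att`/`tau` absorb those
  effects on real data.
* The fourth parameter of four-parameter fitting schemes is not uniquely
  defined in the literature; here the principled options are a fixed
  measured amplitude (default) or a free blood T1 — a free amplitude
  alongside CBF is refused as unidentifiable.
* The intensity cut for low-M0 screening (default 800) is in scanner
  units and must be recalibrated per dataset; the default matches the
  phantom's signal scale (interior M0 ≈ 1000–1150).
* Temporal variability uses a configurable slice subset (default: the
  four most inferior slices, standing in for slices near the transverse
  sinuses); on real data the subset should be chosen anatomically.
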