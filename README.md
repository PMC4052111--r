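# paslcbf

Quantification of cerebral blood flow (CBF) from pulsed arterial spin
labeling (PASL) MRI, aimed at perfusion studies of inferior brain regions
such as the cerebellum, where intravascular artifacts, partial-volume
averaging at tissue boundaries, and the choice of postlabeling delay all
matter. The package covers the full analysis path from a raw alternating
label/control image series to per-subject and group grey-matter (GM) and
white-matter (WM) CBF tables, together with a deterministic digital
phantom so the whole pipeline can be exercised and validated without
scanner data.

## The model

The label-control difference signal of a PASL acquisition is described by
the three-phase single blood compartment model. With arterial transit
time Δt, bolus duration τ, labeling efficiency α, blood longitudinal
relaxation time T1b, and equilibrium blood magnetization M0b, the
difference signal at inversion time *t* is

    ΔM(t) = 0                                   t < Δt
    ΔM(t) = 2 α M0b f (t − Δt) exp(−t/T1b)      Δt ≤ t < Δt + τ
    ΔM(t) = 2 α M0b f τ exp(−t/T1b)             t ≥ Δt + τ

where *f* is perfusion in mL/g/ms (CBF in mL/100 g/min divided by
6 × 10⁶). Fitting this curve over a ladder of inversion times
(`fit_kinetic`) estimates CBF, Δt and τ. When a single inversion time is
used with the bolus truncated to a known width TI1 (Q2TIPS), CBF is
obtained directly from the mean difference image ΔM and the
proton-density image M0 by the single-subtraction formula

    CBF = λ ΔM / (2 α M0 TI1 exp(−TI2/T1b)),   M0b = M0/λ,

with the blood/tissue partition coefficient λ, applied voxelwise with a
per-slice effective TI2 to compensate slice-timing relaxation
differences (`cbf_map`).

Around this core the package provides motion screening of label/control
pairs (correct above 1 mm/1°, exclude pairs above 2 mm/2°), pairwise
subtraction and averaging, probability-threshold tissue masking,
trimmed-mean ROI statistics, interslice/spatial/temporal variability
metrics, paired method comparisons, and QC diagnostics (CBF-vs-M0
correlation, low-intensity voxel screening, intensity histograms).

## Worked example

Reconstructing the group statistics and method comparison for a published
five-subject FAIR ASST vs PICORE cerebellum dataset from its per-subject
CBF values:

```r
library(paslcbf)
ref <- cerebellum_cbf_reference()
perfusion_report(ref, methods = c("fair", "picore"))
#> Group statistics (mean, S.D., C.V. %):
#>      fair_gm fair_wm fair_ratio picore_gm picore_wm picore_ratio
#> mean   43.79   27.56       1.60     40.35     23.73         1.79
#> sd      5.06    4.50       0.15      8.51      7.53         0.47
#> cv     11.60   16.30       9.30     21.10     31.70        26.20
paired_ttest(ref$fair_gm, ref$picore_gm)
#> t = 1.870, df = 4, p = 0.135
```

GM CBF is about 1.6 times WM CBF for the FAIR variant, and the two
labeling schemes do not differ significantly in mean CBF (p = 0.135 for
GM), though the asymmetric scheme is roughly twice as variable.

Running the pipeline end to end on a simulated phantom (GM truth
45 mL/100 g/min, WM truth 27, 90 label/control pairs at thermal noise
typical of 3 T):

```r
ph  <- build_phantom(phantom_spec(seed = 7, m0_rim = list(factor = 1, cbf_factor = 1)))
acq <- acq_params(ti1 = 800, ti2_base = 1800)
sim <- simulate_series(ph, acq, n_pairs = 90, seed = 7)
sub <- pairwise_subtract(sim$series, screen_motion(sim$trace), sim$trace)
cbf <- cbf_map(mean_pwi(sub), mean_m0(sim$m0_pre, sim$m0_post), acq)
masks <- build_tissue_masks(ph$gm_prob, ph$wm_prob, ph$roi)
roi_cbf(cbf, masks$gm, 0.05); roi_cbf(cbf, masks$wm, 0.05)
#> GM CBF: 45.13  WM CBF: 24.86  ratio: 1.82
```

The config-driven wrappers `run_simulate()`, `run_quantify()` and
`run_fit()` execute the same stages against files on disk (NIfTI series,
TSV motion traces, YAML/JSON configs) with manifests and stage logs.

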