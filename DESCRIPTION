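Package: paslcbf
Title: Pulsed Arterial Spin Labeling Perfusion Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of cerebral blood flow (CBF) from pulsed
    arterial spin labeling (PASL) MRI. Implements the single blood
    compartment kinetic model for the label-control difference signal,
    single-subtraction CBF mapping with slice-timing compensation,
    motion screening of label/control series, nonlinear least-squares
    estimation of arterial transit time and bolus duration from
    multi-inversion-time data, probability-threshold tissue masking,
    grey/white matter ROI statistics with interslice, spatial and
    temporal variability metrics, quality-control diagnostics for
    partial-volume and susceptibility effects, and a deterministic
    digital phantom generator for end-to-end validation of the
    pipeline without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
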