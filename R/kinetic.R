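#' PASL difference signal under the single blood compartment model
#'
#' Evaluates the three-phase, single blood compartment model of the
#' label-control difference signal \eqn{\Delta M(t)} at inversion time `t`:
#' zero before the labeled bolus arrives (`t < att`), rising linearly with
#' the delivered bolus while it flows in (`att <= t < att + tau`), and
#' decaying with the blood T1 once the full bolus has been delivered
#' (`t >= att + tau`):
#' \deqn{\Delta M(t) = 0, \quad t < \Delta t}
#' \deqn{\Delta M(t) = 2\alpha M_{0b}\, f\,(t - \Delta t)\, e^{-t/T_{1b}},
#'   \quad \Delta t \le t < \tau + \Delta t}
#' \deqn{\Delta M(t) = 2\alpha M_{0b}\, f\,\tau\, e^{-t/T_{1b}},
#'   \quad t \ge \tau + \Delta t}
#' where \eqn{f} is perfusion in mL/g/ms (i.e. `cbf / 6e6`). The function is
#' continuous at both phase boundaries.
#'
#' @param t Inversion time(s), ms; vectorized. Must be non-negative.
#' @param kp [kinetic_params()] object.
#' @param acq [acq_params()] object (supplies `alpha` and `t1b`).
#' @return Difference signal in the same units as `kp$m0b`, one value per
#'   element of `t`.
#' @seealso [cbf_single_subtraction()] for the inverse operation at a
#'   single inversion time.
#' @examples
#' acq <- acq_params()
#' kp <- kinetic_params(cbf = 45, att = 700, tau = 900, m0b = 1000)
#' delta_m(seq(0, 3000, by = 300), kp, acq)
#' @export
delta_m <- function(t, kp, acq) {
  stopifnot(inherits(kp, "asl_kinetic"), inherits(acq, "asl_acq"))
  if (any(t < 0)) stop("inversion time t must be non-negative")
  f <- kp$cbf / CBF_UNIT_FACTOR                 # mL/g/ms
  amp <- 2 * acq$alpha * kp$m0b * f
  delivered <- pmin(pmax(t - kp$att, 0), kp$tau)  # bolus delivered by time t
  amp * delivered * exp(-t / acq$t1b)
}

#' Blood equilibrium magnetization from tissue proton density
#'
#' Converts the measured tissue proton-density signal M0 to the
#' equilibrium magnetization of arterial blood via the blood/tissue water
#' partition coefficient: `m0b = m0_tissue / lambda`.
#'
#' @param m0_tissue Tissue proton-density signal (vectorized).
#' @param lambda Partition coefficient, mL/g; must be positive.
#' @return Blood magnetization in the same signal units.
#' @export
m0_blood <- function(m0_tissue, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a positive scalar")
  m0_tissue / lambda
}

#' Effective inversion time of a slice
#'
#' Slices are read out sequentially in ascending order, so slice `k`
#' (0-based) is acquired `k * slice_dt` ms after the first; its effective
#' total inversion time is `ti2_base + k * slice_dt`. Quantification and
#' model fitting use this per-slice time to compensate longitudinal
#' relaxation differences between slices.
#'
#' @param slice_index 0-based slice index (vectorized), ascending
#'   acquisition order.
#' @param acq [acq_params()] object.
#' @return Effective TI2 in ms.
#' @export
slice_effective_ti2 <- function(slice_index, acq) {
  stopifnot(inherits(acq, "asl_acq"))
  if (any(slice_index < 0)) stop("slice_index must be non-negative")
  acq$ti2_base + slice_index * acq$slice_dt
}

#' Single-subtraction CBF quantification
#'
#' Converts a mean label-control difference signal and a tissue
#' proton-density signal to perfusion using the single blood compartment
#' model at a single inversion time, assuming the full truncated bolus
#' (of width TI1) has been delivered and is decaying with the blood T1:
#' \deqn{CBF = \frac{\lambda\, \Delta M}{2 \alpha M_0\, TI_1\,
#'   e^{-TI_2/T_{1b}}}}
#' The result is returned in mL/100 g/min. The sign of the output follows
#' the sign of `dm`, so subtraction errors (negative perfusion signal)
#' survive for downstream QC. Voxels with non-positive `m0` yield `NA`
#' rather than an error, matching voxelwise use where such voxels are
#' masked out upstream.
#'
#' @param dm Mean difference signal (control minus label); vectorized.
#' @param m0 Tissue proton-density signal; vectorized (recycled against
#'   `dm`).
#' @param acq [acq_params()] object.
#' @param ti2 Effective inversion time(s), ms; defaults to `acq$ti2_base`.
#'   Pass per-slice values (see [slice_effective_ti2()]) for slice-timing
#'   compensation.
#' @return CBF in mL/100 g/min.
#' @export
cbf_single_subtraction <- function(dm, m0, acq, ti2 = acq$ti2_base) {
  stopifnot(inherits(acq, "asl_acq"))
  m0b <- m0_blood(m0, acq$lambda)
  denom <- 2 * acq$alpha * m0b * acq$ti1 * exp(-ti2 / acq$t1b)
  out <- dm / denom * CBF_UNIT_FACTOR
  out[!is.na(m0) & m0 <= 0] <- NA_real_
  out
}

#' Voxelwise CBF map with slice-timing compensation
#'
#' Applies [cbf_single_subtraction()] to every voxel of a mean
#' perfusion-weighted image, using each slice's effective inversion time.
#'
#' @param mean_pwi 3D array: mean difference image (control minus label).
#' @param mean_m0 3D array: mean proton-density image, same dimensions.
#' @param acq [acq_params()] object.
#' @return 3D array of CBF, mL/100 g/min; `NA` where `m0 <= 0`.
#' @export
cbf_map <- function(mean_pwi, mean_m0, acq) {
  stopifnot(length(dim(mean_pwi)) == 3,
            identical(dim(mean_pwi), dim(mean_m0)))
  nsl <- dim(mean_pwi)[3]
  out <- array(NA_real_, dim(mean_pwi))
  for (k in seq_len(nsl)) {
    ti2 <- slice_effective_ti2(k - 1L, acq)
    out[, , k] <- cbf_single_subtraction(mean_pwi[, , k], mean_m0[, , k],
                                         acq, ti2 = ti2)
  }
  out
}
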