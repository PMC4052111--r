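# Conversion between the external CBF unit (mL/100 g/min) and the internal
# unit system (times in ms, flow in mL/g/ms): 100 g -> g and min -> ms.
CBF_UNIT_FACTOR <- 6e6

#' Acquisition parameters for a PASL experiment
#'
#' Bundles the timing and calibration constants of a pulsed arterial spin
#' labeling acquisition. All times are in milliseconds. `ti1` is the temporal
#' bolus width (the time at which saturation pulses truncate the labeled
#' bolus); `ti2_base` is the total inversion time at which the first
#' (most inferior) slice is acquired; later slices are read out
#' `slice_dt` ms apart in ascending order, so slice `k` (0-based) has an
#' effective inversion time of `ti2_base + k * slice_dt`.
#'
#' @param ti1 Temporal bolus width, ms.
#' @param ti2_base Total inversion time of the first slice, ms
#'   (`ti2_base >= ti1`).
#' @param slice_dt Per-slice acquisition time increment, ms.
#' @param tr Repetition time, ms.
#' @param alpha Labeling (inversion) efficiency, in (0, 1].
#' @param t1b Longitudinal relaxation time of arterial blood, ms. The
#'   default of 1664 ms is a standard 3 T literature value; override it to
#'   probe the sensitivity of quantified CBF to this assumption.
#' @param lambda Blood/tissue water partition coefficient, mL/g.
#'
#' @return An object of class `asl_acq`: a validated list with the above
#'   fields.
#' @examples
#' acq <- acq_params(ti1 = 800, ti2_base = 1800)
#' slice_effective_ti2(0:11, acq)
#' @export
acq_params <- function(ti1 = 800, ti2_base = 1800, slice_dt = 30,
                       tr = 2500, alpha = 0.95, t1b = 1664, lambda = 0.9) {
  stopifnot(
    "ti1 must be a positive number"            = is.numeric(ti1) && length(ti1) == 1 && ti1 > 0,
    "ti2_base must be >= ti1"                  = is.numeric(ti2_base) && length(ti2_base) == 1 && ti2_base >= ti1,
    "slice_dt must be non-negative"            = is.numeric(slice_dt) && length(slice_dt) == 1 && slice_dt >= 0,
    "tr must be positive"                      = is.numeric(tr) && length(tr) == 1 && tr > 0,
    "alpha must be in (0, 1]"                  = is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1,
    "t1b must be positive"                     = is.numeric(t1b) && length(t1b) == 1 && t1b > 0,
    "lambda must be positive"                  = is.numeric(lambda) && length(lambda) == 1 && lambda > 0
  )
  structure(list(ti1 = ti1, ti2_base = ti2_base, slice_dt = slice_dt,
                 tr = tr, alpha = alpha, t1b = t1b, lambda = lambda),
            class = "asl_acq")
}

#' @export
print.asl_acq <- function(x, ...) {
  cat("PASL acquisition parameters\n")
  cat(sprintf("  TI1 / TI2(first slice): %g / %g ms (slice increment %g ms)\n",
              x$ti1, x$ti2_base, x$slice_dt))
  cat(sprintf("  TR: %g ms   alpha: %g   T1b: %g ms   lambda: %g mL/g\n",
              x$tr, x$alpha, x$t1b, x$lambda))
  invisible(x)
}

#' Kinetic parameters of the single blood compartment model
#'
#' Per-voxel or per-ROI physiological parameters governing the PASL
#' difference signal: perfusion `cbf` (mL/100 g/min), arterial transit
#' time `att` (ms, the delay between labeling and arrival of labeled blood
#' in the voxel), bolus duration `tau` (ms, the temporal width of the
#' labeled bolus), and `m0b`, the fully relaxed magnetization of arterial
#' blood in scanner signal units.
#'
#' @param cbf Perfusion, mL/100 g/min (non-negative).
#' @param att Arterial transit time, ms (non-negative).
#' @param tau Bolus duration, ms (positive).
#' @param m0b Equilibrium blood magnetization, signal units (positive).
#' @return An object of class `asl_kinetic`: a validated list.
#' @export
kinetic_params <- function(cbf, att, tau, m0b) {
  stopifnot(
    "cbf must be non-negative" = is.numeric(cbf) && length(cbf) == 1 && cbf >= 0,
    "att must be non-negative" = is.numeric(att) && length(att) == 1 && att >= 0,
    "tau must be positive"     = is.numeric(tau) && length(tau) == 1 && tau > 0,
    "m0b must be positive"     = is.numeric(m0b) && length(m0b) == 1 && m0b > 0
  )
  structure(list(cbf = cbf, att = att, tau = tau, m0b = m0b),
            class = "asl_kinetic")
}

#' @export
print.asl_kinetic <- function(x, ...) {
  cat(sprintf("Kinetic parameters: CBF %.2f mL/100g/min, ATT %.0f ms, tau %.0f ms, M0b %.1f\n",
              x$cbf, x$att, x$tau, x$m0b))
  invisible(x)
}
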