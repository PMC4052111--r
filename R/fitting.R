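#' Two-tailed trimmed mean of voxel signals
#'
#' Robust ROI aggregation: drops `floor(trim_frac * n)` voxels from each
#' tail of the sorted signal distribution and averages the rest. The floor
#' rule means small ROIs are never emptied (for n = 19 and 5% trimming, no
#' voxel is removed and the plain mean is returned). This guards ROI means
#' against bright intravascular signal at short postlabeling delays and
#' against negative subtraction-error voxels.
#'
#' @param values Numeric vector of voxel signals.
#' @param trim_frac Proportion trimmed from each tail, in \[0, 0.5).
#' @return Scalar mean.
#' @export
trimmed_mean <- function(values, trim_frac = 0.05) {
  if (length(values) == 0) stop("cannot take trimmed mean of empty input")
  if (!is.numeric(trim_frac) || trim_frac < 0 || trim_frac >= 0.5)
    stop("trim_frac must be in [0, 0.5)")
  k <- floor(trim_frac * length(values))
  if (2 * k >= length(values)) k <- 0L   # unreachable under floor rule; guard anyway
  if (k == 0) return(mean(values))
  s <- sort(values)
  mean(s[(k + 1):(length(s) - k)])
}

#' ROI signal curve over inversion times
#'
#' @param ti2 Effective inversion times, ms; must be strictly increasing.
#' @param dm Trimmed-mean difference signal at each inversion time.
#' @param n_voxels Voxel count behind each point (all > 0).
#' @param roi,slice Optional identifiers carried through to outputs.
#' @return A data.frame of class `roi_curve` with columns
#'   `ti2_ms dm n_voxels roi slice`.
#' @export
roi_signal_curve <- function(ti2, dm, n_voxels = rep(1L, length(ti2)),
                             roi = "roi", slice = NA_integer_) {
  stopifnot(length(ti2) == length(dm), length(n_voxels) == length(ti2))
  if (any(diff(ti2) <= 0)) stop("ti2 values must be strictly increasing")
  if (any(n_voxels <= 0)) stop("each curve point needs n_voxels > 0")
  structure(data.frame(ti2_ms = ti2, dm = dm, n_voxels = n_voxels,
                       roi = roi, slice = slice),
            class = c("roi_curve", "data.frame"))
}

#' Extract per-slice ROI curves from a multi-TI2 experiment
#'
#' Each experiment in a varied-inversion-time study yields one mean
#' perfusion-weighted image at a given first-slice TI2. For every slice
#' intersecting the mask, this computes the trimmed-mean difference signal
#' and the slice's effective inversion time, producing one curve per
#' slice.
#'
#' @param pwi_list List of 3D mean PWI arrays, one per experiment.
#' @param ti2_values First-slice TI2 of each experiment, ms (same length
#'   as `pwi_list`, strictly increasing).
#' @param mask Logical/binary 3D array.
#' @param acq [acq_params()] object (supplies `slice_dt`).
#' @param trim_frac Per-tail trim proportion (see [trimmed_mean()]).
#' @param roi ROI identifier carried into the curves.
#' @return Named list of [roi_signal_curve()]s, one per contributing
#'   slice (`"slice_<k>"`, 0-based).
#' @export
extract_roi_curves <- function(pwi_list, ti2_values, mask, acq,
                               trim_frac = 0.05, roi = "roi") {
  stopifnot(length(pwi_list) == length(ti2_values))
  mask <- mask > 0
  nsl <- dim(mask)[3]
  out <- list()
  for (k in seq_len(nsl)) {
    if (!any(mask[, , k])) next
    dm <- vapply(pwi_list, function(v)
      trimmed_mean(v[, , k][mask[, , k]], trim_frac), numeric(1))
    ti2_eff <- ti2_values + (k - 1L) * acq$slice_dt
    out[[sprintf("slice_%d", k - 1L)]] <-
      roi_signal_curve(ti2_eff, dm, rep(sum(mask[, , k]), length(dm)),
                       roi = roi, slice = k - 1L)
  }
  out
}

#' Average adjacent-slice curves for SNR
#'
#' Pools non-overlapping consecutive slice pairs (first with second, third
#' with fourth, ...): the pair signal is the mean of the two slice signals
#' and the pair's effective inversion time is the mean of the two slices'
#' times. An odd trailing slice is kept unpaired. Used for grey matter,
#' where the long-TI2 signal is weak.
#'
#' @param curves Named list of [roi_signal_curve()]s as returned by
#'   [extract_roi_curves()] (slices in ascending order).
#' @return Named list of pooled curves.
#' @export
average_adjacent_slices <- function(curves) {
  if (length(curves) < 2) return(curves)
  out <- list()
  i <- 1L
  while (i <= length(curves)) {
    if (i + 1L <= length(curves)) {
      a <- curves[[i]]; b <- curves[[i + 1L]]
      stopifnot(nrow(a) == nrow(b))
      nm <- sprintf("slices_%d_%d", a$slice[1], b$slice[1])
      out[[nm]] <- roi_signal_curve((a$ti2_ms + b$ti2_ms) / 2,
                                    (a$dm + b$dm) / 2,
                                    a$n_voxels + b$n_voxels,
                                    roi = a$roi[1], slice = a$slice[1])
      i <- i + 2L
    } else {
      out[[names(curves)[i]]] <- curves[[i]]
      i <- i + 1L
    }
  }
  out
}

#' Fit the kinetic model to an ROI signal curve
#'
#' Bounded nonlinear least squares (Levenberg–Marquardt, via
#' \pkg{minpack.lm}) of the single blood compartment model to a
#' multi-inversion-time difference-signal curve. The free parameters are
#' perfusion (`cbf`), arterial transit time (`att`) and bolus duration
#' (`tau`); the signal amplitude is calibrated by the measured blood
#' magnetization `m0b`. Optionally the blood T1 can be freed as a fourth
#' parameter (`free_t1b = TRUE`). A free multiplicative amplitude is
#' deliberately not offered alongside `cbf`: in this model amplitude and
#' perfusion enter only as a product and would not be separately
#' identifiable.
#'
#' @param curve A [roi_signal_curve()] with at least 5 distinct inversion
#'   times.
#' @param acq [acq_params()] object (fixed `alpha`, and `t1b` unless
#'   freed).
#' @param m0b Measured blood magnetization used to calibrate the signal
#'   amplitude (e.g. mean M0 over the ROI divided by lambda).
#' @param init Named list of starting values; defaults
#'   `cbf = 50, att = 700, tau = 1000` (and `t1b = acq$t1b` if freed).
#' @param lower,upper Named bounds; defaults `cbf` in \[0, 300\]
#'   mL/100 g/min, `att` in \[0, 3000\] ms, `tau` in \[100, 3000\] ms
#'   (`t1b` in \[500, 3000\] ms if freed).
#' @param free_t1b Also estimate the blood T1 (four-parameter fit).
#' @return List of class `kinetic_fit`: `estimate` (named vector), `rss`,
#'   `residuals`, `fitted`, `converged`, `degenerate`, `std_error` (from
#'   the Jacobian; `NA` where not estimable), `n_points`.
#' @export
fit_kinetic <- function(curve, acq, m0b,
                        init = NULL, lower = NULL, upper = NULL,
                        free_t1b = FALSE) {
  stopifnot(inherits(curve, "roi_curve"), inherits(acq, "asl_acq"))
  t <- curve$ti2_ms
  y <- curve$dm
  if (length(unique(t)) < 5)
    stop("need at least 5 distinct inversion times to fit the model")

  par_names <- c("cbf", "att", "tau", if (free_t1b) "t1b")
  defaults <- list(cbf = 50, att = 700, tau = 1000, t1b = acq$t1b)
  lo_def <- list(cbf = 0, att = 0, tau = 100, t1b = 500)
  hi_def <- list(cbf = 300, att = 3000, tau = 3000, t1b = 3000)
  take <- function(user, def) {
    v <- unlist(def[par_names])
    if (!is.null(user)) v[names(user)] <- unlist(user)[names(user)]
    v[par_names]
  }
  p0 <- take(init, defaults)
  lo <- take(lower, lo_def)
  hi <- take(upper, hi_def)

  if (all(y == 0)) {
    est <- p0; est["cbf"] <- 0
    return(structure(list(estimate = est, rss = 0,
                          residuals = rep(0, length(y)), fitted = rep(0, length(y)),
                          converged = TRUE, degenerate = TRUE,
                          std_error = setNames(rep(NA_real_, length(est)), names(est)),
                          n_points = length(y)),
                     class = "kinetic_fit"))
  }

  model <- function(p) {
    t1b <- if (free_t1b) p[["t1b"]] else acq$t1b
    f <- p[["cbf"]] / CBF_UNIT_FACTOR
    delivered <- pmin(pmax(t - p[["att"]], 0), p[["tau"]])
    2 * acq$alpha * m0b * f * delivered * exp(-t / t1b)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lo, upper = hi,
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500)
  )
  est <- fit$par
  resid <- y - model(est)
  rss <- sum(resid^2)
  se <- tryCatch({
    cv <- chol2inv(chol(fit$hessian)) * rss / max(1, length(y) - length(est))
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  structure(list(estimate = est, rss = rss, residuals = resid,
                 fitted = model(est),
                 converged = fit$info %in% 1:4, degenerate = FALSE,
                 std_error = se, n_points = length(y)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic model fit (", x$n_points, " points, RSS ",
      format(x$rss, digits = 4), ")\n", sep = "")
  est <- data.frame(estimate = x$estimate, std_error = x$std_error)
  print(round(est, 4))
  if (!x$converged) cat("  ** did not converge **\n")
  if (x$degenerate) cat("  ** degenerate (all-zero) curve **\n")
  invisible(x)
}
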