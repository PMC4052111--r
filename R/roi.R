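#' ROI mean CBF
#'
#' (Optionally trimmed) mean of a CBF map over the voxels of a mask.
#' `NA` voxels (e.g. masked-out zero-M0 voxels) are dropped.
#'
#' @param cbf 3D CBF map, mL/100 g/min.
#' @param mask Logical/binary 3D array; must select at least one finite
#'   voxel.
#' @param trim_frac Per-tail trim proportion; 0 gives the plain mean.
#' @return Scalar CBF, mL/100 g/min.
#' @export
roi_cbf <- function(cbf, mask, trim_frac = 0) {
  v <- cbf[mask > 0]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("mask selects no finite CBF voxels")
  trimmed_mean(v, trim_frac)
}

#' Grey-to-white matter CBF ratio
#'
#' @param cbf_gm,cbf_wm ROI CBF values, mL/100 g/min; `cbf_wm` must be
#'   positive.
#' @return Dimensionless ratio.
#' @export
gm_wm_ratio <- function(cbf_gm, cbf_wm) {
  if (any(cbf_wm <= 0)) stop("WM CBF must be positive for a ratio")
  cbf_gm / cbf_wm
}

#' Coefficient of variation, percent
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' expressed as a percentage. Scale-invariant: `cv_percent(c * x)` equals
#' `cv_percent(x)` for any c > 0.
#'
#' @param values Numeric vector, length at least 2, non-zero mean.
#' @return C.V. in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values for a C.V.")
  m <- mean(values)
  if (m == 0) stop("C.V. undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Interslice variability of a CBF map
#'
#' The C.V. of the per-slice masked mean CBF values: each slice
#' intersecting the mask contributes its mean CBF, and the variability is
#' `cv_percent` over those slice means.
#'
#' @param cbf 3D CBF map.
#' @param mask Logical/binary 3D array; at least two slices must
#'   intersect it.
#' @return C.V. in percent.
#' @export
interslice_cv <- function(cbf, mask) {
  mask <- mask > 0
  nsl <- dim(mask)[3]
  means <- vapply(seq_len(nsl), function(k) {
    v <- cbf[, , k][mask[, , k]]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  means <- means[!is.na(means)]
  if (length(means) < 2) stop("need at least 2 slices intersecting the mask")
  cv_percent(means)
}

#' Spatial variability of a CBF map
#'
#' The C.V. over all masked voxel CBF values.
#'
#' @inheritParams interslice_cv
#' @return C.V. in percent.
#' @export
spatial_cv <- function(cbf, mask) {
  v <- cbf[mask > 0]
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("need at least 2 masked voxels")
  cv_percent(v)
}

#' Temporal variability of a perfusion-weighted series
#'
#' For each time point, the mean difference signal over the masked voxels
#' of a chosen slice subset is computed; the temporal variability is the
#' C.V. over those per-time-point means. The slice subset is conventionally
#' a few inferior slices near the transverse sinuses, where venous inflow
#' instability shows up first.
#'
#' @param pwi 4D perfusion-weighted series (x, y, slice, time).
#' @param mask Logical/binary 3D array.
#' @param slices 1-based slice indices defining the region (default: the
#'   four most inferior slices).
#' @return C.V. in percent.
#' @export
temporal_cv <- function(pwi, mask, slices = 1:4) {
  stopifnot(length(dim(pwi)) == 4)
  if (dim(pwi)[4] < 2) stop("need at least 2 time points")
  sub <- array(FALSE, dim(mask))
  sub[, , slices] <- mask[, , slices] > 0
  if (!any(sub)) stop("slice subset does not intersect the mask")
  means <- apply(pwi, 4, function(v) mean(v[sub]))
  cv_percent(means)
}

#' Group summary statistics
#'
#' Arithmetic mean, sample standard deviation and percent C.V. of a set
#' of per-subject values.
#'
#' @param values Numeric vector, length at least 2.
#' @return Named list `mean`, `sd`, `cv`.
#' @export
group_stats <- function(values) {
  if (length(values) < 2) stop("need at least 2 subjects")
  list(mean = mean(values), sd = stats::sd(values), cv = cv_percent(values))
}

#' Paired two-tailed t-test between two methods
#'
#' Classical paired t-test on the per-subject differences, df = n - 1,
#' two-tailed p from the t distribution. Zero difference variance (e.g.
#' identical inputs) is flagged as degenerate rather than raising.
#'
#' @param values_a,values_b Per-subject values for the two methods, equal
#'   length, n >= 2.
#' @return List `t`, `df`, `p`, `degenerate`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired samples must have equal length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, degenerate = TRUE))
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Per-subject and group perfusion report
#'
#' Assembles the standard report for a two-method perfusion comparison:
#' per-subject GM CBF, WM CBF and GM/WM ratio per method, plus group
#' rows (mean, sample S.D., percent C.V.) per column, mirroring the usual
#' published layout. Raw precision is retained; use [format_report()] for
#' display rounding.
#'
#' @param subjects Data.frame with one row per subject and numeric
#'   columns `<method>_gm` and `<method>_wm` for each entry of `methods`.
#' @param methods Character vector of method names.
#' @return List of class `perfusion_report`: `per_subject` (with added
#'   ratio columns) and `group` (rows mean/sd/cv per column).
#' @export
perfusion_report <- function(subjects, methods) {
  cols <- character(0)
  out <- subjects
  for (m in methods) {
    gm <- subjects[[paste0(m, "_gm")]]
    wm <- subjects[[paste0(m, "_wm")]]
    if (is.null(gm) || is.null(wm))
      stop("missing columns for method ", m)
    out[[paste0(m, "_ratio")]] <- gm_wm_ratio(gm, wm)
    cols <- c(cols, paste0(m, c("_gm", "_wm", "_ratio")))
  }
  grp <- sapply(cols, function(cn) {
    g <- group_stats(out[[cn]])
    c(mean = g$mean, sd = g$sd, cv = g$cv)
  })
  structure(list(per_subject = out, group = as.data.frame(grp)),
            class = "perfusion_report")
}

#' Format a perfusion report for display
#'
#' CBF and ratio cells are rounded to 2 decimals, C.V. rows to 1 decimal,
#' matching common reporting practice.
#'
#' @param report A [perfusion_report()].
#' @return List of rounded data.frames `per_subject` and `group`.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "perfusion_report"))
  ps <- report$per_subject
  num <- vapply(ps, is.numeric, logical(1))
  ps[num] <- lapply(ps[num], round, 2)
  grp <- report$group
  grp["mean", ] <- round(grp["mean", ], 2)
  grp["sd", ] <- round(grp["sd", ], 2)
  grp["cv", ] <- round(grp["cv", ], 1)
  list(per_subject = ps, group = grp)
}

#' @export
print.perfusion_report <- function(x, ...) {
  f <- format_report(x)
  cat("Per-subject CBF (mL/100 g/min) and GM/WM ratio:\n")
  print(f$per_subject)
  cat("\nGroup statistics (mean, S.D., C.V. %):\n")
  print(f$group)
  invisible(x)
}
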