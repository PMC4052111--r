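#' Construct a 4D label/control ASL series
#'
#' @param data 4D numeric array (x, y, slice, volume).
#' @param volume_labels Character vector, one tag per volume, each one of
#'   `"label"`, `"control"` or `"m0"`. Label and control volumes must
#'   alternate and pair 1:1 (after dropping any `"m0"` tags).
#' @param acq [acq_params()] object.
#' @param voxel_mm Numeric length-3 voxel size (mm); the third element is
#'   the slice spacing (thickness + gap).
#' @param pair_order `"label_first"` or `"control_first"`: which member of
#'   each pair is acquired first. Scanner conventions differ, so this must
#'   be explicit.
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(data, volume_labels, acq,
                       voxel_mm = c(3.48, 3.48, 6),
                       pair_order = c("label_first", "control_first")) {
  pair_order <- match.arg(pair_order)
  stopifnot(length(dim(data)) == 4,
            dim(data)[4] == length(volume_labels),
            all(volume_labels %in% c("label", "control", "m0")),
            inherits(acq, "asl_acq"))
  lc <- volume_labels[volume_labels != "m0"]
  if (length(lc) == 0 || length(lc) %% 2 != 0)
    stop("label/control volumes must pair 1:1")
  first <- if (pair_order == "label_first") "label" else "control"
  second <- setdiff(c("label", "control"), first)
  expect <- rep(c(first, second), length(lc) / 2)
  if (!identical(lc, expect))
    stop("label and control volumes must alternate (", pair_order, ")")
  structure(list(data = data, volume_labels = volume_labels, acq = acq,
                 voxel_mm = voxel_mm, pair_order = pair_order),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ASL series: %d x %d x %d voxels, %d volumes (%d label/control pairs, %s)\n",
              d[1], d[2], d[3], d[4],
              sum(x$volume_labels != "m0") / 2, x$pair_order))
  invisible(x)
}

#' Construct a per-volume rigid-body motion trace
#'
#' @param tx,ty,tz Translations, mm, one per volume.
#' @param rx,ry,rz Rotations, degrees, one per volume.
#' @return A data.frame of class `motion_trace` with columns
#'   `volume tx ty tz rx ry rz` (volume is 1-based).
#' @export
motion_trace <- function(tx, ty, tz, rx, ry, rz) {
  n <- length(tx)
  stopifnot(lengths(list(ty, tz, rx, ry, rz)) == n)
  structure(data.frame(volume = seq_len(n), tx = tx, ty = ty, tz = tz,
                       rx = rx, ry = ry, rz = rz),
            class = c("motion_trace", "data.frame"))
}

#' Read / write a motion trace TSV
#'
#' The on-disk format is tab-separated with header
#' `volume tx ty tz rx rz ry` reordered as written: translations in mm,
#' rotations in degrees, one row per volume of the associated series.
#'
#' @param path File path.
#' @return For `read_motion_trace`, a `motion_trace`.
#' @export
read_motion_trace <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("volume", "tx", "ty", "tz", "rx", "ry", "rz")
  if (!all(need %in% names(df)))
    stop("motion trace must have columns: ", paste(need, collapse = " "))
  motion_trace(df$tx, df$ty, df$tz, df$rx, df$ry, df$rz)
}

#' @param trace A `motion_trace`.
#' @rdname read_motion_trace
#' @export
write_motion_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screen a series for subject motion
#'
#' Applies the two-tier motion rule to a per-volume rigid-body trace:
#' a volume with any |translation| > `correct_mm` mm or any |rotation| >
#' `correct_deg` degrees is flagged for motion correction; a volume
#' exceeding `exclude_mm` mm or `exclude_deg` degrees is excluded
#' outright. Exclusion operates on complete label/control pairs: if either
#' member of a pair is excluded, so is its partner.
#'
#' @param trace A [motion_trace()].
#' @param volume_labels Optional tags aligned to the trace (as in
#'   [asl_series()]); `"m0"` volumes are never excluded by series motion
#'   and pair propagation skips them. If omitted, all volumes are assumed
#'   to be alternating label/control.
#' @param correct_mm,correct_deg Correction thresholds (default 1 mm, 1
#'   degree).
#' @param exclude_mm,exclude_deg Exclusion thresholds (default 2 mm, 2
#'   degrees).
#' @return Factor vector (`keep`/`correct`/`exclude`), one per volume.
#' @export
screen_motion <- function(trace, volume_labels = NULL,
                          correct_mm = 1, correct_deg = 1,
                          exclude_mm = 2, exclude_deg = 2) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- nrow(trace)
  if (is.null(volume_labels)) {
    volume_labels <- rep(c("label", "control"), length.out = n)
  } else if (length(volume_labels) != n) {
    stop("volume_labels length does not match motion trace")
  }
  tmax <- pmax(abs(trace$tx), abs(trace$ty), abs(trace$tz))
  rmax <- pmax(abs(trace$rx), abs(trace$ry), abs(trace$rz))
  dec <- rep("keep", n)
  dec[tmax > correct_mm | rmax > correct_deg] <- "correct"
  dec[tmax > exclude_mm | rmax > exclude_deg] <- "exclude"
  # pair-level exclusion: promote a flagged volume's partner
  lc <- which(volume_labels != "m0")
  if (length(lc) %% 2 == 0 && length(lc) > 0) {
    pairs <- matrix(lc, nrow = 2)
    for (j in seq_len(ncol(pairs))) {
      if (any(dec[pairs[, j]] == "exclude")) dec[pairs[, j]] <- "exclude"
    }
  }
  factor(dec, levels = c("keep", "correct", "exclude"))
}

#' Pairwise label/control subtraction
#'
#' Subtracts each label volume from its control partner to produce a
#' perfusion-weighted difference series (control minus label, so that
#' perfusion is positive and subtraction errors show up as negative
#' signal). Pairs containing an excluded volume are dropped. Volumes
#' flagged `correct` are first motion-corrected by inverting their
#' recorded rigid translation with trilinear interpolation (rotations,
#' if any, are not resampled; see Details).
#'
#' @details Motion-parameter estimation is out of scope: the trace is an
#'   input (from a registration tool, or the simulator's ground truth).
#'   Correction inverts the recorded translation by trilinear
#'   interpolation. Recorded rotations still drive the screening decision
#'   but are not resampled; series with rotations large enough to matter
#'   are excluded by the 2-degree rule.
#'
#' @param series An [asl_series()].
#' @param decisions Factor from [screen_motion()] aligned to the series
#'   volumes, or `NULL` to keep every pair.
#' @param trace The [motion_trace()] used for the decisions; required if
#'   any decision is `correct`.
#' @return List with `pwi` (4D array of difference volumes, one per
#'   surviving pair), `n_pairs_total`, `n_pairs_excluded`,
#'   `n_volumes_corrected`.
#' @export
pairwise_subtract <- function(series, decisions = NULL, trace = NULL) {
  stopifnot(inherits(series, "asl_series"))
  labs <- series$volume_labels
  lc <- which(labs != "m0")
  pairs <- matrix(lc, nrow = 2)
  n_total <- ncol(pairs)
  if (is.null(decisions)) decisions <- factor(rep("keep", length(labs)),
                                              levels = c("keep", "correct", "exclude"))
  if (length(decisions) != length(labs))
    stop("decisions length does not match series volumes")

  dat <- series$data
  corrected <- 0L
  to_fix <- which(decisions == "correct")
  if (length(to_fix) > 0) {
    if (is.null(trace)) stop("motion trace required to correct flagged volumes")
    for (v in to_fix) {
      shift_vox <- -c(trace$tx[v], trace$ty[v], trace$tz[v]) / series$voxel_mm
      dat[, , , v] <- translate_volume(dat[, , , v], shift_vox)
      corrected <- corrected + 1L
    }
  }

  keep_pair <- vapply(seq_len(n_total), function(j)
    all(decisions[pairs[, j]] != "exclude"), logical(1))
  if (!any(keep_pair)) stop("no label/control pairs survive motion screening")

  li <- if (series$pair_order == "label_first") 1L else 2L
  ci <- 3L - li
  surv <- which(keep_pair)
  d <- dim(dat)
  pwi <- array(0, c(d[1:3], length(surv)))
  for (j in seq_along(surv)) {
    p <- pairs[, surv[j]]
    pwi[, , , j] <- dat[, , , p[ci]] - dat[, , , p[li]]
  }
  list(pwi = pwi,
       n_pairs_total = n_total,
       n_pairs_excluded = sum(!keep_pair),
       n_volumes_corrected = corrected)
}

#' Mean perfusion-weighted image
#'
#' Voxelwise arithmetic mean over the difference volumes of a
#' perfusion-weighted series.
#'
#' @param pwi 4D array of difference volumes (or the list returned by
#'   [pairwise_subtract()]).
#' @return 3D array.
#' @export
mean_pwi <- function(pwi) {
  if (is.list(pwi)) pwi <- pwi$pwi
  stopifnot(length(dim(pwi)) == 4, dim(pwi)[4] >= 1)
  rowMeans(pwi, dims = 3)
}

#' Mean proton-density (M0) image
#'
#' Voxelwise mean of the M0 images acquired before and after the ASL
#' series. M0 images are never excluded by series motion screening.
#'
#' @param m0_pre,m0_post 3D arrays with identical dimensions.
#' @return 3D array.
#' @export
mean_m0 <- function(m0_pre, m0_post) {
  if (!identical(dim(m0_pre), dim(m0_post)))
    stop("M0 image geometries do not match")
  (m0_pre + m0_post) / 2
}

# Shift a 3D volume by a (possibly fractional) voxel offset using trilinear
# interpolation; out-of-volume samples take the nearest edge value.
translate_volume <- function(vol, shift_vox) {
  d <- dim(vol)
  out <- vol
  # sample source coordinate = target - shift
  gx <- seq_len(d[1]) - shift_vox[1]
  gy <- seq_len(d[2]) - shift_vox[2]
  gz <- seq_len(d[3]) - shift_vox[3]
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  x0 <- cl(floor(gx), d[1]); x1 <- cl(x0 + 1L, d[1]); fx <- gx - floor(gx)
  y0 <- cl(floor(gy), d[2]); y1 <- cl(y0 + 1L, d[2]); fy <- gy - floor(gy)
  z0 <- cl(floor(gz), d[3]); z1 <- cl(z0 + 1L, d[3]); fz <- gz - floor(gz)
  for (k in seq_len(d[3])) {
    a00 <- vol[x0, y0, z0[k]] * (1 - fz[k]) + vol[x0, y0, z1[k]] * fz[k]
    a10 <- vol[x1, y0, z0[k]] * (1 - fz[k]) + vol[x1, y0, z1[k]] * fz[k]
    a01 <- vol[x0, y1, z0[k]] * (1 - fz[k]) + vol[x0, y1, z1[k]] * fz[k]
    a11 <- vol[x1, y1, z0[k]] * (1 - fz[k]) + vol[x1, y1, z1[k]] * fz[k]
    b0 <- a00 * (1 - outer(rep(1, d[1]), fy)) + a01 * outer(rep(1, d[1]), fy)
    b1 <- a10 * (1 - outer(rep(1, d[1]), fy)) + a11 * outer(rep(1, d[1]), fy)
    out[, , k] <- b0 * (1 - fx) + b1 * fx
  }
  out
}
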