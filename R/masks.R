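#' Threshold a tissue probability map
#'
#' @param prob_map 3D array of tissue probabilities in \[0, 1\].
#' @param p_thresh Probability threshold in (0, 1\]; a voxel enters the
#'   mask iff its probability is at least the threshold. The conventional
#'   value for high-probability tissue masks is 0.75.
#' @return Logical 3D array.
#' @export
threshold_probability <- function(prob_map, p_thresh = 0.75) {
  if (!is.numeric(p_thresh) || p_thresh <= 0 || p_thresh > 1)
    stop("p_thresh must be in (0, 1]")
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE))
    stop("probability map values must lie in [0, 1]")
  array(prob_map >= p_thresh, dim(prob_map))
}

#' Constrain a mask to an anatomical ROI
#'
#' Voxelwise logical AND between a tissue mask and a region-of-interest
#' mask (e.g. a hand-drawn cerebellum outline), on the same grid.
#'
#' @param mask,roi_mask Logical/binary 3D arrays with identical
#'   dimensions.
#' @return Logical 3D array.
#' @export
constrain_to_roi <- function(mask, roi_mask) {
  if (!identical(dim(mask), dim(roi_mask)))
    stop("mask and ROI grids do not match")
  array((mask > 0) & (roi_mask > 0), dim(mask))
}

#' Re-binarize an interpolated mask
#'
#' Masks resampled between grids with continuous interpolation acquire
#' intermediate voxel values in (0, 1), some of which spill slightly
#' beyond the intended region. A conservative cut (typically 0.9) keeps
#' only voxels whose value is at least the cut. The result is always a
#' subset of the support of the input.
#'
#' @param mask 3D array with values in \[0, 1\].
#' @param cut Threshold in (0, 1\].
#' @return Logical 3D array.
#' @export
rebinarize <- function(mask, cut = 0.9) {
  if (!is.numeric(cut) || cut <= 0 || cut > 1) stop("cut must be in (0, 1]")
  if (any(mask < 0 | mask > 1, na.rm = TRUE))
    stop("mask values must lie in [0, 1]")
  array(mask >= cut, dim(mask))
}

#' Build disjoint GM and WM masks from probability maps
#'
#' Full masking cascade: threshold the grey- and white-matter probability
#' maps at `p_thresh`, constrain both to the anatomical ROI, and resolve
#' any voxel passing both thresholds by assigning it to the tissue with
#' the higher probability (ties go to grey matter), so the returned masks
#' are disjoint. If continuous values are present (interpolated masks),
#' apply [rebinarize()] first.
#'
#' @param gm_prob,wm_prob 3D probability maps in \[0, 1\].
#' @param roi_mask Anatomical ROI mask on the same grid.
#' @param p_thresh Probability threshold (default 0.75).
#' @return List of class `tissue_masks`: logical arrays `gm` and `wm`,
#'   plus `thresholds` recording the provenance.
#' @export
build_tissue_masks <- function(gm_prob, wm_prob, roi_mask, p_thresh = 0.75) {
  gm <- constrain_to_roi(threshold_probability(gm_prob, p_thresh), roi_mask)
  wm <- constrain_to_roi(threshold_probability(wm_prob, p_thresh), roi_mask)
  both <- gm & wm
  if (any(both)) {
    gm_wins <- both & (gm_prob >= wm_prob)
    gm[both] <- gm_wins[both]
    wm[both] <- !gm_wins[both]
  }
  structure(list(gm = gm, wm = wm,
                 thresholds = list(p_thresh = p_thresh)),
            class = "tissue_masks")
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf("Tissue masks (p >= %g): %d GM voxels, %d WM voxels\n",
              x$thresholds$p_thresh, sum(x$gm), sum(x$wm)))
  invisible(x)
}
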