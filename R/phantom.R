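#' Specification of a two-tissue digital perfusion phantom
#'
#' Defines a deterministic phantom emulating the statistical structure of
#' a cerebellar PASL acquisition: a grey-matter ellipsoidal shell
#' enclosing a white-matter core, with per-tissue ground-truth perfusion,
#' arterial transit time, bolus duration and proton density; Gaussian
#' thermal noise; compact intravascular "vessel" clusters in the inferior
#' slices whose difference-signal hyperintensity dies away with
#' postlabeling delay; and a multiplicative proton-density attenuation rim
#' at the phantom surface (the partial-volume signature at tissue
#' boundaries).
#'
#' Default tissue truth (GM: CBF 45 mL/100 g/min, ATT 700 ms, tau 900 ms;
#' WM: CBF 27, ATT 800 ms, tau 1000 ms) sits inside the transit-time
#' (550--1000 ms) and bolus-duration (800--1500 ms) ranges typical of
#' cerebellum at 3 T, with a GM/WM ratio of 1.67.
#'
#' @param dim Grid dimensions (x, y, slices).
#' @param voxel_mm Voxel size, mm (third element = slice spacing).
#' @param gm,wm Named lists with per-tissue truth: `cbf` (mL/100 g/min),
#'   `att` (ms), `tau` (ms), `m0` (signal units).
#' @param noise_sd Thermal noise standard deviation, signal units, equal
#'   on label and control volumes (difference noise sd is
#'   `noise_sd * sqrt(2)`).
#' @param artifact List: `n_clusters` vessel clusters placed in the two
#'   most inferior in-phantom slices, `amplitude` (difference-signal
#'   units at zero delay), `decay_tc` (exponential decay time constant,
#'   ms) and `extinction_delay` (ms; at or beyond this postlabeling delay
#'   the artifact is identically zero).
#' @param m0_rim List: `factor` multiplying M0 on the one-voxel phantom
#'   boundary shell (< 1 attenuates) and `cbf_factor` multiplying the
#'   perfusion truth there. Volume averaging with non-perfused
#'   surroundings depresses the perfusion signal more strongly than the
#'   proton density, so `cbf_factor < factor` induces the
#'   boundary-restricted positive CBF-vs-M0 correlation that the QC
#'   module screens for. Set both to 1 to disable the rim.
#' @param seed Integer seed from which all simulation randomness flows.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32, 32, 12),
                         voxel_mm = c(3.48, 3.48, 6),
                         gm = list(cbf = 45, att = 700, tau = 900, m0 = 1000),
                         wm = list(cbf = 27, att = 800, tau = 1000, m0 = 1150),
                         noise_sd = 10,
                         artifact = list(n_clusters = 3, amplitude = 80,
                                         decay_tc = 1000, extinction_delay = 1000),
                         m0_rim = list(factor = 0.6, cbf_factor = 0.35),
                         seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 8),
            all(unlist(gm) > 0), all(unlist(wm) > 0),
            noise_sd >= 0, m0_rim$factor > 0, m0_rim$factor <= 1)
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm,
                 gm = gm, wm = wm, noise_sd = noise_sd,
                 artifact = artifact, m0_rim = m0_rim,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a private RNG stream; global RNG state untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 3x3x3 boxcar smoothing with edge replication
smooth3_box <- function(a) {
  d <- dim(a)
  acc <- array(0, d); cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    acc <- acc + a[sx, sy, sz]
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Build phantom truth volumes
#'
#' Deterministically renders the phantom geometry and truth maps: a tissue
#' label volume (0 background, 1 GM, 2 WM) from nested ellipsoids, truth
#' maps for CBF, transit time, bolus duration and M0 (with the boundary
#' attenuation rim applied), the phantom-extent ROI mask (standing in for
#' a hand-drawn anatomical ROI), and GM/WM probability maps built by
#' boxcar-smoothing the tissue indicators so that voxels near boundaries
#' take intermediate values in (0, 1), as real interpolated segmentation
#' maps do.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `asl_phantom`: `labels`, `cbf`, `att`, `tau`,
#'   `m0`, `roi`, `gm_prob`, `wm_prob`, `rim`, `vessels` (vessel indicator
#'   volume), `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  cx <- (d + 1) / 2
  # outer ellipsoid semi-axes (voxels): fill most of the grid
  ax_o <- d / 2 - 1.5
  ax_i <- ax_o * c(0.52, 0.52, 0.55)   # WM core
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  r2 <- function(ax) ((idx[, 1] - cx[1]) / ax[1])^2 +
    ((idx[, 2] - cx[2]) / ax[2])^2 + ((idx[, 3] - cx[3]) / ax[3])^2
  inside_o <- r2(ax_o) <= 1
  inside_i <- r2(ax_i) <= 1
  labels <- array(0L, d)
  labels[inside_o] <- 1L
  labels[inside_i] <- 2L
  if (!any(labels == 1L) || !any(labels == 2L))
    stop("degenerate phantom geometry: a tissue region is empty")

  fill <- function(gm_val, wm_val, bg = 0) {
    a <- array(bg, d)
    a[labels == 1L] <- gm_val
    a[labels == 2L] <- wm_val
    a
  }
  cbf <- fill(spec$gm$cbf, spec$wm$cbf)
  att <- fill(spec$gm$att, spec$wm$att)
  tau <- fill(spec$gm$tau, spec$wm$tau, bg = 1)  # tau > 0 everywhere
  m0  <- fill(spec$gm$m0, spec$wm$m0)

  roi <- labels > 0
  # one-voxel boundary rim: phantom voxels with a background neighbour
  eroded <- smooth3_box(array(as.numeric(roi), d)) >= 1 - 1e-9
  rim <- roi & !eroded
  m0[rim] <- m0[rim] * spec$m0_rim$factor
  cbf_fac <- if (is.null(spec$m0_rim$cbf_factor)) 1 else spec$m0_rim$cbf_factor
  cbf[rim] <- cbf[rim] * cbf_fac

  gm_prob <- smooth3_box(array(as.numeric(labels == 1L), d))
  wm_prob <- smooth3_box(array(as.numeric(labels == 2L), d))

  # compact vessel clusters in the two most inferior slices containing tissue
  vessels <- array(FALSE, d)
  zs <- which(apply(roi, 3, any))
  art <- spec$artifact
  if (art$n_clusters > 0) {
    z_art <- zs[seq_len(min(2, length(zs)))]
    centers <- with_seed(spec$seed + 7L, {
      cand <- which(roi[, , z_art[1]], arr.ind = TRUE)
      cand[sample.int(nrow(cand), min(art$n_clusters, nrow(cand))), ,
           drop = FALSE]
    })
    for (i in seq_len(nrow(centers))) {
      xs <- pmin(pmax(centers[i, 1] + (-1:1), 1), d[1])
      ys <- pmin(pmax(centers[i, 2] + (-1:1), 1), d[2])
      for (z in z_art) vessels[xs, ys, z] <- roi[xs, ys, z]
    }
  }

  structure(list(labels = labels, cbf = cbf, att = att, tau = tau, m0 = m0,
                 roi = roi, gm_prob = gm_prob, wm_prob = wm_prob,
                 rim = rim, vessels = vessels, spec = spec),
            class = "asl_phantom")
}

#' @export
print.asl_phantom <- function(x, ...) {
  cat(sprintf("Digital perfusion phantom %s: %d GM, %d WM voxels\n",
              paste(x$spec$dim, collapse = "x"),
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

# noiseless per-slice difference-signal volume for the phantom at the
# acquisition's slice times; Q2TIPS truncation limits the effective bolus
# width to TI1 when truncate_bolus is TRUE
phantom_delta_m <- function(phantom, acq, truncate_bolus = TRUE) {
  d <- dim(phantom$labels)
  dm <- array(0, d)
  for (k in seq_len(d[3])) {
    t <- slice_effective_ti2(k - 1L, acq)
    tau_eff <- if (truncate_bolus) pmin(phantom$tau[, , k], acq$ti1)
               else phantom$tau[, , k]
    m0b <- m0_blood(phantom$m0[, , k], acq$lambda)
    f <- phantom$cbf[, , k] / CBF_UNIT_FACTOR
    delivered <- pmin(pmax(t - phantom$att[, , k], 0), tau_eff)
    dm[, , k] <- 2 * acq$alpha * m0b * f * delivered * exp(-t / acq$t1b)
  }
  dm
}

# vessel hyperintensity amplitude at a given postlabeling delay (ms)
artifact_amplitude <- function(artifact, delay) {
  if (delay >= artifact$extinction_delay) return(0)
  artifact$amplitude * exp(-delay / artifact$decay_tc)
}

#' Simulate a label/control ASL series from a phantom
#'
#' Forward-simulates an alternating label/control acquisition: each
#' control volume is the phantom M0 baseline plus Gaussian thermal noise;
#' each label volume is the baseline minus the slice-timed single blood
#' compartment difference signal (bolus truncated at TI1 when
#' `truncate_bolus`), plus independent noise. When the postlabeling delay
#' (`acq$ti2_base - acq$ti1`) is shorter than the artifact extinction
#' delay, vessel voxels gain a hyperintense difference signal that decays
#' exponentially with delay. Per-volume rigid translations from
#' `motion` are applied by trilinear interpolation and recorded in the
#' returned trace (rotations are recorded but not resampled). A
#' `"picore"` method profile adds alternating per-slice difference
#' offsets (a magnetization-transfer mismatch surrogate) and random
#' venous-inflow spikes in the inferior slices, degrading interslice and
#' temporal stability relative to the clean `"fair"` profile.
#'
#' @param phantom An [build_phantom()] result.
#' @param acq [acq_params()] object.
#' @param n_pairs Number of label/control pairs.
#' @param noise_sd Override of the spec's thermal noise sd.
#' @param artifacts Include vessel hyperintensities.
#' @param truncate_bolus Apply the TI1 bolus truncation (turn off to
#'   emulate a varied-TI2 study with the truncating saturation disabled).
#' @param motion `NULL` (no motion) or a data.frame with columns
#'   `tx ty tz rx ry rz`, one row per volume (2 * n_pairs rows).
#' @param method `"fair"` (clean) or `"picore"` profile.
#' @param seed Seed; defaults to the phantom spec seed.
#' @return List: `series` ([asl_series()]), `trace` ([motion_trace()]),
#'   `m0_pre`, `m0_post` (3D arrays), `dm_truth` (noiseless artifact-free
#'   difference volume), `delay` (postlabeling delay, ms).
#' @export
simulate_series <- function(phantom, acq, n_pairs = 90,
                            noise_sd = phantom$spec$noise_sd,
                            artifacts = TRUE, truncate_bolus = TRUE,
                            motion = NULL,
                            method = c("fair", "picore"),
                            seed = phantom$spec$seed) {
  stopifnot(inherits(phantom, "asl_phantom"), inherits(acq, "asl_acq"))
  method <- match.arg(method)
  if (acq$ti2_base < acq$ti1) stop("schedule inconsistent: TI2 < TI1")
  d <- dim(phantom$labels)
  n_vol <- 2L * n_pairs
  delay <- acq$ti2_base - acq$ti1

  dm_truth <- phantom_delta_m(phantom, acq, truncate_bolus)
  dm_eff <- dm_truth
  if (artifacts) {
    amp <- artifact_amplitude(phantom$spec$artifact, delay)
    if (amp > 0) dm_eff <- dm_eff + amp * phantom$vessels
  }

  slice_offset <- rep(0, d[3])
  vein <- array(FALSE, d)
  if (method == "picore") {
    zs <- which(apply(phantom$roi, 3, any))
    # MT-mismatch surrogate: alternating per-slice difference offset
    slice_offset[zs] <- 0.6 * rep_len(c(1, -1), length(zs)) *
      mean(abs(dm_truth[phantom$roi]))
    vein[, , zs[seq_len(min(3, length(zs)))]] <-
      phantom$vessels[, , zs[seq_len(min(3, length(zs)))]]
  }

  out <- with_seed(seed, {
    dat <- array(0, c(d, n_vol))
    for (p in seq_len(n_pairs)) {
      ctrl <- phantom$m0 + array(stats::rnorm(prod(d), 0, noise_sd), d)
      diff_p <- dm_eff
      if (method == "picore") {
        diff_p <- diff_p + array(rep(slice_offset, each = d[1] * d[2]), d)
        spike <- abs(stats::rnorm(1, 0, 1)) * 2 * mean(abs(dm_truth[phantom$roi]))
        diff_p <- diff_p + spike * vein
      }
      lab <- phantom$m0 - diff_p + array(stats::rnorm(prod(d), 0, noise_sd), d)
      dat[, , , 2L * p - 1L] <- lab
      dat[, , , 2L * p] <- ctrl
    }
    m0_pre <- phantom$m0 + array(stats::rnorm(prod(d), 0, noise_sd), d)
    m0_post <- phantom$m0 + array(stats::rnorm(prod(d), 0, noise_sd), d)
    list(dat = dat, m0_pre = m0_pre, m0_post = m0_post)
  })

  if (is.null(motion)) {
    motion <- data.frame(tx = numeric(n_vol), ty = numeric(n_vol),
                         tz = numeric(n_vol), rx = numeric(n_vol),
                         ry = numeric(n_vol), rz = numeric(n_vol))
  }
  stopifnot(nrow(motion) == n_vol)
  for (v in seq_len(n_vol)) {
    sh <- c(motion$tx[v], motion$ty[v], motion$tz[v]) / phantom$spec$voxel_mm
    if (any(sh != 0)) out$dat[, , , v] <- translate_volume(out$dat[, , , v], sh)
  }

  series <- asl_series(out$dat,
                       rep(c("label", "control"), n_pairs),
                       acq, voxel_mm = phantom$spec$voxel_mm,
                       pair_order = "label_first")
  trace <- motion_trace(motion$tx, motion$ty, motion$tz,
                        motion$rx, motion$ry, motion$rz)
  list(series = series, trace = trace,
       m0_pre = out$m0_pre, m0_post = out$m0_post,
       dm_truth = dm_truth, delay = delay)
}

#' Simulate one series per postlabeling delay
#'
#' Reproduces a delay-optimization experiment: the same phantom is
#' acquired at a ladder of postlabeling delays (TI2 = TI1 + delay), with
#' vessel hyperintensities that shrink with delay and vanish at the
#' artifact extinction delay. Spatial variability of the mean
#' perfusion-weighted image is expected to fall as the artifact decays
#' and to flatten once it is extinct.
#'
#' @param phantom A [build_phantom()] result.
#' @param delays Positive postlabeling delays, ms.
#' @param acq Base [acq_params()]; `ti2_base` is overridden per delay.
#' @param n_pairs Pairs per series.
#' @param ... Passed to [simulate_series()] (e.g. `noise_sd`, `seed`).
#' @return Named list (`delay_<ms>`) of [simulate_series()] results.
#' @export
emulate_delay_sweep <- function(phantom, delays, acq = acq_params(),
                                n_pairs = 30, ...) {
  if (any(delays <= 0)) stop("delays must be positive")
  out <- list()
  for (i in seq_along(delays)) {
    acq_i <- acq_params(ti1 = acq$ti1, ti2_base = acq$ti1 + delays[i],
                        slice_dt = acq$slice_dt, tr = acq$tr,
                        alpha = acq$alpha, t1b = acq$t1b,
                        lambda = acq$lambda)
    out[[sprintf("delay_%d", delays[i])]] <-
      simulate_series(phantom, acq_i, n_pairs = n_pairs,
                      seed = phantom$spec$seed + i, ...)
  }
  out
}

#' Simulate noisy ROI signal curves for a varied-TI2 study
#'
#' Generates ROI-level difference-signal curves on a ladder of inversion
#' times from the single blood compartment model, with Gaussian noise at
#' the level left after averaging: a voxel difference has noise sd
#' `noise_sd * sqrt(2)`, so an ROI point averaging `n_eff` independent
#' voxel-pair samples has sd `noise_sd * sqrt(2 / n_eff)`.
#'
#' @param kp [kinetic_params()] truth.
#' @param acq [acq_params()] object.
#' @param ti2_values First-slice inversion times, ms (default: the
#'   standard 12-step 50--3300 ms ladder).
#' @param n_curves Number of independent noisy curves.
#' @param noise_sd Per-voxel thermal noise sd.
#' @param n_eff Effective number of averaged voxel-pair samples per point
#'   (pairs x ROI voxels).
#' @param seed RNG seed.
#' @return List of [roi_signal_curve()]s.
#' @export
simulate_roi_curves <- function(kp, acq,
                                ti2_values = c(50, seq(300, 3300, by = 300)),
                                n_curves = 1, noise_sd = 10, n_eff = 6000,
                                seed = 1L) {
  stopifnot(inherits(kp, "asl_kinetic"))
  truth <- delta_m(ti2_values, kp, acq)
  sd_point <- noise_sd * sqrt(2 / n_eff)
  with_seed(seed, {
    lapply(seq_len(n_curves), function(i)
      roi_signal_curve(ti2_values,
                       truth + stats::rnorm(length(truth), 0, sd_point),
                       rep(n_eff, length(truth)), roi = "sim"))
  })
}
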