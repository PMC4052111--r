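#' Default run configuration
#'
#' The pipeline stages ([run_simulate()], [run_quantify()], [run_fit()])
#' are driven by a single nested configuration: an `acquisition` block
#' (timing and calibration constants), a `thresholds` block (motion
#' correction/exclusion limits, probability and re-binarization cuts, trim
#' fraction, low-M0 cut), a `simulate` block (phantom truth overrides,
#' pair count, schedule), a `paths` block and a `seed`. Configurations
#' round-trip through YAML or JSON unchanged.
#'
#' @return Nested list with all defaults filled in.
#' @export
default_config <- function() {
  list(
    acquisition = list(ti1 = 800, ti2 = 1800, slice_dt = 30, tr = 2500,
                       alpha = 0.95, t1b = 1664, lambda = 0.9),
    thresholds = list(motion_correct_mm = 1, motion_correct_deg = 1,
                      motion_exclude_mm = 2, motion_exclude_deg = 2,
                      prob = 0.75, rebinarize = 0.9,
                      trim = 0.05, m0_cut = 800),
    simulate = list(n_pairs = 90, noise_sd = 10, artifacts = TRUE,
                    method = "fair",
                    schedule = "single",          # or "ti2_ladder"
                    ladder = c(50, seq(300, 3300, by = 300)),
                    ladder_pairs = 30),
    paths = list(out_dir = "."),
    seed = 1L
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_config()]; everything else is filled in. Basic range checks
#' are applied with the offending field named in the error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  cfg <- modify_defaults(default_config(), user)
  validate_config(cfg)
  cfg
}

modify_defaults <- function(def, user) {
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && is.list(user[[nm]]))
      def[[nm]] <- modify_defaults(def[[nm]], user[[nm]])
    else def[[nm]] <- user[[nm]]
  }
  def
}

validate_config <- function(cfg) {
  chk <- function(ok, field) if (!ok) stop("invalid config field: ", field)
  a <- cfg$acquisition
  chk(a$ti1 > 0, "acquisition.ti1")
  chk(a$ti2 >= a$ti1, "acquisition.ti2")
  chk(a$alpha > 0 && a$alpha <= 1, "acquisition.alpha")
  chk(a$t1b > 0, "acquisition.t1b")
  chk(a$lambda > 0, "acquisition.lambda")
  th <- cfg$thresholds
  chk(th$motion_exclude_mm >= th$motion_correct_mm, "thresholds.motion_exclude_mm")
  chk(th$motion_exclude_deg >= th$motion_correct_deg, "thresholds.motion_exclude_deg")
  chk(th$prob > 0 && th$prob <= 1, "thresholds.prob")
  chk(th$rebinarize > 0 && th$rebinarize <= 1, "thresholds.rebinarize")
  chk(th$trim >= 0 && th$trim < 0.5, "thresholds.trim")
  invisible(cfg)
}

config_acq <- function(cfg) {
  a <- cfg$acquisition
  acq_params(ti1 = a$ti1, ti2_base = a$ti2, slice_dt = a$slice_dt,
             tr = a$tr, alpha = a$alpha, t1b = a$t1b, lambda = a$lambda)
}

# tiny stable string hash (djb2); avoids an extra dependency for a log tag
digest_string <- function(s) {
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_manifest <- function(out_dir, stage, files, cfg, extra = list()) {
  man <- c(list(stage = stage, files = files,
                config_hash = digest_string(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
                seed = cfg$seed),
           extra)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Simulate a phantom dataset to disk
#'
#' Builds the phantom, simulates the label/control series (single delay,
#' or one series per inversion time for the `"ti2_ladder"` schedule) and
#' writes: the 4D series, the two M0 images, tissue probability maps, ROI
#' mask, truth maps, the motion trace TSV, a truth sidecar JSON, and a
#' manifest listing every output. Deterministic given config + seed.
#'
#' @param config Configuration list (see [default_config()]).
#' @param motion Optional per-volume motion data.frame forwarded to
#'   [simulate_series()].
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(config = default_config(), motion = NULL) {
  validate_config(config)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- config_acq(config)
  sim <- config$simulate

  spec <- if (isTRUE(sim$artifacts)) {
    phantom_spec(noise_sd = sim$noise_sd, seed = config$seed)
  } else {
    # artifact battery off: no vessels and no M0 boundary rim
    phantom_spec(noise_sd = sim$noise_sd, seed = config$seed,
                 artifact = list(n_clusters = 0, amplitude = 0,
                                 decay_tc = 1000, extinction_delay = 1000),
                 m0_rim = list(factor = 1, cbf_factor = 1))
  }
  ph <- build_phantom(spec)
  vx <- spec$voxel_mm
  files <- c()
  wv <- function(vol, name) {
    p <- file.path(out_dir, name)
    write_volume(vol, p, vx)
    files <<- c(files, name)
    p
  }
  wv(ph$gm_prob, "gm_prob.nii.gz"); wv(ph$wm_prob, "wm_prob.nii.gz")
  wv(ph$cbf, "truth_cbf.nii.gz"); wv(ph$m0, "truth_m0.nii.gz")
  write_mask(ph$roi, file.path(out_dir, "roi.nii.gz"), vx)
  files <- c(files, "roi.nii.gz")

  if (identical(sim$schedule, "ti2_ladder")) {
    for (ti2 in sim$ladder) {
      # the truncating saturation is off in a varied-TI2 study, so TI1 is
      # inert; clamp it so short inversion times remain representable
      acq_i <- acq_params(ti1 = min(acq$ti1, ti2), ti2_base = ti2,
                          slice_dt = acq$slice_dt, tr = acq$tr,
                          alpha = acq$alpha, t1b = acq$t1b, lambda = acq$lambda)
      s <- simulate_series(ph, acq_i, n_pairs = sim$ladder_pairs,
                           noise_sd = sim$noise_sd, artifacts = FALSE,
                           truncate_bolus = FALSE,
                           seed = config$seed + match(ti2, sim$ladder))
      wv(s$series$data, sprintf("asl_ti2_%04d.nii.gz", ti2))
    }
    s_last <- NULL
  } else {
    s_last <- simulate_series(ph, acq, n_pairs = sim$n_pairs,
                              noise_sd = sim$noise_sd,
                              artifacts = isTRUE(sim$artifacts),
                              method = sim$method, motion = motion,
                              seed = config$seed)
    wv(s_last$series$data, "asl_series.nii.gz")
    wv(s_last$m0_pre, "m0_pre.nii.gz"); wv(s_last$m0_post, "m0_post.nii.gz")
    wv(s_last$dm_truth, "truth_dm.nii.gz")
    write_motion_trace(s_last$trace, file.path(out_dir, "motion.tsv"))
    files <- c(files, "motion.tsv")
  }

  truth <- list(gm = spec$gm, wm = spec$wm, noise_sd = spec$noise_sd,
                artifact = spec$artifact, seed = config$seed,
                schedule = sim$schedule)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "truth.json")
  log_stage("simulate", "wrote %d files to %s (schedule %s)",
            length(files), out_dir, sim$schedule)
  invisible(write_manifest(out_dir, "simulate", files, config))
}

#' Quantify CBF from a simulated or acquired dataset
#'
#' End-to-end single-subtraction quantification: screen the motion trace,
#' pairwise-subtract surviving pairs, average to mean perfusion-weighted
#' and M0 images, map CBF with per-slice inversion times, build GM/WM
#' masks from the probability maps, and assemble ROI statistics
#' (GM and WM CBF, GM/WM ratio, interslice/spatial/temporal variability).
#'
#' @param config Configuration list; `paths$out_dir` must hold the
#'   files written by [run_simulate()] (or equivalently named inputs).
#' @return List of class `quantify_result`: `report` (named numerics),
#'   `cbf` (3D map), `masks`, `counts` (pairs kept / corrected /
#'   excluded), plus output file paths. Also written as JSON/TSV/NIfTI.
#' @export
run_quantify <- function(config = default_config()) {
  validate_config(config)
  out_dir <- config$paths$out_dir
  need <- c(series = "asl_series.nii.gz", m0_pre = "m0_pre.nii.gz",
            m0_post = "m0_post.nii.gz", gm_prob = "gm_prob.nii.gz",
            wm_prob = "wm_prob.nii.gz", roi = "roi.nii.gz",
            motion = "motion.tsv")
  for (role in names(need)) {
    if (!file.exists(file.path(out_dir, need[[role]])))
      stop("missing ", role, " input: ", need[[role]])
  }
  acq <- config_acq(config)
  th <- config$thresholds

  dat <- read_volume(file.path(out_dir, "asl_series.nii.gz"))
  vx <- attr(dat, "pixdim")[1:3]
  n_vol <- dim(dat)[4]
  series <- asl_series(dat, rep(c("label", "control"), n_vol / 2), acq,
                       voxel_mm = vx)
  trace <- read_motion_trace(file.path(out_dir, "motion.tsv"))
  dec <- screen_motion(trace, series$volume_labels,
                       correct_mm = th$motion_correct_mm,
                       correct_deg = th$motion_correct_deg,
                       exclude_mm = th$motion_exclude_mm,
                       exclude_deg = th$motion_exclude_deg)
  sub <- pairwise_subtract(series, dec, trace)
  log_stage("quantify", "pairs: %d total, %d excluded; %d volumes corrected",
            sub$n_pairs_total, sub$n_pairs_excluded, sub$n_volumes_corrected)

  pwi <- mean_pwi(sub)
  m0 <- mean_m0(read_volume(file.path(out_dir, "m0_pre.nii.gz")),
                read_volume(file.path(out_dir, "m0_post.nii.gz")))
  cbf <- cbf_map(pwi, m0, acq)

  gm_prob <- read_volume(file.path(out_dir, "gm_prob.nii.gz"))
  wm_prob <- read_volume(file.path(out_dir, "wm_prob.nii.gz"))
  roi <- read_volume(file.path(out_dir, "roi.nii.gz"))
  masks <- build_tissue_masks(gm_prob, wm_prob, roi, p_thresh = th$prob)
  log_stage("quantify", "masks: %d GM, %d WM voxels", sum(masks$gm), sum(masks$wm))

  cbf_gm <- roi_cbf(cbf, masks$gm, trim_frac = th$trim)
  cbf_wm <- roi_cbf(cbf, masks$wm, trim_frac = th$trim)
  report <- c(cbf_gm = cbf_gm, cbf_wm = cbf_wm,
              ratio = gm_wm_ratio(cbf_gm, cbf_wm),
              interslice_cv_gm = interslice_cv(cbf, masks$gm),
              spatial_cv_gm = spatial_cv(cbf, masks$gm),
              spatial_cv_wm = spatial_cv(cbf, masks$wm),
              temporal_cv = temporal_cv(sub$pwi, masks$gm))

  write_volume(cbf, file.path(out_dir, "cbf.nii.gz"), vx)
  write_mask(masks$gm, file.path(out_dir, "mask_gm.nii.gz"), vx)
  write_mask(masks$wm, file.path(out_dir, "mask_wm.nii.gz"), vx)
  rep_df <- data.frame(metric = names(report), value = unname(report))
  utils::write.table(rep_df, file.path(out_dir, "report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  counts <- list(n_pairs_total = sub$n_pairs_total,
                 n_pairs_excluded = sub$n_pairs_excluded,
                 n_volumes_corrected = sub$n_volumes_corrected)
  jsonlite::write_json(c(as.list(report), counts),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "quantify",
                 c("cbf.nii.gz", "mask_gm.nii.gz", "mask_wm.nii.gz",
                   "report.tsv", "report.json"), config, counts)
  structure(list(report = report, cbf = cbf, masks = masks,
                 counts = counts, pwi = sub$pwi, mean_pwi = pwi,
                 mean_m0 = m0, out_dir = out_dir),
            class = "quantify_result")
}

#' Fit the kinetic model to a multi-TI2 dataset
#'
#' Reads the per-inversion-time series written by the `"ti2_ladder"`
#' schedule of [run_simulate()], reduces each to a mean difference image,
#' extracts per-slice trimmed-mean GM and WM curves (GM curves pooled over
#' adjacent slice pairs for SNR), and fits the single blood compartment
#' model to each curve. Results (estimates, standard errors, diagnostics)
#' are written as JSON.
#'
#' @param config Configuration list; `paths$out_dir` must hold ladder
#'   outputs of [run_simulate()].
#' @param pool_gm_slices Average adjacent GM slices before fitting.
#' @return Invisibly, a nested list of [fit_kinetic()] results
#'   (`$gm`, `$wm`, by curve name), also written to `fits.json`.
#' @export
run_fit <- function(config = default_config(), pool_gm_slices = TRUE) {
  validate_config(config)
  out_dir <- config$paths$out_dir
  acq <- config_acq(config)
  th <- config$thresholds
  ladder <- config$simulate$ladder
  if (length(unique(ladder)) < 5)
    stop("need at least 5 distinct inversion times in the ladder")
  paths <- file.path(out_dir, sprintf("asl_ti2_%04d.nii.gz", ladder))
  missing <- !file.exists(paths)
  if (any(missing)) stop("missing multi-TI2 series input: ",
                         basename(paths[missing][1]))

  gm_prob <- read_volume(file.path(out_dir, "gm_prob.nii.gz"))
  wm_prob <- read_volume(file.path(out_dir, "wm_prob.nii.gz"))
  roi <- read_volume(file.path(out_dir, "roi.nii.gz"))
  masks <- build_tissue_masks(gm_prob, wm_prob, roi, p_thresh = th$prob)
  m0_truth <- read_volume(file.path(out_dir, "truth_m0.nii.gz"))

  pwi_list <- lapply(paths, function(p) {
    dat <- read_volume(p)
    series <- asl_series(dat, rep(c("label", "control"), dim(dat)[4] / 2), acq)
    mean_pwi(pairwise_subtract(series))
  })

  fit_tissue <- function(mask, pool) {
    curves <- extract_roi_curves(pwi_list, ladder, mask, acq,
                                 trim_frac = th$trim)
    if (pool) curves <- average_adjacent_slices(curves)
    m0b <- m0_blood(mean(m0_truth[mask > 0]), acq$lambda)
    lapply(curves, fit_kinetic, acq = acq, m0b = m0b)
  }
  fits <- list(gm = fit_tissue(masks$gm, pool_gm_slices),
               wm = fit_tissue(masks$wm, FALSE))
  log_stage("fit", "fitted %d GM and %d WM curves over %d inversion times",
            length(fits$gm), length(fits$wm), length(ladder))

  to_json <- lapply(fits, function(tf) lapply(tf, function(f)
    list(estimate = as.list(f$estimate), std_error = as.list(f$std_error),
         rss = f$rss, converged = f$converged, degenerate = f$degenerate,
         n_points = f$n_points)))
  jsonlite::write_json(to_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "fit", "fits.json", config)
  invisible(fits)
}
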