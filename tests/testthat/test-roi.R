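ref <- cerebellum_cbf_reference()

test_that("ROI CBF is the (trimmed) masked mean", {
  d <- c(4, 4, 3)
  m <- array(TRUE, d)
  expect_equal(roi_cbf(array(42, d), m), 42)
  set.seed(3)
  v <- array(rnorm(prod(d), 50, 5), d)
  expect_equal(roi_cbf(v, m, trim_frac = 0), mean(v))
  v[1, 1, 1] <- NA
  expect_equal(roi_cbf(v, m), mean(v, na.rm = TRUE))
  expect_error(roi_cbf(v, array(FALSE, d)), "no finite")
})

test_that("GM/WM ratio reproduces printed per-subject values", {
  expect_equal(round(gm_wm_ratio(42.58, 29.56), 2), 1.44)
  expect_equal(round(gm_wm_ratio(51.57, 32.53), 2), 1.59)
  expect_equal(gm_wm_ratio(30, 30), 1)
  expect_error(gm_wm_ratio(40, 0), "positive")
})

test_that("percent C.V. uses the sample standard deviation and is scale invariant", {
  expect_equal(cv_percent(c(40, 50, 60)), 20)
  expect_equal(cv_percent(rep(4, 5)), 0)
  expect_equal(round(cv_percent(ref$fair_gm), 1), 11.6)
  set.seed(19)
  for (i in 1:50) {
    x <- rnorm(sample(2:30, 1), mean = 50, sd = 5)
    c1 <- cv_percent(x)
    expect_equal(cv_percent(x * runif(1, 0.1, 10)), c1, tolerance = 1e-10)
  }
  expect_error(cv_percent(5), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("interslice variability is the C.V. of slice mean CBF", {
  d <- c(4, 4, 3)
  m <- array(TRUE, d)
  expect_equal(interslice_cv(array(50, d), m), 0)
  v <- array(rep(c(40, 50, 60), each = 16), d)
  expect_equal(interslice_cv(v, m), 20)
  m1 <- array(FALSE, d); m1[, , 2] <- TRUE
  expect_error(interslice_cv(v, m1), "at least 2 slices")
})

test_that("interslice variability shrinks with voxels per slice on noisy maps", {
  cv_at <- function(npx, seed) {
    set.seed(seed)
    d <- c(npx, npx, 6)
    v <- array(rnorm(prod(d), 50, 10), d)
    interslice_cv(v, array(TRUE, d))
  }
  big <- mean(vapply(1:20, function(s) cv_at(24, s), numeric(1)))
  small <- mean(vapply(1:20, function(s) cv_at(6, s), numeric(1)))
  # slice means tighten roughly as 1 / sqrt(voxels per slice)
  expect_equal(small / big, sqrt(24^2 / 6^2), tolerance = 0.25)
})

test_that("spatial variability is the C.V. over masked voxels", {
  d <- c(2, 1, 1)
  expect_equal(spatial_cv(array(c(40, 60), d), array(TRUE, d)),
               100 * sqrt(200) / 50)
  expect_equal(spatial_cv(array(5, c(3, 3, 2)), array(TRUE, c(3, 3, 2))), 0)
  set.seed(23)
  v <- array(rnorm(64, 50, 7), c(4, 4, 4))
  m <- array(runif(64) > 0.4, c(4, 4, 4))
  expect_equal(spatial_cv(v, m), 100 * sd(v[m]) / mean(v[m]))
})

test_that("temporal variability is the C.V. of regional means over time", {
  d <- c(3, 3, 4)
  m <- array(TRUE, d)
  const <- array(2, c(d, 5))
  expect_equal(temporal_cv(const, m), 0)
  a <- 1.3
  alt <- array(rep(c(a, 3 * a), each = prod(d)), c(d, 2))
  expect_equal(temporal_cv(alt, m), 100 * sd(c(a, 3 * a)) / (2 * a))
  expect_equal(temporal_cv(alt, m), 70.71068, tolerance = 1e-6)
  expect_error(temporal_cv(const[, , , 1, drop = FALSE], m), "at least 2")
})

test_that("temporal variability of white-noise series matches 100/SNR", {
  set.seed(29)
  d <- c(10, 10, 4); nt <- 800; mu <- 5
  snr <- 10
  reg <- array(TRUE, d)
  nvox <- prod(c(10, 10, 4))
  # regional mean noise scaled so the per-time-point mean has sd mu/snr
  pwi <- array(rnorm(prod(d) * nt, mu, (mu / snr) * sqrt(nvox)), c(d, nt))
  expect_equal(temporal_cv(pwi, reg), 100 / snr, tolerance = 0.1 * 100 / snr)
})

test_that("group statistics reproduce the printed column summaries", {
  g <- group_stats(ref$fair_gm)
  expect_equal(g$mean, 43.78, tolerance = 0.01)
  expect_equal(g$sd, 5.06, tolerance = 0.01)
  w <- group_stats(ref$picore_wm)
  expect_equal(w$mean, 23.73, tolerance = 0.01)
  expect_equal(w$sd, 7.53, tolerance = 0.01)
  cst <- group_stats(rep(7, 4))
  expect_equal(cst$sd, 0)
  expect_error(group_stats(1), "at least 2")
})

test_that("paired t-test matches published two-tailed comparisons", {
  gm <- paired_ttest(ref$fair_gm, ref$picore_gm)
  expect_equal(gm$df, 4)
  expect_equal(round(gm$p, 3), 0.135)
  wm <- paired_ttest(ref$fair_wm, ref$picore_wm)
  expect_equal(round(wm$p, 3), 0.278)
  same <- paired_ttest(ref$fair_gm, ref$fair_gm)
  expect_true(same$degenerate)
  expect_error(paired_ttest(1:4, 1:5), "equal length")
})

test_that("the perfusion report reconstructs every derived table cell", {
  rep1 <- perfusion_report(ref, methods = c("fair", "picore"))
  f <- format_report(rep1)
  expect_equal(f$per_subject$fair_ratio, c(1.44, 1.57, 1.85, 1.57, 1.59))
  expect_equal(f$per_subject$picore_ratio, c(1.25, 1.54, 1.59, 2.28, 2.29))
  printed_mean <- c(fair_gm = 43.78, fair_wm = 27.56, fair_ratio = 1.60,
                    picore_gm = 40.35, picore_wm = 23.73, picore_ratio = 1.79)
  printed_sd <- c(fair_gm = 5.06, fair_wm = 4.49, fair_ratio = 0.15,
                  picore_gm = 8.52, picore_wm = 7.53, picore_ratio = 0.47)
  printed_cv <- c(fair_gm = 11.6, fair_wm = 16.3, fair_ratio = 9.4,
                  picore_gm = 21.1, picore_wm = 31.7, picore_ratio = 26.3)
  for (nm in names(printed_mean)) {
    expect_equal(rep1$group["mean", nm], printed_mean[[nm]], tolerance = 0.011)
    expect_equal(rep1$group["sd", nm], printed_sd[[nm]], tolerance = 0.011)
    expect_equal(rep1$group["cv", nm], printed_cv[[nm]], tolerance = 0.11)
  }
})
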