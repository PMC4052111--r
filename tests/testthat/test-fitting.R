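acq <- acq_params()

test_that("trimmed mean drops floor(trim * n) voxels per tail", {
  expect_equal(trimmed_mean(rep(3.5, 10), 0.05), 3.5)
  # 20 values, 5% per tail: one dropped at each end
  expect_equal(trimmed_mean(1:20, 0.05), mean(2:19))
  expect_equal(trimmed_mean(1:20, 0.05), 10.5)
  # 19 values: floor(0.95) = 0 dropped, plain mean
  expect_equal(trimmed_mean(1:19, 0.05), 10)
  expect_equal(trimmed_mean(c(5, 1, 9), 0), 5)
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:5, 0.5), "trim_frac")
})

test_that("trimmed mean equals the sort-and-slice oracle on random vectors", {
  set.seed(101)
  oracle <- function(x, f) {
    k <- floor(f * length(x))
    s <- sort(x)
    mean(s[seq(k + 1, length(x) - k)])
  }
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    f <- runif(1, 0, 0.49)
    x <- rnorm(n, sd = 10)
    expect_equal(trimmed_mean(x, f), oracle(x, f), tolerance = 1e-12)
  }
})

test_that("adjacent-slice averaging pools non-overlapping pairs", {
  mk <- function(slice, dm) roi_signal_curve(c(100, 400, 700), dm,
                                             rep(10L, 3), slice = slice)
  curves <- lapply(0:11, function(k) mk(k, rep(k + 1, 3)))
  names(curves) <- sprintf("slice_%d", 0:11)
  pooled <- average_adjacent_slices(curves)
  expect_length(pooled, 6)
  # linear-in-slice signal: pooled values are midpoints
  expect_equal(pooled[[1]]$dm, rep(1.5, 3))
  expect_equal(pooled[[6]]$dm, rep(11.5, 3))
  # effective inversion time is the mean of the two slices' times
  c0 <- mk(0, rep(1, 3)); c0$ti2_ms <- c(100, 400, 700)
  c1 <- mk(1, rep(1, 3)); c1$ti2_ms <- c(130, 430, 730)
  p <- average_adjacent_slices(list(slice_0 = c0, slice_1 = c1))
  expect_equal(p[[1]]$ti2_ms, c(115, 415, 715))
  # identical slice signals are unchanged by pooling
  expect_equal(p[[1]]$dm, rep(1, 3))
  # odd trailing slice is kept unpaired
  odd <- average_adjacent_slices(curves[1:5])
  expect_length(odd, 3)
  expect_equal(odd[[3]]$dm, rep(5, 3))
})

test_that("noiseless curves are recovered to optimizer precision", {
  truth <- kinetic_params(cbf = 50, att = 700, tau = 900,
                          m0b = m0_blood(1000, acq$lambda))
  curve <- simulate_roi_curves(truth, acq, n_curves = 1, noise_sd = 0)[[1]]
  # start away from the truth
  fit <- fit_kinetic(curve, acq, m0b = truth$m0b,
                     init = list(cbf = 30, att = 400, tau = 1500))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate["cbf"]), 50, tolerance = 1e-7)
  expect_equal(unname(fit$estimate["att"]), 700, tolerance = 1e-7)
  expect_equal(unname(fit$estimate["tau"]), 900, tolerance = 1e-7)
})

test_that("an all-zero curve is flagged degenerate with zero flow", {
  curve <- roi_signal_curve(c(50, seq(300, 3300, 300)), rep(0, 12),
                            rep(5L, 12))
  fit <- fit_kinetic(curve, acq, m0b = 1000)
  expect_true(fit$degenerate)
  expect_equal(unname(fit$estimate["cbf"]), 0)
})

test_that("fits are deterministic and respect bounds", {
  truth <- kinetic_params(cbf = 50, att = 700, tau = 900, m0b = 1111)
  curve <- simulate_roi_curves(truth, acq, n_curves = 1, noise_sd = 10,
                               seed = 9)[[1]]
  f1 <- fit_kinetic(curve, acq, m0b = 1111)
  f2 <- fit_kinetic(curve, acq, m0b = 1111)
  expect_identical(f1$estimate, f2$estimate)
  expect_true(all(f1$estimate >= c(cbf = 0, att = 0, tau = 100)))
  expect_true(all(f1$estimate <= c(cbf = 300, att = 3000, tau = 3000)))
})

test_that("a curve with too few inversion times is rejected", {
  curve <- roi_signal_curve(c(100, 400, 700, 1000), rep(1, 4), rep(5L, 4))
  expect_error(fit_kinetic(curve, acq, m0b = 1000), "at least 5")
})

test_that("Monte-Carlo recovery at simulator SNR is accurate and nearly unbiased", {
  truth <- kinetic_params(cbf = 50, att = 700, tau = 900,
                          m0b = m0_blood(1000, 0.9))
  curves <- simulate_roi_curves(truth, acq, n_curves = 120, seed = 77)
  est <- t(vapply(curves, function(cu)
    fit_kinetic(cu, acq, m0b = truth$m0b)$estimate, numeric(3)))
  expect_lt(median(abs(est[, "cbf"] - 50)) / 50, 0.05)
  expect_lt(median(abs(est[, "att"] - 700)) / 700, 0.10)
  expect_lt(median(abs(est[, "tau"] - 900)) / 900, 0.10)
  expect_lt(abs(mean(est[, "cbf"]) - 50) / 50, 0.05)
})

test_that("curves extracted from a noiseless simulated ladder match the model", {
  ph <- build_phantom(clean_spec())
  ladder <- ti2_ladder()
  pwi_list <- lapply(ladder, function(ti2) {
    acq_i <- acq_params(ti1 = min(800, ti2), ti2_base = ti2)
    s <- simulate_series(ph, acq_i, n_pairs = 2, noise_sd = 0,
                         artifacts = FALSE, truncate_bolus = FALSE)
    mean_pwi(pairwise_subtract(s$series))
  })
  masks <- build_tissue_masks(ph$gm_prob, ph$wm_prob, ph$roi)
  curves <- extract_roi_curves(pwi_list, ladder, masks$gm, acq)
  expect_gt(length(curves), 2)
  cu <- curves[[2]]
  kp <- kinetic_params(ph$spec$gm$cbf, ph$spec$gm$att, ph$spec$gm$tau,
                       m0_blood(ph$spec$gm$m0, acq$lambda))
  expect_equal(cu$dm, delta_m(cu$ti2_ms, kp, acq), tolerance = 1e-10)
})
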