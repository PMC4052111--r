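make_series <- function(ctrl, lab, n_pairs, acq = default_acq()) {
  d <- dim(ctrl)
  dat <- array(0, c(d, 2 * n_pairs))
  for (p in seq_len(n_pairs)) {
    dat[, , , 2 * p - 1] <- lab
    dat[, , , 2 * p] <- ctrl
  }
  asl_series(dat, rep(c("label", "control"), n_pairs), acq)
}

zero_trace <- function(n) motion_trace(numeric(n), numeric(n), numeric(n),
                                       numeric(n), numeric(n), numeric(n))

test_that("motion screening applies the 1 mm/1 deg and 2 mm/2 deg rules", {
  tr <- zero_trace(6)
  tr$tx <- c(0.5, 0, 1.5, 0, 0, 0)
  tr$rz <- c(0, 0.5, 0, 0, 2.5, 0)
  dec <- screen_motion(tr)
  expect_equal(as.character(dec[1:2]), c("keep", "keep"))
  expect_equal(as.character(dec[3]), "correct")
  # volume 5 exceeds 2 deg: excluded, and its pair partner (volume 6) too
  expect_equal(as.character(dec[5:6]), c("exclude", "exclude"))
})

test_that("exclusion propagates to the pair partner in either direction", {
  tr <- zero_trace(4)
  tr$ty[1] <- 3  # first volume of first pair
  dec <- screen_motion(tr)
  expect_equal(as.character(dec), c("exclude", "exclude", "keep", "keep"))
})

test_that("screening is monotone in its thresholds", {
  set.seed(5)
  tr <- zero_trace(40)
  tr$tx <- runif(40, 0, 3); tr$ry <- runif(40, 0, 3)
  surv <- function(mm, deg) {
    d <- screen_motion(tr, exclude_mm = mm, exclude_deg = deg)
    sum(d != "exclude")
  }
  expect_lte(surv(1.5, 1.5), surv(2, 2))
  expect_lte(surv(2, 2), surv(3, 3))
})

test_that("screening validates trace/series alignment", {
  expect_error(screen_motion(zero_trace(4), volume_labels = rep("label", 3)),
               "does not match")
})

test_that("pairwise subtraction is control minus label, one volume per surviving pair", {
  d <- c(4, 4, 3)
  ctrl <- array(100, d)
  dm <- array(seq_len(prod(d)) / 10, d)
  s <- make_series(ctrl, ctrl - dm, n_pairs = 5)
  out <- pairwise_subtract(s)
  expect_equal(dim(out$pwi)[4], 5)
  expect_equal(out$n_pairs_total, 5)
  expect_equal(out$n_pairs_excluded, 0)
  for (p in 1:5) expect_equal(out$pwi[, , , p], dm)
})

test_that("identical label and control volumes give all-zero differences", {
  ctrl <- array(7, c(3, 3, 2))
  out <- pairwise_subtract(make_series(ctrl, ctrl, n_pairs = 3))
  expect_true(all(out$pwi == 0))
})

test_that("excluded pairs are dropped and an all-excluded series errors", {
  ctrl <- array(1, c(3, 3, 2))
  s <- make_series(ctrl, ctrl, n_pairs = 4)
  dec <- factor(rep(c("exclude", "keep"), times = c(2, 6)),
                levels = c("keep", "correct", "exclude"))
  out <- pairwise_subtract(s, dec)
  expect_equal(dim(out$pwi)[4], 3)
  expect_equal(out$n_pairs_excluded, 1)
  all_ex <- factor(rep("exclude", 8), levels = levels(dec))
  expect_error(pairwise_subtract(s, all_ex), "no label/control pairs")
})

test_that("mean PWI is the voxelwise mean", {
  v <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  one <- array(v, c(3, 3, 2, 1))
  expect_equal(mean_pwi(one), v)
  two <- array(c(v, -v), c(3, 3, 2, 2))
  expect_equal(mean_pwi(two), array(0, c(3, 3, 2)))
})

test_that("mean PWI of noisy simulated volumes approaches truth at the 4 sigma / sqrt(N) level", {
  set.seed(21)
  d <- c(6, 6, 4); N <- 64; sigma <- 2
  truth <- array(runif(prod(d), 1, 3), d)
  pwi <- array(rnorm(prod(d) * N, mean = truth, sd = sigma), c(d, N))
  m <- mean_pwi(pwi)
  expect_true(all(abs(m - truth) < 4 * sigma / sqrt(N)))
})

test_that("mean M0 averages the pre and post images", {
  x <- array(runif(8), c(2, 2, 2))
  expect_equal(mean_m0(x, x), x)
  expect_equal(mean_m0(array(0, dim(x)), x), x / 2)
  expect_error(mean_m0(x, array(0, c(2, 2, 3))), "geometries")
})

test_that("averaging two independently noisy M0 images halves the variance", {
  set.seed(31)
  d <- c(8, 8, 4); sigma <- 3; reps <- 400
  errs <- replicate(reps, {
    m <- mean_m0(array(rnorm(prod(d), 100, sigma), d),
                 array(rnorm(prod(d), 100, sigma), d))
    m[1, 1, 1] - 100
  })
  expect_equal(var(errs), sigma^2 / 2, tolerance = 0.2)
})

test_that("subtract-then-average commutes with average-then-subtract", {
  set.seed(41)
  d <- c(5, 5, 3); n_pairs <- 8
  dat <- array(rnorm(prod(d) * 2 * n_pairs, 100, 5), c(d, 2 * n_pairs))
  s <- asl_series(dat, rep(c("label", "control"), n_pairs), default_acq())
  route1 <- mean_pwi(pairwise_subtract(s))
  ctrl_mean <- rowMeans(dat[, , , seq(2, 2 * n_pairs, 2)], dims = 3)
  lab_mean <- rowMeans(dat[, , , seq(1, 2 * n_pairs, 2)], dims = 3)
  expect_equal(route1, ctrl_mean - lab_mean, tolerance = 1e-10)
})

test_that("motion trace round-trips through TSV", {
  tr <- motion_trace(runif(6), runif(6), runif(6), runif(6), runif(6), runif(6))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_motion_trace(tr, path)
  back <- read_motion_trace(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})

test_that("series construction rejects broken label/control alternation", {
  dat <- array(0, c(2, 2, 2, 4))
  expect_error(asl_series(dat, c("label", "label", "control", "control"),
                          default_acq()), "alternate")
  expect_error(asl_series(dat[, , , 1:3], c("label", "control", "label"),
                          default_acq()), "pair 1:1")
})
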