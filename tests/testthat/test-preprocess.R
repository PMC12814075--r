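test_that("initial-volume trimming shortens the run and validates k", {
  m <- matrix(rnorm(8 * 500), 8, 500)
  run <- run_from_matrix(m, c(2, 2, 2))
  expect_equal(dim(drop_initial_volumes(run, 5)$data)[4], 495)
  expect_identical(drop_initial_volumes(run, 0), run)
  short <- run_from_matrix(m[, 1:4], c(2, 2, 2))
  expect_error(drop_initial_volumes(short, 5), "cannot drop")
})

test_that("framewise displacement follows the Power formula", {
  zero <- matrix(0, 20, 6)
  expect_equal(framewise_displacement(zero), rep(0, 19))
  shift <- zero
  shift[10:20, 1] <- 0.1 # one +0.1 mm translation step at frame 10
  fd <- framewise_displacement(shift)
  expect_equal(fd[9], 0.1)
  expect_equal(fd[-9], rep(0, 18))
  set.seed(4)
  rand <- matrix(rnorm(30 * 6, sd = 0.05), 30, 6)
  expect_equal(framewise_displacement(rand), oracle_fd(rand),
               tolerance = 1e-12)
  expect_error(framewise_displacement(rand[, 1:5]), "6 columns")
  # time-reversal symmetry: FD of the reversed table is the reversed series
  expect_equal(framewise_displacement(rand[30:1, ]),
               rev(framewise_displacement(rand)), tolerance = 1e-12)
})

test_that("DVARS is the RMS frame derivative over the mask", {
  grid <- c(3, 3, 2)
  mask <- array(TRUE, grid)
  const <- run_from_matrix(matrix(5, prod(grid), 10), grid)
  expect_equal(dvars(const, mask), rep(0, 9))
  step <- matrix(0, prod(grid), 10)
  step[1, 6:10] <- 2 # one voxel steps by +2 at frame 6
  run <- run_from_matrix(step, grid)
  dv <- dvars(run, mask)
  expect_equal(dv[5], 2 / sqrt(prod(grid)))
  expect_equal(dv[-5], rep(0, 8))
  set.seed(5)
  rnd <- run_from_matrix(matrix(rnorm(prod(grid) * 12), prod(grid), 12), grid)
  expect_equal(dvars(rnd, mask), oracle_dvars(rnd$data, mask),
               tolerance = 1e-12)
  expect_equal(dvars(rnd, mask), rev(dvars(
    run_from_matrix(matrix(rnd$data, prod(grid), 12)[, 12:1], grid), mask)),
    tolerance = 1e-12)
  expect_error(dvars(rnd, array(FALSE, grid)), "empty")
})

test_that("QC gate excludes only dual-threshold breaches under AND", {
  expect_false(qc_gate(0.25, 25)$included)
  expect_true(qc_gate(0, 0)$included)
  expect_warning(g <- qc_gate(0.25, 10), "retained")
  expect_true(g$included)
  expect_false(qc_gate(0.25, 10, rule = "or")$included)
})

test_that("nuisance regression removes confound signal and nothing else", {
  set.seed(6)
  t_len <- 50
  conf <- matrix(rnorm(t_len * 8), t_len, 8)
  grid <- c(2, 2, 2)
  # voxels that ARE confound columns regress to zero
  m <- t(conf)
  run <- run_from_matrix(m, grid)
  res <- regress_nuisance(run, conf)
  expect_lt(max(abs(res$data)), 1e-8)
  # signal orthogonal to the design survives up to mean removal
  x <- qr.resid(qr(cbind(1, conf)), rnorm(t_len))
  run2 <- run_from_matrix(matrix(x, 8, t_len, byrow = TRUE), grid)
  res2 <- regress_nuisance(run2, conf)
  expect_equal(as.vector(res2$data[1, 1, 1, ]), x, tolerance = 1e-8)
  # random case equals the normal-equations solution
  y <- matrix(rnorm(8 * t_len), 8, t_len)
  run3 <- run_from_matrix(y, grid)
  d <- cbind(1, conf)
  beta <- solve(t(d) %*% d, t(d) %*% t(y))
  expect_equal(matrix(regress_nuisance(run3, conf)$data, 8, t_len),
               y - t(d %*% beta), tolerance = 1e-8)
  # rank-deficient design warns and still returns residuals
  expect_warning(regress_nuisance(run3, cbind(conf, conf[, 1])),
                 "rank-deficient")
})

test_that("ideal band-pass keeps in-band tones and kills the rest", {
  t_len <- 200; tr <- 1.6
  tm <- (0:(t_len - 1)) * tr
  grid <- c(2, 2, 1)
  m <- rbind(sin(2 * pi * 0.05 * tm), # bin-aligned in-band
             sin(2 * pi * 0.2 * tm),  # bin-aligned out-of-band
             rep(3, t_len),           # DC
             rnorm(t_len))
  run <- run_from_matrix(m, grid, tr = tr)
  out <- bandpass(run)
  flat <- matrix(out$data, 4, t_len)
  expect_gt(max(abs(flat[1, ])) / max(abs(m[1, ])), 0.99)
  expect_lt(max(abs(flat[2, ])), 0.01 * max(abs(m[2, ])))
  expect_lt(max(abs(flat[3, ])), 1e-10)
  expect_error(bandpass(run, 0.01, 0.4), "Nyquist")
})

test_that("Gaussian smoothing has the requested FWHM and conserves mass", {
  grid <- c(15, 15, 15)
  delta <- array(0, c(grid, 2))
  delta[8, 8, 8, 1] <- 1
  run <- bold_run(delta, diag(4) * c(3, 3, 3, 1), 1.6)
  sm <- smooth_run(run, fwhm_mm = 6)
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-6)
  # recover sigma from the log-ratio of the profile (exact for a Gaussian)
  w0 <- sm$data[8, 8, 8, 1]; w1 <- sm$data[9, 8, 8, 1]
  sigma_vox <- sqrt(-1 / (2 * log(w1 / w0)))
  fwhm_est <- 2 * sqrt(2 * log(2)) * sigma_vox * 3
  expect_equal(fwhm_est, 6, tolerance = 0.05 * 6)
  # sub-half-voxel kernel is the identity
  tinyk <- smooth_run(run, fwhm_mm = 0.001)
  expect_equal(tinyk$data, run$data, tolerance = 1e-6)
  expect_error(smooth_run(run, fwhm_mm = 0), "positive")
})

test_that("tSNR is mean over sample SD with sensible degenerate behavior", {
  set.seed(8)
  x <- 100 + rnorm(495, sd = 10)
  expect_equal(tsnr(x), 10, tolerance = 1)
  expect_lt(abs(tsnr(rnorm(400))), 0.2)
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(tsnr(v), mean(v) / sd(v))
  expect_equal(round(tsnr(v), 3), 2.339)
  expect_warning(expect_equal(tsnr(rep(3, 10)), Inf), "infinite")
  expect_equal(tsnr(5 * x), tsnr(x), tolerance = 1e-12)
})

test_that("qc_report assembles series, means, tSNR and the gate decision", {
  s <- tiny_subject()
  atl <- tiny_atlas()
  rep <- qc_report(s$bold, s$confounds[, 1:6], atl$brain_mask,
                   rois = list(larger = s$lesions$larger_mask))
  expect_length(rep$fd_series, 199)
  expect_length(rep$dvars_series, 199)
  expect_equal(rep$mean_fd, mean(rep$fd_series))
  expect_gte(rep$tsnr_by_roi[["larger"]], 0)
  expect_type(rep$included, "logical")
})
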