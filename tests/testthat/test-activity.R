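test_that("ALFF scales with squared amplitude and zeroes constants", {
  t_len <- 200; tr <- 1.6
  tm <- (0:(t_len - 1)) * tr
  grid <- c(2, 2, 1)
  mask <- array(TRUE, grid)
  m <- rbind(sin(2 * pi * 0.05 * tm),
             2 * sin(2 * pi * 0.05 * tm),
             rep(7, t_len),
             rnorm(t_len))
  run <- run_from_matrix(m, grid, tr = tr)
  a <- alff(run, brain_mask = mask)
  expect_equal(a[2, 1, 1] / a[1, 1, 1], 4, tolerance = 0.01)
  expect_equal(a[1, 2, 1], 0) # constant voxel, DC excluded
  # white-noise voxel equals the direct DFT-sum oracle
  expect_equal(a[2, 2, 1], oracle_band_power(m[4, ], tr, c(0.01, 0.1)),
               tolerance = 1e-10)
})

test_that("fALFF is the in-band share of total power", {
  t_len <- 200; tr <- 1.6 # 0.05 and 0.2 Hz sit exactly on Fourier bins
  tm <- (0:(t_len - 1)) * tr
  grid <- c(2, 2, 1)
  mask <- array(TRUE, grid)
  inband <- sin(2 * pi * 0.05 * tm)
  outband <- sin(2 * pi * 0.2 * tm)
  two_tone <- 3 * inband + 2 * outband
  m <- rbind(inband, outband, two_tone, rnorm(t_len))
  run <- run_from_matrix(m, grid, tr = tr)
  f <- falff(run, brain_mask = mask)
  expect_gte(f[1, 1, 1], 0.99)
  expect_lte(f[2, 1, 1], 0.01)
  expect_equal(f[1, 2, 1], 9 / (9 + 4), tolerance = 1e-10)
  # random voxel equals the oracle band ratio
  expect_equal(f[2, 2, 1],
               oracle_band_power(m[4, ], tr, c(0.01, 0.1)) /
                 oracle_band_power(m[4, ], tr, c(1e-9, 0.25)),
               tolerance = 1e-10)
  expect_true(all(f[mask] >= 0 & f[mask] <= 1))
  expect_error(falff(run, total = c(0, 0.4), brain_mask = mask), "Nyquist")
})

test_that("ALFF on the band-passed run equals ALFF on the raw run", {
  set.seed(9)
  grid <- c(3, 3, 2)
  mask <- array(TRUE, grid)
  run <- run_from_matrix(matrix(rnorm(prod(grid) * 160), prod(grid), 160),
                         grid)
  filtered <- bandpass(run)
  expect_equal(alff(filtered, brain_mask = mask),
               alff(run, brain_mask = mask), tolerance = 1e-6)
})

test_that("ReHo is Kendall's W over the in-mask neighborhood", {
  grid <- c(5, 5, 5)
  mask <- array(TRUE, grid)
  t_len <- 40
  # identical series everywhere: perfect concordance at the center
  base <- sin(seq_len(t_len))
  m <- matrix(rep(base, each = prod(grid)), prod(grid), t_len)
  run <- run_from_matrix(m, grid)
  w <- reho(run, mask)
  expect_equal(w[3, 3, 3], 1, tolerance = 1e-12)
  # random field matches the brute-force oracle at interior + corner voxels
  set.seed(10)
  rnd <- matrix(rnorm(prod(grid) * t_len), prod(grid), t_len)
  run2 <- run_from_matrix(rnd, grid)
  w2 <- reho(run2, mask)
  arr <- run2$data
  neigh_series <- function(i, j, k) {
    out <- NULL
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5 && kk >= 1 && kk <= 5) {
        out <- rbind(out, arr[ii, jj, kk, ])
      }
    }
    out
  }
  expect_equal(w2[3, 3, 3], oracle_kendall_w(neigh_series(3, 3, 3)),
               tolerance = 1e-12)
  expect_equal(w2[1, 1, 1], oracle_kendall_w(neigh_series(1, 1, 1)),
               tolerance = 1e-12)
  expect_equal(w2[5, 3, 1], oracle_kendall_w(neigh_series(5, 3, 1)),
               tolerance = 1e-12)
  expect_true(all(w2[mask] > 0 & w2[mask] <= 1))
})

test_that("null ReHo concentrates near 1/K and grows with shared signal", {
  grid <- c(5, 5, 5)
  mask <- array(TRUE, grid)
  t_len <- 100
  set.seed(11)
  ws <- replicate(8, {
    run <- run_from_matrix(matrix(rnorm(prod(grid) * t_len),
                                  prod(grid), t_len), grid)
    reho(run, mask)[3, 3, 3]
  })
  expect_lt(abs(mean(ws) - 1 / 27), 0.015)
  # adding a common component to all neighbors raises W
  set.seed(12)
  noise <- matrix(rnorm(prod(grid) * t_len), prod(grid), t_len)
  common <- matrix(rep(rnorm(t_len), each = prod(grid)), prod(grid), t_len)
  w_lo <- reho(run_from_matrix(noise, grid), mask)[3, 3, 3]
  w_hi <- reho(run_from_matrix(noise + 2 * common, grid), mask)[3, 3, 3]
  expect_gt(w_hi, w_lo)
})

test_that("z-scoring standardizes the mask and is idempotent and affine-invariant", {
  grid <- c(4, 4, 2)
  mask <- array(TRUE, grid)
  set.seed(13)
  m <- array(rnorm(prod(grid), 5, 3), grid)
  z <- zscore_map(m, mask)
  expect_lt(abs(mean(z[mask])), 1e-6)
  expect_lt(abs(sd(z[mask]) - 1), 1e-6)
  expect_equal(zscore_map(z, mask), z, tolerance = 1e-12)
  expect_equal(zscore_map(3 * m + 7, mask), z, tolerance = 1e-12)
  expect_error(zscore_map(array(1, grid), mask), "zero variance")
})

test_that("ROI summaries are plain in-mask means", {
  grid <- c(4, 4, 2)
  mask <- array(FALSE, grid); mask[1:2, 1, 1] <- TRUE
  uniform <- array(3.5, grid)
  expect_equal(roi_summary(uniform, mask), 3.5)
  half <- array(0, grid); half[2, 1, 1] <- 2
  expect_equal(roi_summary(half, mask), 1)
  set.seed(14)
  rnd <- array(rnorm(prod(grid)), grid)
  expect_equal(roi_summary(rnd, mask), mean(rnd[which(mask)]),
               tolerance = 1e-12)
  expect_error(roi_summary(rnd, array(FALSE, grid)), "empty")
})

test_that("activity maps and ROI tables cover tumor and mirror control alike", {
  s <- tiny_subject()
  atl <- tiny_atlas()
  run <- regress_nuisance(drop_initial_volumes(s$bold, 5),
                          s$confounds[-(1:5), ])
  maps <- activity_maps(run, atl$brain_mask)
  bm <- atl$brain_mask
  for (nm in c("alff_z", "falff_z", "reho_z")) {
    expect_lt(abs(mean(maps[[nm]][bm])), 1e-6)
    expect_lt(abs(sd(maps[[nm]][bm]) - 1), 1e-6)
  }
  expect_true(all(maps$falff[bm] >= 0 & maps$falff[bm] <= 1))
  tab <- activity_roi_table(maps, s$lesions)
  expect_equal(nrow(tab), 12)
  expect_setequal(unique(tab$roi),
                  c("larger", "smaller", "larger_control", "smaller_control"))
  # mirror of the mirror control recovers the tumor summary exactly
  ctrl_of_ctrl <- mirror_mask(s$lesions$larger_control, atl)
  expect_equal(roi_summary(maps$alff, ctrl_of_ctrl),
               roi_summary(maps$alff, s$lesions$larger_mask))
})
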