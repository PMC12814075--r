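#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Integrated one-sided periodogram power of each voxel's time series over
#' the low-frequency band: for Fourier bins k with frequency in
#' `[band[1], band[2]]` (DC excluded), ALFF = sum 2 |X_k|^2 / T^2, so a
#' sinusoid of amplitude A contributes A^2 / 2 (its variance). Computed on
#' the nuisance-regressed, smoothed but temporally unfiltered run —
#' band-passing first would erase the spectral contrast the metric
#' quantifies.
#'
#' @param run a `bold_run` (unfiltered stage).
#' @param band low/high frequency bounds in Hz (default 0.01–0.1).
#' @param brain_mask logical 3D array; metric is 0 outside.
#' @return 3D map of ALFF values.
#' @export
alff <- function(run, band = c(0.01, 0.1), brain_mask) {
  band_power_map(run, band, brain_mask)
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of low-band power to total power over `total` (default 0–0.25 Hz,
#' DC bin excluded from both). Values lie in \[0, 1\]; a voxel with zero
#' total power maps to 0 with a warning.
#'
#' @inheritParams alff
#' @param total full analysis band in Hz (upper edge must not exceed
#'   Nyquist).
#' @return 3D map of fALFF values.
#' @export
falff <- function(run, band = c(0.01, 0.1), total = c(0, 0.25), brain_mask) {
  nyq <- 1 / (2 * run$tr_seconds)
  if (total[2] > nyq + 1e-12) {
    stop(sprintf("total band upper edge %.3f Hz exceeds Nyquist %.3f Hz",
                 total[2], nyq))
  }
  num <- band_power_map(run, band, brain_mask)
  den <- band_power_map(run, total, brain_mask)
  out <- array(0, dim(num))
  idx <- which(brain_mask)
  zero <- den[idx] == 0
  if (any(zero)) warning(sum(zero), " voxel(s) with zero total power; fALFF set to 0")
  ok <- idx[!zero]
  out[ok] <- num[ok] / den[ok]
  out
}

# shared periodogram band integral; DC always excluded
band_power_map <- function(run, band, brain_mask) {
  stopifnot(identical(dim(brain_mask), dim(run$data)[1:3]))
  t_len <- n_frames(run)
  freqs <- seq(0, t_len - 1) / (t_len * run$tr_seconds)
  half <- seq(2L, floor(t_len / 2) + 1L)
  bins <- half[freqs[half] >= band[1] - 1e-12 & freqs[half] <= band[2] + 1e-12]
  if (length(bins) == 0L) {
    stop("no Fourier bin falls inside the requested band")
  }
  idx <- which(brain_mask)
  m <- as_voxel_matrix(run)[idx, , drop = FALSE]
  spec <- mvfft(t(m))
  pw <- 2 * colSums(Mod(spec[bins, , drop = FALSE])^2) / t_len^2
  out <- array(0, dim(brain_mask))
  out[idx] <- pw
  out
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's coefficient of concordance W of each voxel's band-passed time
#' series with its 3x3x3 neighborhood (the voxel plus its 26 neighbors;
#' edge voxels use the in-mask subset, K < 27). With R_t the per-frame sum
#' of the K series' temporal ranks (average ranks on ties, no tie
#' correction), W = 12 sum_t (R_t - K(T+1)/2)^2 / (K^2 (T^3 - T)).
#' Voxels with fewer than 2 in-mask neighbors get `NA`.
#'
#' @param run a band-passed `bold_run`.
#' @param brain_mask logical 3D array.
#' @param neighborhood neighborhood size; only the 27-voxel cube is
#'   supported.
#' @return 3D map of W values in (0, 1\] (`NA` where undefined, 0 outside
#'   the mask).
#' @export
reho <- function(run, brain_mask, neighborhood = 27L) {
  stopifnot(identical(dim(brain_mask), dim(run$data)[1:3]))
  if (neighborhood != 27L) stop("only the 27-voxel neighborhood is supported")
  d <- dim(run$data)
  t_len <- d[4]
  idx <- which(brain_mask)
  m <- as_voxel_matrix(run)[idx, , drop = FALSE]
  ranks <- matrix(0, nrow(m), t_len)
  for (i in seq_len(nrow(m))) ranks[i, ] <- rank(m[i, ])

  rank_arr <- array(0, d)
  rk <- matrix(rank_arr, prod(d[1:3]), t_len)
  rk[idx, ] <- ranks
  dim(rk) <- d
  cnt <- array(0, d[1:3])
  cnt[idx] <- 1

  sum_r <- array(0, d)
  sum_k <- array(0, d[1:3])
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    sum_r <- sum_r + shift3(rk, c(ox, oy, oz))
    sum_k <- sum_k + shift3(cnt, c(ox, oy, oz))
  }
  k_map <- sum_k
  sr <- matrix(sum_r, prod(d[1:3]), t_len)[idx, , drop = FALSE]
  k_vec <- k_map[idx]
  dev <- sr - k_vec * (t_len + 1) / 2
  s_stat <- rowSums(dev^2)
  w <- 12 * s_stat / (k_vec^2 * (t_len^3 - t_len))
  w[k_vec < 2] <- NA_real_
  out <- array(0, d[1:3])
  out[idx] <- w
  out
}

# shift a 3D or 4D array by an integer 3-vector, zero fill
shift3 <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  rng <- function(n, o) {
    dst <- seq_len(n); src <- dst + o
    ok <- src >= 1L & src <= n
    list(dst = dst[ok], src = src[ok])
  }
  x <- rng(d[1], off[1]); y <- rng(d[2], off[2]); z <- rng(d[3], off[3])
  if (length(d) == 3L) {
    out[x$dst, y$dst, z$dst] <- a[x$src, y$src, z$src]
  } else {
    out[x$dst, y$dst, z$dst, ] <- a[x$src, y$src, z$src, , drop = FALSE]
  }
  out
}

#' Within-subject z-scoring of a metric map
#'
#' Centers and scales in-mask voxels to mean 0, SD 1 (sample SD);
#' background voxels are untouched.
#'
#' @param map 3D numeric array.
#' @param brain_mask logical 3D array with >= 2 in-mask voxels.
#' @return The z-scored map.
#' @export
zscore_map <- function(map, brain_mask) {
  idx <- which(brain_mask)
  if (length(idx) < 2) stop("need at least 2 in-mask voxels")
  v <- map[idx]
  s <- sd(v)
  if (s == 0) stop("zero variance within the mask; cannot z-score")
  map[idx] <- (v - mean(v)) / s
  map
}

#' Mean metric value within an ROI
#'
#' @param map 3D numeric array.
#' @param mask logical 3D array with non-empty overlap.
#' @return Scalar mean.
#' @export
roi_summary <- function(map, mask) {
  idx <- which(mask)
  if (length(idx) == 0) stop("empty ROI")
  mean(map[idx])
}

#' All three local activity maps, raw and z-scored
#'
#' ALFF and fALFF are computed on the unfiltered run, ReHo on its
#' band-passed counterpart (supplied or derived here); all maps are also
#' z-scored within the brain mask.
#'
#' @param run nuisance-regressed, smoothed, unfiltered `bold_run`.
#' @param brain_mask logical 3D array.
#' @param band low-frequency band (Hz).
#' @param total full fALFF band (Hz).
#' @param run_filtered optional pre-computed band-passed run.
#' @return Object of class `activity_maps`: list of `alff`, `falff`,
#'   `reho` and their `_z` variants plus the band definition.
#' @export
activity_maps <- function(run, brain_mask, band = c(0.01, 0.1),
                          total = c(0, 0.25), run_filtered = NULL) {
  if (is.null(run_filtered)) run_filtered <- bandpass(run, band[1], band[2])
  a <- alff(run, band, brain_mask)
  f <- falff(run, band, total, brain_mask)
  r <- reho(run_filtered, brain_mask)
  r_fill <- r
  r_fill[is.na(r_fill)] <- 0
  structure(list(alff = a, falff = f, reho = r,
                 alff_z = zscore_map(a, brain_mask),
                 falff_z = zscore_map(f, brain_mask),
                 reho_z = zscore_map(r_fill, brain_mask),
                 band = band, total = total),
            class = "activity_maps")
}

#' Per-ROI activity summaries for a lesion set
#'
#' @param maps an `activity_maps` object.
#' @param lesions a `lesion_set` (larger/smaller masks and their mirror
#'   controls).
#' @return Tibble with one row per ROI x metric: raw and z-scored means.
#' @export
activity_roi_table <- function(maps, lesions) {
  rois <- lesions[c("larger_mask", "smaller_mask", "larger_control",
                    "smaller_control")]
  names(rois) <- c("larger", "smaller", "larger_control", "smaller_control")
  purrr::map_dfr(names(rois), function(rn) {
    purrr::map_dfr(c("alff", "falff", "reho"), function(mt) {
      tibble::tibble(roi = rn, metric = mt,
                     raw = roi_summary(maps[[mt]], rois[[rn]]),
                     zscored = roi_summary(maps[[paste0(mt, "_z")]],
                                           rois[[rn]]))
    })
  })
}
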