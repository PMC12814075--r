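#' BOLD run container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world mm affine.
#' @param tr_seconds repetition time in seconds.
#' @return Object of class `bold_run`.
#' @export
bold_run <- function(data, affine, tr_seconds) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 2,
            is.matrix(affine), all(dim(affine) == c(4, 4)),
            abs(det(affine[1:3, 1:3])) > 0, tr_seconds > 0)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("bold_run:", paste(d[1:3], collapse = "x"), "voxels,", d[4],
      "frames @ TR", x$tr_seconds, "s\n")
  invisible(x)
}

n_frames <- function(run) dim(run$data)[4]

# voxels-by-time view of a run (rows follow column-major voxel order)
as_voxel_matrix <- function(run) {
  d <- dim(run$data)
  matrix(run$data, prod(d[1:3]), d[4])
}

with_data <- function(run, m, grid = dim(run$data)[1:3]) {
  dim(m) <- c(grid, ncol(m))
  run$data <- m
  run
}

#' Discard initial volumes
#'
#' Drops the first `k` frames (magnetic-stabilization dummies). Callers are
#' responsible for trimming confound tables to match.
#'
#' @param run a `bold_run`.
#' @param k number of leading frames to drop (default 5).
#' @return The shortened `bold_run`.
#' @export
drop_initial_volumes <- function(run, k = 5L) {
  t_len <- n_frames(run)
  if (k >= t_len) stop("cannot drop ", k, " volumes from a run of ", t_len)
  if (k == 0L) return(run)
  run$data <- run$data[, , , -seq_len(k), drop = FALSE]
  run
}

#' Framewise displacement (Power formulation)
#'
#' FD_t = sum of absolute frame-to-frame translation differences (mm) plus
#' the rotation differences (rad) converted to arc length on a
#' `radius_mm` sphere.
#'
#' @param motion matrix/data frame with 6 columns: trans_x/y/z in mm,
#'   rot_x/y/z in radians.
#' @param radius_mm head-radius used to convert rotations (default 50).
#' @return Numeric series of length `nrow(motion) - 1`.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("motion must have 6 columns (3 translations mm, 3 rotations rad)")
  }
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' DVARS: RMS of the frame-to-frame signal derivative over brain voxels
#'
#' Unstandardized, in native signal units (the exclusion threshold of 20 is
#' interpreted on raw units).
#'
#' @param run a `bold_run`.
#' @param brain_mask logical 3D array selecting brain voxels.
#' @return Series of length t - 1.
#' @export
dvars <- function(run, brain_mask) {
  stopifnot(identical(dim(brain_mask), dim(run$data)[1:3]))
  if (!any(brain_mask)) stop("brain mask is empty")
  m <- as_voxel_matrix(run)[which(brain_mask), , drop = FALSE]
  diffs <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  sqrt(colMeans(diffs^2))
}

#' Motion/variance inclusion gate
#'
#' A subject is excluded when mean FD exceeds `fd_max` AND mean DVARS
#' exceeds `dvars_max` (the conjunction matches the excluded patients of
#' the motivating cohort, which breached both); `rule = "or"` switches to
#' either-threshold exclusion. A single-threshold breach under the
#' conjunctive rule is flagged with a warning.
#'
#' @param mean_fd,mean_dvars per-subject means of the two series.
#' @param fd_max,dvars_max thresholds (defaults 0.2 mm and 20).
#' @param rule `"and"` (default) or `"or"`.
#' @return List with `included` (logical) and `reason` (character).
#' @export
qc_gate <- function(mean_fd, mean_dvars, fd_max = 0.2, dvars_max = 20,
                    rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(is.finite(mean_fd), is.finite(mean_dvars))
  fd_bad <- mean_fd > fd_max
  dv_bad <- mean_dvars > dvars_max
  excluded <- if (rule == "and") fd_bad && dv_bad else fd_bad || dv_bad
  if (!excluded && rule == "and" && (fd_bad || dv_bad)) {
    warning("single QC threshold breached (", if (fd_bad) "FD" else "DVARS",
            "); subject retained under the conjunctive rule")
  }
  reason <- if (!excluded) "passed" else {
    paste0(c(if (fd_bad) sprintf("mean FD %.3f > %.3f", mean_fd, fd_max),
             if (dv_bad) sprintf("mean DVARS %.2f > %.2f", mean_dvars,
                                 dvars_max)), collapse = "; ")
  }
  list(included = !excluded, reason = reason)
}

#' Nuisance regression
#'
#' Removes, per voxel, the least-squares projection onto an intercept plus
#' the supplied confound columns (six motion parameters, WM and CSF
#' signals). A rank-deficient design triggers a warning and a
#' pseudoinverse (SVD) fit.
#'
#' @param run a `bold_run`.
#' @param confounds data frame/matrix with one row per frame.
#' @return `bold_run` of residuals.
#' @export
regress_nuisance <- function(run, confounds) {
  x <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(x) != n_frames(run)) {
    stop("confound rows (", nrow(x), ") must equal run length (",
         n_frames(run), ")")
  }
  m <- t(as_voxel_matrix(run)) # time x voxels
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient confound design; using pseudoinverse fit")
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% m / sv$d[pos])
    res <- m - x %*% beta
  } else {
    res <- qr.resid(qx, m)
  }
  with_data(run, t(res))
}

#' Ideal band-pass temporal filter
#'
#' Zeroes all Fourier bins whose frequency falls outside `[low, high]`
#' (including DC), leaving in-band bins untouched — an ideal rectangular
#' frequency response.
#'
#' @param run a `bold_run`.
#' @param low,high band edges in Hz (defaults 0.01 and 0.1).
#' @return Filtered `bold_run`.
#' @export
bandpass <- function(run, low = 0.01, high = 0.1) {
  t_len <- n_frames(run)
  nyq <- 1 / (2 * run$tr_seconds)
  if (high > nyq + 1e-12) {
    stop(sprintf("upper band edge %.3f Hz exceeds Nyquist %.3f Hz", high, nyq))
  }
  if (low >= high) stop("band must satisfy low < high")
  freqs <- seq(0, t_len - 1) / (t_len * run$tr_seconds)
  f_fold <- pmin(freqs, 1 / run$tr_seconds - freqs) # two-sided spectrum
  keep <- f_fold >= low - 1e-12 & f_fold <= high + 1e-12
  m <- t(as_voxel_matrix(run)) # time x voxels
  spec <- mvfft(m)
  spec[!keep, ] <- 0
  with_data(run, t(Re(mvfft(spec, inverse = TRUE)) / t_len))
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable Gaussian convolution with
#' sigma = fwhm / (2 sqrt(2 ln 2)) converted to voxels (isotropic voxels
#' required); zero padding at the grid edge. A kernel narrower than ~1e-3
#' voxels is treated as the identity.
#'
#' @param run a `bold_run`.
#' @param fwhm_mm kernel full width at half maximum in mm (default 5).
#' @return Smoothed `bold_run`.
#' @export
smooth_run <- function(run, fwhm_mm = 5) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  vs <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  if (max(vs) - min(vs) > 1e-6) stop("smoothing requires isotropic voxels")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs[1]
  if (sigma < 1e-3) return(run)
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  a <- run$data
  for (axis in 1:3) a <- convolve_axis(a, w, axis)
  run$data <- a
  run
}

# zero-padded 1D convolution of a 4D array along a spatial axis
convolve_axis <- function(a, w, axis) {
  d <- dim(a)
  r <- (length(w) - 1L) / 2L
  out <- array(0, d)
  n <- d[axis]
  for (o in seq(-r, r)) {
    wt <- w[o + r + 1L]
    dst <- seq_len(n)
    src <- dst + o
    ok <- src >= 1L & src <= n
    dst <- dst[ok]
    src <- src[ok]
    if (axis == 1L) {
      out[dst, , , ] <- out[dst, , , , drop = FALSE] +
        wt * a[src, , , , drop = FALSE]
    } else if (axis == 2L) {
      out[, dst, , ] <- out[, dst, , , drop = FALSE] +
        wt * a[, src, , , drop = FALSE]
    } else {
      out[, , dst, ] <- out[, , dst, , drop = FALSE] +
        wt * a[, , src, , drop = FALSE]
    }
  }
  out
}

#' Temporal signal-to-noise ratio
#'
#' Mean of a time series divided by its sample SD (n - 1 denominator). A
#' constant series yields +Inf with a warning.
#'
#' @param series numeric vector, length >= 2.
#' @return Scalar ratio.
#' @export
tsnr <- function(series) {
  stopifnot(length(series) >= 2)
  s <- sd(series)
  if (s == 0) {
    warning("zero temporal SD; tSNR is infinite")
    return(Inf)
  }
  mean(series) / s
}

#' QC report for one run
#'
#' Computes FD and DVARS series and means, per-ROI tSNR, and the inclusion
#' decision.
#'
#' @param run the raw `bold_run` (before trimming).
#' @param motion 6-column motion table aligned with `run`.
#' @param brain_mask logical 3D array.
#' @param rois named list of logical masks for tSNR summaries.
#' @inheritParams qc_gate
#' @return List of class `qc_report`.
#' @export
qc_report <- function(run, motion, brain_mask, rois = list(),
                      fd_max = 0.2, dvars_max = 20, rule = "and") {
  fd <- framewise_displacement(motion)
  dv <- dvars(run, brain_mask)
  gate <- qc_gate(mean(fd), mean(dv), fd_max, dvars_max, rule)
  ts <- vapply(rois, function(m) tsnr(roi_series(run, m)), numeric(1))
  structure(list(fd_series = fd, dvars_series = dv, mean_fd = mean(fd),
                 mean_dvars = mean(dv), tsnr_by_roi = ts,
                 included = gate$included, reason = gate$reason),
            class = "qc_report")
}

#' Full preprocessing chain
#'
#' Applies, in order: initial-volume trimming, nuisance regression,
#' spatial smoothing, and (optionally) temporal band-pass filtering —
#' the order the emulated pipeline describes. ALFF/fALFF are defined on
#' the unfiltered stage, so the band-pass is switchable.
#'
#' @param run a `bold_run`.
#' @param confounds confound table aligned with the untrimmed run.
#' @param drop_first frames to discard (default 5).
#' @param fwhm_mm smoothing kernel FWHM; `NULL` skips smoothing.
#' @param band band-pass edges in Hz; `NULL` skips filtering.
#' @return Preprocessed `bold_run`.
#' @export
preprocess_run <- function(run, confounds, drop_first = 5L, fwhm_mm = 5,
                           band = c(0.01, 0.1)) {
  run <- drop_initial_volumes(run, drop_first)
  confounds <- as.matrix(confounds)
  if (drop_first > 0) {
    confounds <- confounds[-seq_len(drop_first), , drop = FALSE]
  }
  run <- regress_nuisance(run, confounds)
  if (!is.null(fwhm_mm)) run <- smooth_run(run, fwhm_mm)
  if (!is.null(band)) run <- bandpass(run, band[1], band[2])
  run
}
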