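#' Simulation parameters for a multifocal-glioma BOLD cohort
#'
#' Bundles and validates the generator's knobs. The defaults are the study
#' conditions of the cohort the package emulates: 24 subjects, a 400-parcel
#' cortex, TR 1.6 s, 500 volumes, and paired lesions whose mean volumes keep
#' the 78.6 : 24.9 larger-to-smaller ratio of the clinical cohort (the
#' simulator works in voxels, so only the ratio is carried over; the larger
#' lesion mean defaults to 3% of brain voxels).
#'
#' @param n_subjects number of simulated patients.
#' @param n_parcels even parcel count for the companion atlas.
#' @param grid_shape voxel grid dimensions (x even).
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes number of BOLD frames (> 5).
#' @param kappa_larger,kappa_smaller tumor-cortex coupling of the larger and
#'   smaller lesion, each in \[0, 1). The realized expected tumor-parcel
#'   correlation is `kappa * global_loading`.
#' @param vol_mean_larger,vol_mean_smaller mean lesion volumes in voxels;
#'   `NULL` derives them from the grid (3% of brain voxels for the larger,
#'   scaled by 24.9/78.6 for the smaller).
#' @param ar1_rho lag-1 autocorrelation of the voxel noise.
#' @param noise_sd marginal SD of the voxel noise (latent signals have unit
#'   SD, so this is an inverse SNR dial).
#' @param confound_weight amplitude of the WM/CSF confound leakage added to
#'   every brain voxel.
#' @param band low/high frequency bounds (Hz) of the latent signals.
#' @param global_loading,network_loading loadings of the shared cortical
#'   factor and the within-network factor in each parcel's latent signal;
#'   their squares plus the parcel-specific share sum to 1.
#' @param baseline additive mean BOLD level of brain voxels (gives tSNR its
#'   usual scale).
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 24L, n_parcels = 400L,
                       grid_shape = c(64L, 76L, 64L), tr_seconds = 1.6,
                       n_volumes = 500L, kappa_larger = 0.6,
                       kappa_smaller = 0.2, vol_mean_larger = NULL,
                       vol_mean_smaller = NULL, ar1_rho = 0.3, noise_sd = 1,
                       confound_weight = 0.15, band = c(0.01, 0.1),
                       global_loading = 0.3,
                       network_loading = sqrt(0.15), baseline = 100,
                       seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            n_parcels = as.integer(n_parcels),
            grid_shape = as.integer(grid_shape), tr_seconds = tr_seconds,
            n_volumes = as.integer(n_volumes), kappa_larger = kappa_larger,
            kappa_smaller = kappa_smaller, vol_mean_larger = vol_mean_larger,
            vol_mean_smaller = vol_mean_smaller, ar1_rho = ar1_rho,
            noise_sd = noise_sd, confound_weight = confound_weight,
            band = band, global_loading = global_loading,
            network_loading = network_loading, baseline = baseline,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$n_subjects >= 1, p$n_parcels >= 2, p$n_volumes > 5,
            p$tr_seconds > 0, p$ar1_rho >= 0, p$ar1_rho < 1,
            p$noise_sd >= 0, length(p$band) == 2, p$band[1] < p$band[2])
  if (p$kappa_larger < 0 || p$kappa_larger >= 1 ||
      p$kappa_smaller < 0 || p$kappa_smaller >= 1) {
    stop("kappa values must lie in [0, 1)")
  }
  if (!is.null(p$vol_mean_larger) || !is.null(p$vol_mean_smaller)) {
    if (is.null(p$vol_mean_larger) || is.null(p$vol_mean_smaller) ||
        !(p$vol_mean_larger > p$vol_mean_smaller &&
          p$vol_mean_smaller > 0)) {
      stop("lesion volume means must satisfy larger > smaller > 0")
    }
  }
  if (p$global_loading^2 + p$network_loading^2 >= 1) {
    stop("global and network loadings must leave positive parcel-specific variance")
  }
  invisible(p)
}

# deterministic per-subject seed derived from the master seed
subject_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + as.double(i) * 7919) %% 2147483629) + 1L
}

#' Band-limited unit-variance Gaussian series
#'
#' Draws each series in the frequency domain (iid complex-normal
#' coefficients on the Fourier bins inside the band, zero elsewhere) and
#' inverse-transforms, so all latent power sits in the band by
#' construction. Columns are standardized to zero mean, unit sample SD.
#'
#' @param n_series number of independent series (columns).
#' @param n_volumes series length.
#' @param tr_seconds sampling interval (s).
#' @param band c(low, high) in Hz.
#' @return `n_volumes` x `n_series` matrix.
#' @keywords internal
band_limited_series <- function(n_series, n_volumes, tr_seconds,
                                band = c(0.01, 0.1)) {
  t_len <- n_volumes
  freqs <- seq(0, t_len - 1) / (t_len * tr_seconds)
  half <- seq(2L, floor(t_len / 2) + 1L) # positive-frequency bins (1-based)
  in_band <- half[freqs[half] >= band[1] - 1e-12 &
                    freqs[half] <= band[2] + 1e-12]
  if (length(in_band) == 0L) {
    stop("no Fourier bin falls inside the requested band; lengthen the run")
  }
  out <- matrix(0, t_len, n_series)
  for (j in seq_len(n_series)) {
    spec <- complex(real = rep(0, t_len), imaginary = rep(0, t_len))
    spec[in_band] <- complex(real = rnorm(length(in_band)),
                             imaginary = rnorm(length(in_band)))
    # Hermitian symmetry for a real signal
    mirror <- t_len - in_band + 2L
    keep <- mirror >= 1 & mirror <= t_len & mirror != in_band
    spec[mirror[keep]] <- Conj(spec[in_band][keep])
    x <- Re(fft(spec, inverse = TRUE)) / t_len
    out[, j] <- (x - mean(x)) / sd(x)
  }
  out
}

place_spheroid <- function(target_voxels, atlas, forbidden, max_tries = 200L) {
  grid <- dim(atlas$labels)
  nx <- grid[1]
  left_brain <- atlas$brain_mask
  left_brain[(nx / 2 + 1):nx, , ] <- FALSE
  cand <- which(left_brain)
  r0 <- (3 * target_voxels / (4 * pi))^(1 / 3)
  for (try in seq_len(max_tries)) {
    ctr <- arrayInd(sample(cand, 1L), grid)
    axes <- pmax(1, r0 * runif(3, 0.85, 1.15))
    lo <- pmax(1, floor(ctr - axes)); hi <- pmin(grid, ceiling(ctr + axes))
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx <- ((ii - ctr[1]) / axes[1])^2
    dy <- ((jj - ctr[2]) / axes[2])^2
    dz <- ((kk - ctr[3]) / axes[3])^2
    inside <- outer(outer(dx, dy, `+`), dz, `+`) <= 1
    mask <- array(FALSE, grid)
    mask[ii, jj, kk] <- inside
    # must sit wholly in the left-hemisphere brain and clear of other lesions
    if (!all(left_brain[mask])) next
    if (!is.null(forbidden) && any(forbidden[mask])) next
    if (sum(mask) < max(4, 0.5 * target_voxels)) next
    return(mask)
  }
  stop("lesion placement failed after ", max_tries, " attempts")
}

#' Simulate one multifocal-glioma subject
#'
#' Generates a 4D BOLD run on the atlas grid: band-limited latent signals
#' for every parcel (a shared cortical factor + a within-network factor +
#' a parcel-specific component) and for each of two tumors (coupled to the
#' shared cortical factor with strength kappa), broadcast to member voxels,
#' plus WM/CSF confound leakage, a constant brain baseline, and AR(1)+white
#' voxel noise. Two spheroidal lesions (larger/smaller, volumes drawn
#' around the configured means) are placed off-midline in the left
#' hemisphere; their exact x-mirrors serve as contralateral controls. The
#' ground truth used (couplings, volumes, loadings) is recorded.
#'
#' @param atlas a `parcel_atlas` (see [make_atlas()]).
#' @param params a `sim_params` object.
#' @param seed integer RNG seed for this subject.
#' @return An object of class `glioma_subject`: list with `bold` (a
#'   `bold_run`), `lesions` (a `lesion_set` with the four masks and volumes
#'   in mm^3), `confounds` (tibble: trans_x/y/z mm, rot_x/y/z rad, wm, csf)
#'   and `truth`.
#' @export
simulate_subject <- function(atlas, params, seed) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  validate_sim_params(params)
  set.seed(as.integer(seed))
  grid <- dim(atlas$labels)
  t_len <- params$n_volumes
  p_n <- atlas$n_parcels
  n_net <- max(atlas$network_of)

  vox_vol_mm3 <- abs(det(atlas$affine[1:3, 1:3]))
  n_brain <- sum(atlas$brain_mask)
  vml <- params$vol_mean_larger %||% max(8, round(0.03 * n_brain))
  vms <- params$vol_mean_smaller %||% max(4, round(vml * 24.9 / 78.6))
  # coefficients of variation carried over from the clinical volume table
  draw_vol <- function(mu, cv) max(4, round(rnorm(1, mu, cv * mu)))
  v_larger <- draw_vol(vml, 33.7 / 78.6)
  v_smaller <- draw_vol(vms, 15.3 / 24.9)
  for (k in seq_len(20)) {
    if (v_larger > v_smaller) break
    v_smaller <- draw_vol(vms, 15.3 / 24.9)
  }
  if (v_larger <= v_smaller) v_smaller <- max(4, v_larger - 1)

  larger <- place_spheroid(v_larger, atlas, forbidden = NULL)
  smaller <- place_spheroid(v_smaller, atlas, forbidden = larger)
  larger_control <- mirror_mask(larger, atlas)
  smaller_control <- mirror_mask(smaller, atlas)

  # latent signals: 1 global + n_net network + P parcel + 2 tumor series
  lat <- band_limited_series(1 + n_net + p_n + 2, t_len, params$tr_seconds,
                             params$band)
  g_global <- lat[, 1]
  g_net <- lat[, 1 + seq_len(n_net), drop = FALSE]
  g_parc <- lat[, 1 + n_net + seq_len(p_n), drop = FALSE]
  g_tum <- lat[, 1 + n_net + p_n + 1:2, drop = FALSE]
  a <- params$global_loading; b <- params$network_loading
  d <- sqrt(1 - a^2 - b^2)
  parcel_sig <- a * g_global + b * g_net[, atlas$network_of, drop = FALSE] +
    d * g_parc
  kap <- c(params$kappa_larger, params$kappa_smaller)
  tumor_sig <- sweep(matrix(g_global, t_len, 2), 2, kap, `*`) +
    sweep(g_tum, 2, sqrt(1 - kap^2), `*`)

  # confounds: slow random-walk motion, AR(1)-like WM/CSF series
  motion <- vapply(c(0.005, 0.005, 0.005, 5e-4, 5e-4, 5e-4), function(s) {
    cumsum(rnorm(t_len, 0, s))
  }, numeric(t_len))
  wm <- as.numeric(scale(ar1_series(t_len, 0.8)))
  csf <- as.numeric(scale(ar1_series(t_len, 0.8)))
  confounds <- tibble::tibble(trans_x = motion[, 1], trans_y = motion[, 2],
                              trans_z = motion[, 3], rot_x = motion[, 4],
                              rot_y = motion[, 5], rot_z = motion[, 6],
                              wm = wm, csf = csf)

  n_vox <- prod(grid)
  brain_idx <- which(atlas$brain_mask)
  nb <- length(brain_idx)
  noise <- matrix(rnorm(nb * t_len, 0, params$noise_sd *
                          sqrt(1 - params$ar1_rho^2)), nb, t_len)
  if (params$ar1_rho > 0) {
    for (t in 2:t_len) {
      noise[, t] <- noise[, t] + params$ar1_rho * noise[, t - 1]
    }
  }
  lab_brain <- atlas$labels[brain_idx]
  sig <- t(parcel_sig[, lab_brain, drop = FALSE]) # brain voxels x T
  tum_idx_l <- which(larger[brain_idx]); tum_idx_s <- which(smaller[brain_idx])
  sig[tum_idx_l, ] <- matrix(tumor_sig[, 1], length(tum_idx_l), t_len,
                             byrow = TRUE)
  sig[tum_idx_s, ] <- matrix(tumor_sig[, 2], length(tum_idx_s), t_len,
                             byrow = TRUE)
  leak <- params$confound_weight * (wm + csf) / sqrt(2)
  bold <- matrix(0, n_vox, t_len) # background (air) carries no signal
  bold[brain_idx, ] <- noise + sig + params$baseline +
    matrix(leak, nb, t_len, byrow = TRUE)
  dim(bold) <- c(grid, t_len)

  run <- bold_run(bold, atlas$affine, params$tr_seconds)
  lesions <- structure(
    list(larger_mask = larger, smaller_mask = smaller,
         larger_control = larger_control, smaller_control = smaller_control,
         volumes_mm3 = c(larger = sum(larger) * vox_vol_mm3,
                         smaller = sum(smaller) * vox_vol_mm3)),
    class = "lesion_set"
  )
  truth <- list(kappa_larger = params$kappa_larger,
                kappa_smaller = params$kappa_smaller,
                volume_voxels = c(larger = sum(larger), smaller = sum(smaller)),
                global_loading = a, network_loading = b, seed = as.integer(seed))
  structure(list(bold = run, lesions = lesions, confounds = confounds,
                 truth = truth),
            class = "glioma_subject")
}

ar1_series <- function(t_len, rho) {
  x <- rnorm(t_len, 0, sqrt(1 - rho^2))
  for (t in 2:t_len) x[t] <- x[t] + rho * x[t - 1]
  x
}

#' Simulate a full cohort
#'
#' Builds the companion atlas (unless one is supplied) and simulates
#' `params$n_subjects` subjects with per-subject seeds derived
#' deterministically from the master seed, so cohorts are bit-reproducible
#' and subjects could be generated in parallel without order effects.
#'
#' @param params a `sim_params` object.
#' @param atlas optional pre-built `parcel_atlas`.
#' @return Object of class `glioma_cohort`: list with `atlas`, `subjects`
#'   (list of `glioma_subject`) and `params`.
#' @export
simulate_cohort <- function(params, atlas = NULL) {
  validate_sim_params(params)
  if (is.null(atlas)) {
    atlas <- make_atlas(params$n_parcels, params$grid_shape,
                        seed = params$seed)
  }
  subjects <- lapply(seq_len(params$n_subjects), function(i) {
    simulate_subject(atlas, params, seed = subject_seed(params$seed, i))
  })
  structure(list(atlas = atlas, subjects = subjects, params = params),
            class = "glioma_cohort")
}

#' @export
print.glioma_cohort <- function(x, ...) {
  cat("glioma_cohort:", length(x$subjects), "subjects,",
      x$atlas$n_parcels, "parcels,", x$params$n_volumes, "volumes @ TR",
      x$params$tr_seconds, "s\n")
  invisible(x)
}
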