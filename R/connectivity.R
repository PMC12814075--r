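#' Mean time series of an ROI
#'
#' @param run a `bold_run`.
#' @param mask logical 3D array.
#' @return Numeric series (length = frames).
#' @export
roi_series <- function(run, mask) {
  idx <- which(mask)
  if (length(idx) == 0) stop("empty ROI")
  colMeans(as_voxel_matrix(run)[idx, , drop = FALSE])
}

#' Parcel-mean time series with tumor exclusion
#'
#' Averages each parcel's member voxels after removing every voxel covered
#' by an exclusion mask (the tumor masks are subtracted from the
#' parcellation so tumor signal never leaks into cortical parcels). A
#' parcel emptied by the exclusion yields an `NA` row and is reported in
#' the `"empty"` attribute.
#'
#' @param run a `bold_run` on the atlas grid.
#' @param atlas a `parcel_atlas`.
#' @param exclusion_masks list of logical 3D arrays to subtract.
#' @return `n_parcels` x T matrix; attribute `"empty"` holds the indices
#'   of parcels without surviving voxels.
#' @export
parcel_series <- function(run, atlas, exclusion_masks = list()) {
  stopifnot(identical(dim(run$data)[1:3], dim(atlas$labels)))
  lab <- atlas$labels
  for (m in exclusion_masks) {
    stopifnot(identical(dim(m), dim(lab)))
    lab[m] <- 0L
  }
  sel <- which(lab > 0L)
  if (length(sel) == 0L) stop("exclusion removed every labeled voxel")
  m <- as_voxel_matrix(run)[sel, , drop = FALSE]
  sums <- rowsum(m, lab[sel])
  counts <- tabulate(lab[sel], nbins = atlas$n_parcels)
  out <- matrix(NA_real_, atlas$n_parcels, n_frames(run))
  present <- as.integer(rownames(sums))
  out[present, ] <- sums / counts[present]
  empty <- which(counts == 0L)
  if (length(empty)) {
    attr(out, "empty") <- empty
  } else {
    attr(out, "empty") <- integer(0)
  }
  out
}

#' Seed-to-parcel functional connectivity
#'
#' Pearson correlation of the seed series with each parcel series, Fisher
#' z-transform (|r| capped just below 1 to keep atanh finite), and
#' two-sided p-values from t = r sqrt((T-2)/(1-r^2)) on T-2 df. Parcels
#' with missing (`NA`) series or zero variance receive `NA` sentinels and
#' are never selected. Bonferroni parcel selection divides `alpha` by the
#' usable parcel count by default (`n_comparisons` overrides, e.g. to the
#' full atlas size).
#'
#' @param seed_series numeric series (length T >= 4).
#' @param parcel_mat parcels x T matrix (rows may be `NA`).
#' @param alpha familywise significance level (default 0.05).
#' @param n_comparisons Bonferroni denominator; defaults to the number of
#'   usable parcels.
#' @return Object of class `seed_fc`: tibble `table` (parcel, r, z, p,
#'   significant) plus scalars `mean_fc` (mean z over usable parcels),
#'   `n_sig`, `sig_set`, `n_usable`, `alpha`.
#' @export
seed_fc <- function(seed_series, parcel_mat, alpha = 0.05,
                    n_comparisons = NULL) {
  t_len <- length(seed_series)
  stopifnot(ncol(parcel_mat) == t_len, t_len >= 4)
  if (sd(seed_series) == 0) stop("seed series has zero variance")
  p_n <- nrow(parcel_mat)
  pv <- rep(NA_real_, p_n)
  r <- rep(NA_real_, p_n)
  usable <- rowSums(is.na(parcel_mat)) == 0
  usable[usable] <- apply(parcel_mat[usable, , drop = FALSE], 1, sd) > 0
  if (any(usable)) {
    r[usable] <- as.vector(cor(seed_series,
                               t(parcel_mat[usable, , drop = FALSE])))
  }
  cap <- 1 - 1e-15
  z <- atanh(pmin(pmax(r, -cap), cap))
  tstat <- r * sqrt((t_len - 2) / pmax(1 - r^2, 1e-300))
  pv <- 2 * pt(-abs(tstat), df = t_len - 2)
  pv[abs(r) >= 1] <- 0
  sig <- select_significant(pv, alpha, n_comparisons %||% sum(usable))
  tab <- tibble::tibble(parcel = seq_len(p_n), r = r, z = z, p = pv,
                        significant = seq_len(p_n) %in% sig)
  structure(list(table = tab, mean_fc = mean(z[usable]),
                 n_sig = length(sig), sig_set = sig,
                 n_usable = sum(usable), alpha = alpha),
            class = "seed_fc")
}

#' Bonferroni parcel selection
#'
#' @param p_vec per-parcel two-sided p-values (`NA` = unusable, never
#'   selected).
#' @param alpha familywise level.
#' @param n_comparisons Bonferroni denominator; defaults to the number of
#'   non-missing p-values.
#' @return Integer indices with p < alpha / n_comparisons.
#' @export
select_significant <- function(p_vec, alpha = 0.05, n_comparisons = NULL) {
  m <- n_comparisons %||% sum(!is.na(p_vec))
  if (m < 1) return(integer(0))
  which(!is.na(p_vec) & p_vec < alpha / m)
}

#' Mean centroid distance to significantly connected parcels
#'
#' @param seed_centroid world-mm point (length 3).
#' @param parcel_centroids n_parcels x 3 matrix of world-mm centroids.
#' @param sig_set integer indices of selected parcels.
#' @return Mean Euclidean distance in mm; `NA` when `sig_set` is empty.
#' @export
mean_distance <- function(seed_centroid, parcel_centroids, sig_set) {
  if (length(sig_set) == 0) return(NA_real_)
  d <- sqrt(rowSums(sweep(parcel_centroids[sig_set, , drop = FALSE], 2,
                          seed_centroid)^2))
  mean(d)
}

#' Seed connectivity analysis for one subject
#'
#' Runs the full seed-based workflow for each requested seed (both tumors
#' and/or their mirror controls): parcel series with both tumor masks
#' always excluded (a control seed additionally excludes its own voxels),
#' seed FC with Bonferroni selection, and the three summary scalars (mean
#' FC, number of significant parcels, mean centroid distance). Tumor and
#' control seeds run through the identical code path.
#'
#' @param subject a `glioma_subject`.
#' @param atlas the cohort's `parcel_atlas`.
#' @param run `bold_run` to analyze (defaults to `subject$bold`; pass a
#'   preprocessed run to analyze that instead).
#' @param seeds character subset of `c("larger", "smaller",
#'   "larger_control", "smaller_control")`.
#' @param alpha familywise level for parcel selection.
#' @param n_comparisons optional fixed Bonferroni denominator.
#' @return Tibble with one row per seed: `seed_type`, `mean_fc`, `n_sig`,
#'   `mean_dist_mm`, and a list-column `fc` of `seed_fc` objects.
#' @export
seed_connectivity <- function(subject, atlas, run = subject$bold,
                              seeds = c("larger", "smaller",
                                        "larger_control", "smaller_control"),
                              alpha = 0.05, n_comparisons = NULL) {
  les <- subject$lesions
  mask_of <- list(larger = les$larger_mask, smaller = les$smaller_mask,
                  larger_control = les$larger_control,
                  smaller_control = les$smaller_control)
  seeds <- match.arg(seeds, names(mask_of), several.ok = TRUE)
  tumor_excl <- list(les$larger_mask, les$smaller_mask)
  base_series <- parcel_series(run, atlas, tumor_excl)
  purrr::map_dfr(seeds, function(sn) {
    mask <- mask_of[[sn]]
    pmat <- if (grepl("control$", sn)) {
      parcel_series(run, atlas, c(tumor_excl, list(mask)))
    } else {
      base_series
    }
    fc <- seed_fc(roi_series(run, mask), pmat, alpha, n_comparisons)
    ctr <- centroid(mask, atlas$affine)
    tibble::tibble(seed_type = sn, mean_fc = fc$mean_fc, n_sig = fc$n_sig,
                   mean_dist_mm = mean_distance(ctr, atlas$centroids,
                                                fc$sig_set),
                   fc = list(fc))
  })
}
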