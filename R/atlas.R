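#' Midline-symmetric parcellated cortex atlas
#'
#' Builds a synthetic cortical parcellation emulating a Schaefer-style
#' even-numbered parcel scheme on a voxel grid: an ellipsoidal "brain" is
#' split at the midsagittal plane, the left hemisphere is tiled with
#' `n_parcels / 2` contiguous Voronoi parcels grown from randomly placed
#' seed voxels, and the right hemisphere is its exact x-mirror (parcel `i`
#' pairs with parcel `i + n_parcels/2`). Each mirror pair is assigned one of
#' up to seven resting-state network labels (bilateral networks, as in the
#' Yeo scheme); all seven networks are represented whenever
#' `n_parcels >= 14`.
#'
#' @param n_parcels even number of parcels (half per hemisphere).
#' @param grid_shape integer length-3 voxel grid dimensions; the x extent
#'   must be even so the midline falls between voxel columns.
#' @param seed RNG seed controlling parcel seed placement.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 3, an
#'   EPI-like resolution).
#' @param n_networks number of network labels to cycle over (default 7).
#' @return An object of class `parcel_atlas`: a list with `labels` (3D
#'   integer array, 0 = background), `affine` (4x4 voxel-to-world mm map
#'   placing world x = 0 on the midline), `network_of` (integer vector,
#'   parcel -> network), `centroids` (n_parcels x 3 matrix, world mm),
#'   `brain_mask` (logical 3D array) and `n_parcels`.
#' @examples
#' atl <- make_atlas(8, c(20, 20, 10), seed = 1)
#' table(atl$labels[atl$labels > 0])
#' @export
make_atlas <- function(n_parcels, grid_shape, seed = 1L, voxel_size_mm = 3,
                       n_networks = 7L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2))
  grid_shape <- as.integer(grid_shape)
  if (n_parcels %% 2 != 0) {
    stop("n_parcels must be even (half per hemisphere)")
  }
  if (grid_shape[1] %% 2 != 0) {
    stop("grid x extent must be even so the midline falls between voxel columns")
  }
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]

  brain <- ellipsoid_mask(grid_shape)
  left <- brain
  left[(nx / 2 + 1):nx, , ] <- FALSE
  left_vox <- which(left)
  half <- n_parcels / 2L
  if (length(left_vox) < half * 2L) {
    stop("grid too small for requested parcel count")
  }

  set.seed(seed)
  seeds <- sample(left_vox, half)
  coords <- arrayInd(left_vox, grid_shape)
  seed_coords <- arrayInd(seeds, grid_shape)

  # nearest-seed (Voronoi) assignment: convex cells stay contiguous
  best <- rep.int(1L, length(left_vox))
  best_d <- rep.int(Inf, length(left_vox))
  for (p in seq_len(half)) {
    d <- (coords[, 1] - seed_coords[p, 1])^2 +
      (coords[, 2] - seed_coords[p, 2])^2 +
      (coords[, 3] - seed_coords[p, 3])^2
    upd <- d < best_d
    best[upd] <- p
    best_d[upd] <- d[upd]
  }

  labels <- array(0L, grid_shape)
  labels[left_vox] <- best
  right <- labels[nx:1, , , drop = FALSE]
  dim(right) <- grid_shape
  labels[right > 0L] <- right[right > 0L] + half

  network_of <- rep(seq_len(max(1L, min(n_networks, half))), length.out = half)
  network_of <- c(network_of, network_of) # mirror pair shares its network

  affine <- diag(4)
  affine[1, 1] <- affine[2, 2] <- affine[3, 3] <- voxel_size_mm
  affine[1:3, 4] <- -voxel_size_mm * c((nx + 1) / 2, (ny + 1) / 2, (nz + 1) / 2)

  centroids <- t(vapply(seq_len(n_parcels), function(p) {
    centroid(labels == p, affine)
  }, numeric(3)))

  structure(
    list(labels = labels, affine = affine, network_of = network_of,
         centroids = centroids, brain_mask = brain,
         n_parcels = as.integer(n_parcels), voxel_size_mm = voxel_size_mm),
    class = "parcel_atlas"
  )
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("parcel_atlas:", x$n_parcels, "parcels on a",
      paste(dim(x$labels), collapse = "x"), "grid,",
      length(unique(x$network_of)), "networks\n")
  invisible(x)
}

ellipsoid_mask <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ix <- ((seq_len(nx) - cx) / (nx / 2 - 0.5))^2
  iy <- ((seq_len(ny) - cy) / (ny / 2 - 0.5))^2
  iz <- ((seq_len(nz) - cz) / (nz / 2 - 0.5))^2
  outer(outer(ix, iy, `+`), iz, `+`) <= 1
}

#' Reflect a mask (or any 3D array) across the midsagittal plane
#'
#' The contralateral mirror control of a tumor mask: the voxelwise
#' reflection x -> -x in world coordinates, which for the even-x grids used
#' here is an exact flip of the first array dimension. The operation is an
#' involution: `mirror_mask(mirror_mask(m, atl), atl)` recovers `m`.
#'
#' @param mask logical (or numeric) 3D array on the atlas grid.
#' @param atlas a `parcel_atlas` defining the grid and its symmetry plane.
#' @return The reflected array, same type and dimensions.
#' @export
mirror_mask <- function(mask, atlas) {
  stopifnot(identical(dim(mask), dim(atlas$labels)))
  if (is.logical(mask) && !any(mask)) stop("mask is empty")
  out <- mask[dim(mask)[1]:1, , , drop = FALSE]
  dim(out) <- dim(mask)
  out
}

#' Number of distinct resting-state networks intersected by an ROI
#'
#' Counts the distinct network labels among atlas-labeled voxels under the
#' mask, the quantity used as a fixed-effect covariate in the mixed-model
#' adjustment (an ROI straddling many networks samples more heterogeneous
#' signal).
#'
#' @inheritParams mirror_mask
#' @return Integer count; 0 with a warning when the mask misses every
#'   labeled voxel.
#' @export
count_intersected_networks <- function(mask, atlas) {
  stopifnot(identical(dim(mask), dim(atlas$labels)))
  labs <- atlas$labels[mask & atlas$labels > 0L]
  if (length(labs) == 0L) {
    warning("mask does not intersect any labeled voxel")
    return(0L)
  }
  length(unique(atlas$network_of[unique(labs)]))
}

#' Center of mass of a voxel region in world coordinates
#'
#' @param mask logical 3D array (or the result of `atlas$labels == p`).
#' @param affine 4x4 voxel-to-world (mm) affine.
#' @return Numeric length-3 world-mm point.
#' @export
centroid <- function(mask, affine) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take the centroid of an empty region")
  colMeans(voxel_to_world(idx, affine))
}

voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}
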