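#' 3D image volume
#'
#' A minimal voxel container shared by the reconstructed ultrasound volume,
#' the simulated MRI, and the phantom masks. `voxels` is a numeric array of
#' dimension `(nx, ny, nz)`; the world position of voxel `(i, j, k)`
#' (1-based) is `origin + (c(i, j, k) - 1) * spacing`, in mm, under the
#' package coordinate convention (see [prostacoreg-package]).
#'
#' @param voxels numeric 3D array.
#' @param spacing mm triple, all positive.
#' @param origin mm triple, finite.
#' @param background value used for "outside the sampled support".
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0), background = 0) {
  stopifnot(length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be a positive mm triple")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be a finite mm triple")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 background = background),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, origin (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# World coordinates of voxel centres along axis k.
vol_axis <- function(vol, k) {
  vol$origin[k] + (seq_len(dim(vol$voxels)[k]) - 1) * vol$spacing[k]
}

#' Sample a volume at world points by trilinear interpolation
#'
#' Points outside the voxel grid return the volume's `background` value.
#'
#' @param vol an [image_volume()].
#' @param pts n x 3 matrix of world mm coordinates.
#' @return numeric vector of length n.
#' @export
vol_sample <- function(vol, pts) {
  pts <- as_point_matrix(pts, 3)
  dm <- dim(vol$voxels)
  g <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
  ok <- g[, 1] >= 0 & g[, 1] <= dm[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= dm[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= dm[3] - 1
  out <- rep(vol$background, nrow(pts))
  if (!any(ok)) return(out)
  g <- g[ok, , drop = FALSE]
  i0 <- pmin(floor(g[, 1]), dm[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(g[, 2]), dm[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(g[, 3]), dm[3] - 2); k0 <- pmax(k0, 0)
  fx <- g[, 1] - i0; fy <- g[, 2] - j0; fz <- g[, 3] - k0
  v <- vol$voxels
  at <- function(di, dj, dk) {
    v[(i0 + di) + dm[1] * ((j0 + dj) + dm[2] * (k0 + dk)) + 1]
  }
  val <- (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
         fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
         (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
         fx * fy * (1 - fz) * at(1, 1, 0) +
         (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
         fx * (1 - fy) * fz * at(1, 0, 1) +
         (1 - fx) * fy * fz * at(0, 1, 1) +
         fx * fy * fz * at(1, 1, 1)
  out[ok] <- val
  out
}

#' Centroid and principal-axis lengths of a binary mask volume
#'
#' For a solid ellipsoid the covariance eigenvalues are `a^2/5`, so the full
#' axis length is estimated as `2 * sqrt(5 * lambda)`; the same estimator is
#' applied to both the scene and the reconstructed mask so the comparison is
#' like-for-like.
#'
#' @param vol an [image_volume()] whose voxels are in `[0, 1]`.
#' @param threshold voxels `> threshold` count as inside.
#' @return list with `centroid` (mm triple), `axis_lengths_mm`
#'   (decreasing), and `n_voxels`.
#' @export
mask_moments <- function(vol, threshold = 0.5) {
  idx <- which(vol$voxels > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  pts <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  ev <- sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE)
  list(centroid = ctr, axis_lengths_mm = 2 * sqrt(5 * pmax(ev, 0)),
       n_voxels = nrow(idx))
}

# Voxel volume in mm^3.
voxel_volume <- function(vol) prod(vol$spacing)
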