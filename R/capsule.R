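# 2D MRI-to-whole-mount registration: slide correspondence validation,
# capsule contour correspondence, similarity + TPS slice registration,
# and transition-zone Dice.

#' Capsule or transition-zone contour
#'
#' A closed simple polygon in slide (y, z) mm coordinates; closure is
#' implied (first vertex is not repeated).
#'
#' @param slice_id identifier of the slice/slide the contour lives on.
#' @param kind `"capsule"` or `"transition_zone"`.
#' @param vertices n x 2 matrix, n >= 3.
#' @export
capsule_contour <- function(slice_id, kind = c("capsule", "transition_zone"),
                            vertices) {
  kind <- match.arg(kind)
  vertices <- as_point_matrix(vertices, 2)
  if (nrow(vertices) < 3) stop("contour needs at least 3 vertices")
  if (nrow(vertices) > 1 &&
      sqrt(sum((vertices[1, ] - vertices[nrow(vertices), ])^2)) < 1e-9)
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  if (!polygon_is_simple(vertices)) stop("contour polygon is self-intersecting")
  structure(list(slice_id = slice_id, kind = kind, vertices = vertices),
            class = "capsule_contour")
}

contour_vertices <- function(x) {
  if (inherits(x, "capsule_contour")) x$vertices else as_point_matrix(x, 2)
}

#' Slide-to-MRI correspondence table
#'
#' @param entries data.frame with columns `wm_slide_id`, `mri_slice_index`,
#'   ordered by slide position.
#' @param mri_slice_spacing_mm MRI slice spacing.
#' @param wm_thickness_mm WM section thickness.
#' @export
slide_correspondence <- function(entries, mri_slice_spacing_mm = 1.5,
                                 wm_thickness_mm = 4.5) {
  stopifnot(is.data.frame(entries),
            all(c("wm_slide_id", "mri_slice_index") %in% names(entries)))
  structure(list(entries = entries,
                 mri_slice_spacing_mm = mri_slice_spacing_mm,
                 wm_thickness_mm = wm_thickness_mm),
            class = "slide_correspondence")
}

#' Validate a slide-to-MRI correspondence table
#'
#' The anatomical matching of slides to MRI frames is a human input; this
#' only checks its internal consistency: MRI indices strictly increasing
#' with slide order, no duplicates, and consecutive assigned indices
#' differing by `round(wm_thickness / mri_spacing) +/- 1` (one WM slide
#' contained in every ~3 MRI frames at 4.5 / 1.5 mm). The input is never
#' mutated.
#'
#' @param corr a [slide_correspondence()].
#' @return list with `valid` (logical) and `violations` (character).
#' @export
validate_slide_correspondence <- function(corr) {
  stopifnot(inherits(corr, "slide_correspondence"))
  idx <- corr$entries$mri_slice_index
  if (!length(idx)) stop("empty correspondence")
  viol <- character(0)
  if (anyDuplicated(idx))
    viol <- c(viol, sprintf("duplicate MRI slice index %d",
                            idx[duplicated(idx)][1]))
  if (any(diff(idx) <= 0))
    viol <- c(viol, "MRI slice indices not strictly increasing with slide order")
  step <- round(corr$wm_thickness_mm / corr$mri_slice_spacing_mm)
  bad <- which(abs(diff(idx) - step) > 1)
  for (b in bad)
    viol <- c(viol, sprintf(
      "slides %s -> %s: MRI index step %d outside %d +/- 1",
      corr$entries$wm_slide_id[b], corr$entries$wm_slide_id[b + 1],
      diff(idx)[b], step))
  list(valid = length(viol) == 0, violations = viol)
}

#' Establish point correspondence between two capsule contours
#'
#' Each contour is resampled to `n_points` equal-arc-length vertices,
#' oriented counter-clockwise, and anchored at its posterior-most
#' (minimum-z) boundary point; correspondence is then by index. This rule
#' is deterministic and rotation-robust for prostate-like shapes whose
#' posterior aspect is geometrically distinctive.
#'
#' @param fixed,moving [capsule_contour()]s (or raw n x 2 polygons).
#' @param n_points resampled vertex count, default 64.
#' @return list with `fixed` and `moving` n_points x 2 matched matrices.
#' @export
correspond_contours <- function(fixed, moving, n_points = 64) {
  fv <- contour_vertices(fixed); mv <- contour_vertices(moving)
  if (nrow(fv) < 3 || nrow(mv) < 3) stop("degenerate contour (< 3 vertices)")
  list(fixed = resample_closed_polygon(fv, n_points, "posterior"),
       moving = resample_closed_polygon(mv, n_points, "posterior"))
}

#' Least-squares similarity transform between matched 2D point sets
#'
#' Closed-form orthogonal-Procrustes (Umeyama) solution for scale,
#' rotation and translation; reflection disallowed. The in-plane "rigid"
#' alignment includes scale because fixation shrinkage changes slide size.
#'
#' @param moving n x 2 matrix.
#' @param fixed n x 2 matrix, corresponding order.
#' @return a [similarity_transform_2d()] mapping moving onto fixed.
#' @export
fit_similarity <- function(moving, fixed) {
  M <- as_point_matrix(moving, 2); F <- as_point_matrix(fixed, 2)
  if (nrow(M) != nrow(F)) stop("pair counts differ")
  if (nrow(M) < 2) stop("need at least 2 pairs")
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F, 2, cf)
  varM <- mean(rowSums(Mc^2))
  if (varM < 1e-12) stop("all moving points coincident")
  S <- crossprod(Fc, Mc) / nrow(M)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  Dm <- diag(c(1, d))
  R <- sv$u %*% Dm %*% t(sv$v)
  scale <- sum(sv$d * diag(Dm)) / varM
  rot_deg <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  translation <- cf - scale * as.numeric(R %*% cm)
  similarity_transform_2d(scale, rot_deg, translation)
}

#' Register an MRI slice to its matched WM slide by capsule
#'
#' A similarity transform is fitted on all corresponded capsule points,
#' then a 2D TPS on every `tps_control_stride`-th residual pair refines
#' the fit (stride 4 of 64 resampled points = 16 controls, enough to
#' absorb smooth specimen deformation without chasing contour noise).
#'
#' @param moving_capsule MRI capsule contour.
#' @param fixed_capsule WM capsule contour.
#' @param tps_control_stride keep every stride-th corresponded pair as a
#'   TPS control, default 4.
#' @param lambda TPS regularization, default 0 (exact interpolation).
#' @param n_points resampled correspondence count, default 64.
#' @return a [composite_transform()] (similarity then TPS).
#' @export
register_slice <- function(moving_capsule, fixed_capsule,
                           tps_control_stride = 4, lambda = 0,
                           n_points = 64) {
  pairs <- correspond_contours(fixed_capsule, moving_capsule, n_points)
  sim <- fit_similarity(pairs$moving, pairs$fixed)
  keep <- seq(1, n_points, by = tps_control_stride)
  src <- apply_transform(sim, pairs$moving[keep, , drop = FALSE])
  tps <- fit_tps(src, pairs$fixed[keep, , drop = FALSE], dimension = 2,
                 regularization = lambda)
  composite_transform(sim, tps)
}

#' Dice coefficient of two transition zones after registration
#'
#' Both contours are rasterized on a common grid (default 0.2 mm pixels,
#' far below every reported registration error) and the Dice coefficient
#' `2|A n B| / (|A| + |B|)` is returned in `[0, 1]`.
#'
#' @param fixed_tz WM transition-zone contour.
#' @param moving_tz MRI transition-zone contour.
#' @param transform transform from [register_slice()] applied to
#'   `moving_tz` (`NULL` = identity).
#' @param pixel_mm rasterization pixel size.
#' @export
transition_zone_dice <- function(fixed_tz, moving_tz, transform = NULL,
                                 pixel_mm = 0.2) {
  fv <- contour_vertices(fixed_tz)
  mv <- contour_vertices(moving_tz)
  if (!is.null(transform)) mv <- apply_transform(transform, mv)
  lo <- pmin(apply(fv, 2, min), apply(mv, 2, min)) - pixel_mm
  hi <- pmax(apply(fv, 2, max), apply(mv, 2, max)) + pixel_mm
  grid <- make_raster_grid(c(lo[1], hi[1]), c(lo[2], hi[2]), pixel_mm)
  A <- rasterize_polygon(fv, grid)
  B <- rasterize_polygon(mv, grid)
  if (!any(A) || !any(B)) stop("empty region after rasterization")
  2 * sum(A & B) / (sum(A) + sum(B))
}
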