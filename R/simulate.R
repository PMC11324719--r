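# Simulated acquisitions of a phantom scene: fan-sweep ultrasound, axial
# MRI under a smooth deformation, and whole-mount sections with per-slide
# deformation and shrinkage.

#' Simulate a rotational fan sweep of a phantom scene
#'
#' Frame i carries a rotation angle linearly spaced over `angle_range`;
#' each frame's pixels are trilinear samples of the scene intensity on the
#' plane placed by the inverse of the reconstruction geometry, so
#' reconstruction is exercised as a true round trip. The default 300
#' frames sweep right to left across the gland; the angular extent is a
#' package choice (the acquisition protocol does not pin it down) and is
#' fully configurable.
#'
#' @param scene a [generate_scene()] result.
#' @param n_frames number of frames (>= 1).
#' @param angle_range degree pair, strictly increasing when `n_frames > 1`.
#' @param offset_mm transducer-to-first-pixel-row offset (>= 0; 2 mm for
#'   the modelled probe).
#' @param in_plane_spacing mm pair `(depth su, along-probe sv)`.
#' @param noise_sd additive Gaussian pixel noise.
#' @param seed integer controlling the noise.
#' @return a [fan_sweep()].
#' @export
simulate_fan_sweep <- function(scene, n_frames = 300, angle_range = c(-70, 70),
                               offset_mm = 2, in_plane_spacing = c(0.5, 0.5),
                               noise_sd = 0, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (offset_mm < 0) stop("offset_mm must be >= 0")
  if (n_frames > 1 && angle_range[2] <= angle_range[1])
    stop("angle range must be strictly increasing")
  su <- in_plane_spacing[1]; sv <- in_plane_spacing[2]
  iv <- scene$intensity_volume
  xmax <- vol_axis(iv, 1)[dim(iv$voxels)[1]]
  ymax <- max(abs(range(vol_axis(iv, 2))))
  zmax <- max(vol_axis(iv, 3))
  r_need <- sqrt(ymax^2 + zmax^2)
  nu <- floor((r_need - offset_mm) / su) + 1L
  nv <- floor(xmax / sv) + 1L
  angles <- if (n_frames == 1) angle_range[1]
            else seq(angle_range[1], angle_range[2], length.out = n_frames)
  r <- (0:(nu - 1)) * su + offset_mm
  xcol <- (0:(nv - 1)) * sv
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    th <- angles[i] * pi / 180
    pts <- cbind(rep(xcol, each = nu),
                 rep(r * sin(th), times = nv),
                 rep(r * cos(th), times = nv))
    px <- matrix(vol_sample(iv, pts), nrow = nu, ncol = nv)
    if (noise_sd > 0) px <- px + matrix(rnorm(nu * nv, sd = noise_sd), nu, nv)
    frames[[i]] <- fan_frame(px, angles[i], in_plane_spacing, offset_mm)
  }
  fan_sweep(frames)
}

#' Simulate an axial MRI acquisition of a deformed scene
#'
#' The scene is pushed through `deformation` and resampled on axial slices
#' (along x) at `slice_spacing_mm`; in-plane sampling matches the scene
#' grid. Ground-truth fiducial positions under the deformation are
#' returned for TRE evaluation. Optional Gaussian jitter models landmark
#' identification error (default 0: identification error is out of scope).
#'
#' @param scene a [generate_scene()] result.
#' @param deformation a [deformation_field()] (3D).
#' @param slice_spacing_mm axial slice spacing (> 0), 1.5 mm typical.
#' @param landmark_jitter_sd mm; Gaussian jitter added to returned landmarks.
#' @param seed integer controlling the jitter.
#' @return list with `volume` (an [image_volume()]), `landmarks` (named
#'   matrix of deformed fiducials), and `deformation`.
#' @export
simulate_mri_volume <- function(scene, deformation, slice_spacing_mm = 1.5,
                                landmark_jitter_sd = 0, seed = 1) {
  if (slice_spacing_mm <= 0) stop("slice_spacing_mm must be > 0")
  stopifnot(inherits(deformation, "deformation_field"))
  fid <- scene$fiducials
  probe <- if (nrow(fid)) fid else matrix(scene$spec$gland_center, 1)
  if (!check_invertible(deformation, probe))
    stop("non-invertible deformation field")
  iv <- scene$intensity_volume
  xs <- seq(vol_axis(iv, 1)[1], vol_axis(iv, 1)[dim(iv$voxels)[1]],
            by = slice_spacing_mm)
  ys <- vol_axis(iv, 2); zs <- vol_axis(iv, 3)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  pts <- cbind(rep(xs, times = ny * nz),
               rep(rep(ys, each = nx), times = nz),
               rep(zs, each = nx * ny))
  if (deformation$magnitude_mm > 0) {
    src <- invert_deformation(deformation, pts)
  } else {
    src <- pts
  }
  vox <- array(vol_sample(iv, src), c(nx, ny, nz))
  vol <- image_volume(vox, c(slice_spacing_mm, iv$spacing[2], iv$spacing[3]),
                      c(xs[1], iv$origin[2], iv$origin[3]))
  lm <- apply_transform(deformation, fid)
  if (landmark_jitter_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    lm <- lm + matrix(rnorm(length(lm), sd = landmark_jitter_sd), nrow(lm))
  }
  dimnames(lm) <- dimnames(fid)
  list(volume = vol, landmarks = lm, deformation = deformation)
}

#' Simulate whole-mount pathology sections of a scene
#'
#' Axial sections of the given thickness are cut through the gland; each
#' retained slide carries the analytic capsule, transition-zone, and
#' lesion contours of its central plane, uniformly shrunk about the
#' capsule centroid (tissue fixation) and warped by an independent smooth
#' 2D deformation, plus ground-truth fiducial positions. The slide count
#' is `ceiling(gland axial extent / thickness)`; sections that miss the
#' gland are omitted with a message.
#'
#' @param scene a [generate_scene()] result.
#' @param deformation_per_slide optional list of 2D [deformation_field()]s,
#'   one per section; `NULL` draws smooth fields of
#'   `deformation_magnitude_mm` from the seed.
#' @param section_thickness_mm section thickness (> 0), 4.5 mm typical.
#' @param shrink_factor uniform in-plane linear shrinkage in (0, 1].
#' @param deformation_magnitude_mm max per-slide displacement (mm).
#' @param seed integer; determines generated deformations.
#' @param n_contour_points vertices per contour polygon.
#' @return object of class `wm_slide_set`.
#' @export
simulate_wm_slides <- function(scene, deformation_per_slide = NULL,
                               section_thickness_mm = 4.5,
                               shrink_factor = 0.95,
                               deformation_magnitude_mm = 3,
                               seed = 1, n_contour_points = 128) {
  if (section_thickness_mm <= 0) stop("section_thickness_mm must be > 0")
  if (shrink_factor <= 0 || shrink_factor > 1)
    stop("shrink_factor must be in (0, 1]")
  ctr <- scene$spec$gland_center; a <- scene$spec$gland_semiaxes
  x_lo <- ctr[1] - a[1]
  n_slides <- ceiling(2 * a[1] / section_thickness_mm)
  slides <- list()
  for (i in seq_len(n_slides)) {
    x_c <- x_lo + (i - 0.5) * section_thickness_mm
    cs <- scene_cross_section(scene, x_c, n_contour_points)
    if (is.null(cs)) {
      message(sprintf("section %d omitted: no gland intersection at x = %.1f mm",
                      i, x_c))
      next
    }
    cen <- polygon_centroid(cs$capsule)
    shrink <- similarity_transform_2d(shrink_factor, 0,
                                      (1 - shrink_factor) * cen)
    if (!is.null(deformation_per_slide)) {
      defo <- deformation_per_slide[[min(i, length(deformation_per_slide))]]
    } else {
      bb <- rbind(apply(cs$capsule, 2, min) - 2, apply(cs$capsule, 2, max) + 2)
      defo <- make_smooth_deformation(bb, deformation_magnitude_mm,
                                      n_control = 8,
                                      seed = (seed * 131 + i) %% 2147483647)
    }
    truth <- composite_transform(shrink, defo)
    warp <- function(p) if (is.null(p)) NULL else apply_transform(truth, p)
    fid_idx <- which(abs(scene$fiducials[, 1] - x_c) <= section_thickness_mm / 2)
    fid2 <- NULL
    if (length(fid_idx)) {
      fid2 <- warp(scene$fiducials[fid_idx, 2:3, drop = FALSE])
      rownames(fid2) <- rownames(scene$fiducials)[fid_idx]
    }
    lesions <- lapply(cs$lesions, function(l) {
      list(lesion_id = l$lesion_id, grade_group = l$grade_group,
           polygon = warp(l$polygon))
    })
    slides[[length(slides) + 1]] <- list(
      slide_id = sprintf("WM%02d", i), index = i, x_center = x_c,
      capsule = warp(cs$capsule),
      transition_zone = warp(cs$transition_zone),
      lesions = lesions, fiducials = fid2,
      truth_transform = truth)
  }
  structure(list(slides = slides,
                 section_thickness_mm = section_thickness_mm,
                 shrink_factor = shrink_factor,
                 gland_axial_extent_mm = 2 * a[1]),
            class = "wm_slide_set")
}

#' @export
print.wm_slide_set <- function(x, ...) {
  cat(sprintf("<wm_slide_set> %d slide(s), %.1f mm sections, shrink %.2f\n",
              length(x$slides), x$section_thickness_mm, x$shrink_factor))
  invisible(x)
}
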