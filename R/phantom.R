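# Digital prostate phantom.
#
# The phantom is an ellipsoidal gland with a bright capsule rim, a
# transition zone surrounding a curved urethra, 1-3 ellipsoidal lesions
# with ISUP grade groups, and named point fiducials. It is the stated world
# for every synthetic acquisition: a ~300-frame angular fan sweep with a
# 2 mm probe offset, an axial MRI at 1.5 mm slice spacing under a smooth
# 3D deformation, and 4.5 mm-thick whole-mount sections with per-slide 2D
# deformation and uniform shrinkage.

#' Phantom specification
#'
#' Default geometry places the gland centre 24 mm anterior to the probe
#' axis at the middle of the probe's x range; gland semiaxes default to
#' (22, 18, 15) mm, a prostatectomy-sized gland. When `lesion_specs` is
#' `NULL`, 1-3 lesions are drawn from the seed with a grade-group mix
#' resembling a prostatectomy cohort (index lesion GG 2-5, secondaries
#' GG 1-2); the count distribution has mean 1.6 and sd ~0.6.
#'
#' @param gland_semiaxes mm triple (x, y, z), all positive.
#' @param gland_center mm triple; the probe axis is the line y = z = 0.
#' @param urethra_waypoints matrix of 3D mm points the urethra passes
#'   through (apex to base); `NULL` for a default curved path.
#' @param lesion_specs list of `list(center=, semiaxes=, grade_group=)`;
#'   `NULL` to draw from the seed.
#' @param fiducial_count number of internal point fiducials.
#' @param voxel_spacing mm triple for the voxel grids.
#' @param seed integer; fully determines the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(gland_semiaxes = c(22, 18, 15),
                         gland_center = c(28, 0, 24),
                         urethra_waypoints = NULL,
                         lesion_specs = NULL,
                         fiducial_count = 5,
                         voxel_spacing = c(1, 1, 1),
                         seed = 1) {
  gland_semiaxes <- as.numeric(gland_semiaxes)
  if (length(gland_semiaxes) != 3 || any(gland_semiaxes <= 0))
    stop("gland_semiaxes must be a positive mm triple")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (fiducial_count < 0) stop("fiducial_count must be >= 0")
  a <- gland_semiaxes; ctr <- as.numeric(gland_center)
  if (is.null(urethra_waypoints)) {
    urethra_waypoints <- rbind(
      ctr + c(-0.8 * a[1], 0, 0),
      ctr + c(0, 0, -0.20 * a[3]),
      ctr + c(0.8 * a[1], 0, 0))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(lesion_specs)) {
    n_lesions <- sample(1:3, 1, prob = c(0.45, 0.50, 0.05))
    lesion_specs <- vector("list", n_lesions)
    for (i in seq_len(n_lesions)) {
      gg <- if (i == 1) sample(2:5, 1, prob = c(8, 5, 1, 1)) else sample(1:2, 1)
      semi <- if (i == 1) runif(3, 5, 9) else runif(3, 3, 6)
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
      center <- ctr + u * a * 0.5
      semi <- fit_lesion_inside(center, semi, ctr, a)
      lesion_specs[[i]] <- list(center = center, semiaxes = semi,
                                grade_group = gg)
    }
  }
  for (i in seq_along(lesion_specs)) {
    ls <- lesion_specs[[i]]
    if (!all(c("center", "semiaxes", "grade_group") %in% names(ls)))
      stop("each lesion spec needs center, semiaxes, grade_group")
    if (!ls$grade_group %in% 1:5)
      stop(sprintf("lesion %d: grade_group must be in 1..5", i))
    if (any(ls$semiaxes <= 0)) stop(sprintf("lesion %d: semiaxes must be > 0", i))
  }
  structure(list(gland_semiaxes = a, gland_center = ctr,
                 urethra_waypoints = as.matrix(urethra_waypoints),
                 lesion_specs = lesion_specs,
                 fiducial_count = as.integer(fiducial_count),
                 voxel_spacing = as.numeric(voxel_spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Shrink lesion semiaxes (exactly, by bisection) until the whole lesion
# surface lies inside the gland ellipsoid with margin.
fit_lesion_inside <- function(center, semiaxes, gland_center, gland_semiaxes,
                              margin = 0.97) {
  dirs <- sphere_directions(200)
  surf_max <- function(s) {
    pts <- sweep(dirs %*% diag(semiaxes * s), 2, center, "+")
    max(rowSums(sweep(sweep(pts, 2, gland_center, "-"), 2,
                      gland_semiaxes, "/")^2))
  }
  if (surf_max(1) <= margin^2) return(semiaxes)
  lo <- 0.05; hi <- 1
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (surf_max(mid) <= margin^2) lo <- mid else hi <- mid
  }
  semiaxes * lo
}

ellipsoid_value <- function(x, y, z, center, semiaxes) {
  ((x - center[1]) / semiaxes[1])^2 +
    ((y - center[2]) / semiaxes[2])^2 +
    ((z - center[3]) / semiaxes[3])^2
}

#' Generate a phantom scene from a specification
#'
#' Voxelises the analytic shapes onto a common grid. Repeated calls with
#' the same spec (which embeds the seed) are bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_scene` with the intensity volume,
#'   binary capsule / transition-zone / lesion masks (all on the same
#'   grid), the urethra polyline, and named fiducials.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$gland_semiaxes; ctr <- spec$gland_center
  for (i in seq_along(spec$lesion_specs)) {
    ls <- spec$lesion_specs[[i]]
    dirs <- sphere_directions(200)
    pts <- sweep(dirs %*% diag(ls$semiaxes), 2, ls$center, "+")
    f <- rowSums(sweep(sweep(pts, 2, ctr, "-"), 2, a, "/")^2)
    if (max(f) > 1)
      stop(sprintf("lesion %d extends outside the gland ellipsoid", i))
  }
  margin <- 6
  lo <- pmax(ctr - a - margin, c(0, -Inf, 0))
  hi <- ctr + a + margin
  sp <- spec$voxel_spacing
  xs <- seq(lo[1], hi[1], by = sp[1])
  ys <- seq(lo[2], hi[2], by = sp[2])
  zs <- seq(lo[3], hi[3], by = sp[3])
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  fg <- ellipsoid_value(X, Y, Z, ctr, a)
  vol <- function(vals) image_volume(array(vals, c(nx, ny, nz)), sp, lo)

  intensity <- rep(0.25, length(X))
  intensity[fg <= 1] <- 0.65
  intensity[fg <= 1 & fg > 0.92] <- 0.85   # capsule rim
  tz_center <- ctr + c(0, 0, 0.13 * a[3])
  tz_semi <- c(0.55, 0.50, 0.45) * a
  ftz <- ellipsoid_value(X, Y, Z, tz_center, tz_semi)
  intensity[ftz <= 1] <- 0.50
  lesion_masks <- vector("list", length(spec$lesion_specs))
  for (i in seq_along(spec$lesion_specs)) {
    ls <- spec$lesion_specs[[i]]
    fl <- ellipsoid_value(X, Y, Z, ls$center, ls$semiaxes)
    intensity[fl <= 1] <- 0.95
    m <- vol(as.numeric(fl <= 1))
    attr(m, "grade_group") <- ls$grade_group
    lesion_masks[[i]] <- m
  }
  # urethra: dark tube of radius 1.5 mm along a spline through the waypoints
  wp <- spec$urethra_waypoints
  t0 <- c(0, cumsum(sqrt(rowSums(diff(wp)^2))))
  tq <- seq(0, max(t0), length.out = max(40, ceiling(max(t0))))
  upath <- cbind(spline(t0, wp[, 1], xout = tq)$y,
                 spline(t0, wp[, 2], xout = tq)$y,
                 spline(t0, wp[, 3], xout = tq)$y)
  ivol <- array(intensity, c(nx, ny, nz))
  r_u <- 1.5
  for (p in seq_len(nrow(upath))) {
    q <- upath[p, ]
    ii <- which(abs(xs - q[1]) <= r_u)
    jj <- which(abs(ys - q[2]) <= r_u)
    kk <- which(abs(zs - q[3]) <= r_u)
    if (!length(ii) || !length(jj) || !length(kk)) next
    sub <- expand.grid(i = ii, j = jj, k = kk)
    d2 <- (xs[sub$i] - q[1])^2 + (ys[sub$j] - q[2])^2 + (zs[sub$k] - q[3])^2
    inside <- sub[d2 <= r_u^2, , drop = FALSE]
    if (nrow(inside))
      ivol[cbind(inside$i, inside$j, inside$k)] <- 0.05
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer((spec$seed + 7919) %% .Machine$integer.max))
  fid <- matrix(numeric(0), 0, 3)
  while (nrow(fid) < spec$fiducial_count) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
    p <- ctr + u * a * 0.8
    if (nrow(fid) == 0 || min(sqrt(rowSums(sweep(fid, 2, p, "-")^2))) > 8)
      fid <- rbind(fid, p)
  }
  rownames(fid) <- if (nrow(fid)) paste0("fiducial_", seq_len(nrow(fid))) else NULL
  colnames(fid) <- c("x", "y", "z")

  structure(list(
    intensity_volume = image_volume(ivol, sp, lo),
    capsule_mask = vol(as.numeric(fg <= 1)),
    transition_zone_mask = vol(as.numeric(ftz <= 1)),
    lesion_masks = lesion_masks,
    urethra_polyline = upath,
    fiducials = fid,
    tz_center = tz_center, tz_semiaxes = tz_semi,
    spec = spec), class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> gland semiaxes (%.1f, %.1f, %.1f) mm, %d lesion(s), %d fiducial(s)\n",
              x$spec$gland_semiaxes[1], x$spec$gland_semiaxes[2],
              x$spec$gland_semiaxes[3], length(x$lesion_masks),
              nrow(x$fiducials)))
  invisible(x)
}

#' Analytic capsule cross-section of a scene
#'
#' @param scene a [generate_scene()] result.
#' @param x0 axial position (mm).
#' @param n polygon vertex count.
#' @return n x 2 polygon in slide (y, z) coordinates, or `NULL` when the
#'   plane misses the gland.
#' @export
capsule_cross_section <- function(scene, x0, n = 128) {
  cs <- ellipsoid_cross_section(scene$spec$gland_center,
                                scene$spec$gland_semiaxes, x0)
  if (is.null(cs)) return(NULL)
  ellipse_polygon(cs$center, cs$semiaxes, n)
}

# All analytic cross-sections (capsule, transition zone, lesions) at x = x0.
scene_cross_section <- function(scene, x0, n = 128) {
  caps <- capsule_cross_section(scene, x0, n)
  if (is.null(caps)) return(NULL)
  tz <- ellipsoid_cross_section(scene$tz_center, scene$tz_semiaxes, x0)
  lesions <- list()
  for (i in seq_along(scene$spec$lesion_specs)) {
    ls <- scene$spec$lesion_specs[[i]]
    cx <- ellipsoid_cross_section(ls$center, ls$semiaxes, x0)
    if (!is.null(cx))
      lesions[[length(lesions) + 1]] <-
        list(lesion_id = i, grade_group = ls$grade_group,
             polygon = ellipse_polygon(cx$center, cx$semiaxes, n))
  }
  list(capsule = caps,
       transition_zone = if (is.null(tz)) NULL
                         else ellipse_polygon(tz$center, tz$semiaxes, n),
       lesions = lesions)
}

#' Control and evaluation landmarks of a phantom scene
#'
#' Mirrors the clinical landmark protocol: three urethra points (apex,
#' mid-gland, base) plus `n_capsule` evenly spaced capsule points in each
#' of three axial frames are `control` landmarks that fit the warp; the
#' scene fiducials are `evaluation` landmarks held out for TRE. The two
#' roles are disjoint by construction.
#'
#' @param scene a [generate_scene()] result.
#' @param n_capsule capsule points per axial frame (default 8).
#' @return data.frame with columns name, role, x, y, z.
#' @export
phantom_landmarks <- function(scene, n_capsule = 8) {
  ctr <- scene$spec$gland_center; a <- scene$spec$gland_semiaxes
  wp <- scene$spec$urethra_waypoints
  rows <- data.frame(name = c("urethra_apex", "urethra_mid", "urethra_base"),
                     role = "control",
                     x = wp[, 1], y = wp[, 2], z = wp[, 3])
  frames <- ctr[1] + c(-0.6, 0, 0.6) * a[1]
  labels <- c("apex", "mid", "base")
  for (f in seq_along(frames)) {
    cs <- ellipsoid_cross_section(ctr, a, frames[f])
    pts <- ellipse_polygon(cs$center, cs$semiaxes, n_capsule)
    rows <- rbind(rows, data.frame(
      name = sprintf("capsule_%s_%d", labels[f], seq_len(n_capsule)),
      role = "control", x = frames[f], y = pts[, 1], z = pts[, 2]))
  }
  if (nrow(scene$fiducials))
    rows <- rbind(rows, data.frame(name = rownames(scene$fiducials),
                                   role = "evaluation",
                                   x = scene$fiducials[, 1],
                                   y = scene$fiducials[, 2],
                                   z = scene$fiducials[, 3]))
  rownames(rows) <- NULL
  rows
}
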