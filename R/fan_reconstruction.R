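# Fan-sweep reconstruction: place rotated para-sagittal frames in 3D and
# resample onto parallel sagittal planes.
#
# Geometry: a frame pixel at depth row u and along-probe column v (0-based)
# in a frame rotated by theta about the probe (x) axis sits at
#   (x, y, z) = (v*sv, (u*su + offset)*sin(theta), (u*su + offset)*cos(theta)).
# The offset is the transducer-to-first-row gap (2 mm for the modelled
# probe): each image is shifted away from the probe axis before rotation.

#' Fan frame
#'
#' @param pixels numeric matrix, rows = depth (u), columns = along-probe (v).
#' @param angle_deg rotation about the probe axis (0 = straight anterior).
#' @param in_plane_spacing mm pair `(su, sv)`, both positive.
#' @param offset_mm transducer-to-first-row offset, >= 0.
#' @export
fan_frame <- function(pixels, angle_deg, in_plane_spacing, offset_mm = 2) {
  pixels <- as.matrix(pixels)
  if (!length(pixels)) stop("frame pixels must be nonempty")
  if (any(in_plane_spacing <= 0)) stop("in_plane_spacing must be positive")
  if (offset_mm < 0) stop("offset_mm must be >= 0")
  structure(list(pixels = pixels, angle_deg = as.numeric(angle_deg),
                 in_plane_spacing = as.numeric(in_plane_spacing),
                 offset_mm = as.numeric(offset_mm)),
            class = "fan_frame")
}

#' Fan sweep: an ordered list of frames
#'
#' All frames must share shape and spacing. Frames with missing angles
#' (`NA`) are filled by linear interpolation between the nearest known
#' angles, with a warning.
#'
#' @param frames list of [fan_frame()]s.
#' @export
fan_sweep <- function(frames) {
  if (!length(frames)) stop("empty sweep")
  stopifnot(all(vapply(frames, inherits, logical(1), "fan_frame")))
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims != dims[, 1])) stop("all frames must share pixel dimensions")
  sp <- vapply(frames, function(f) f$in_plane_spacing, numeric(2))
  if (any(abs(sp - sp[, 1]) > 1e-12)) stop("all frames must share spacing")
  ang <- vapply(frames, function(f) f$angle_deg, numeric(1))
  if (anyNA(ang)) {
    known <- which(!is.na(ang))
    if (length(known) < 2) stop("need at least two known frame angles")
    warning("missing frame angles interpolated from neighbours")
    ang <- approx(known, ang[known], xout = seq_along(ang), rule = 2)$y
    for (i in seq_along(frames)) frames[[i]]$angle_deg <- ang[i]
  }
  monotone <- all(diff(ang) > 0) || all(diff(ang) < 0)
  structure(list(frames = frames, monotone = monotone),
            class = "fan_sweep")
}

#' @export
length.fan_sweep <- function(x) length(x$frames)

#' @export
print.fan_sweep <- function(x, ...) {
  ang <- vapply(x$frames, function(f) f$angle_deg, numeric(1))
  cat(sprintf("<fan_sweep> %d frames of %d x %d px, angles %.1f..%.1f deg\n",
              length(x$frames), nrow(x$frames[[1]]$pixels),
              ncol(x$frames[[1]]$pixels), min(ang), max(ang)))
  invisible(x)
}

#' Map frame pixel indices to world coordinates
#'
#' @param frame a [fan_frame()].
#' @param u depth index (0-based, may be fractional).
#' @param v along-probe index (0-based, may be fractional); recycled
#'   against `u`.
#' @return n x 3 matrix of world mm points.
#' @export
frame_pixel_to_world <- function(frame, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  dm <- dim(frame$pixels)
  if (any(u < 0 | u > dm[1] - 1) || any(v < 0 | v > dm[2] - 1))
    stop("pixel index out of frame bounds")
  su <- frame$in_plane_spacing[1]; sv <- frame$in_plane_spacing[2]
  r <- u * su + frame$offset_mm
  th <- frame$angle_deg * pi / 180
  cbind(x = v * sv, y = r * sin(th), z = r * cos(th))
}

#' Reconstruct a parallel-plane volume from a fan sweep
#'
#' Every frame pixel is placed in 3D; parallel sagittal planes spaced
#' `plane_spacing_mm` along y are populated with all samples landing
#' within `bin_halfwidth_mm` of the plane. Multiple samples in one voxel
#' bin are averaged (arithmetic mean: unbiased and order-independent).
#' Remaining holes inside the sampled support are filled per plane by
#' separable 1D linear interpolation along the depth then along-probe
#' directions, with no extrapolation beyond contributed samples; voxels
#' outside the support keep the background value 0, recorded in the
#' volume metadata.
#'
#' The output grid keeps the native in-plane spacing: voxel spacing is
#' `(sv, plane_spacing_mm, su)` on (x, y, z).
#'
#' @param sweep a [fan_sweep()].
#' @param plane_spacing_mm plane spacing along y (> 0), default 1.
#' @param bin_halfwidth_mm half-width of the y bin (> 0), default 0.5.
#' @param fill_holes fill in-plane holes by gridded interpolation.
#' @return an [image_volume()] with an extra logical `support` array
#'   marking voxels that received (or interpolated between) samples.
#' @export
reconstruct_volume <- function(sweep, plane_spacing_mm = 1,
                               bin_halfwidth_mm = 0.5, fill_holes = TRUE) {
  stopifnot(inherits(sweep, "fan_sweep"))
  if (plane_spacing_mm <= 0 || bin_halfwidth_mm <= 0)
    stop("plane spacing and bin halfwidth must be > 0")
  fr1 <- sweep$frames[[1]]
  su <- fr1$in_plane_spacing[1]; sv <- fr1$in_plane_spacing[2]
  off <- fr1$offset_mm
  nu <- nrow(fr1$pixels); nv <- ncol(fr1$pixels)
  r <- (0:(nu - 1)) * su + off
  ang <- vapply(sweep$frames, function(f) f$angle_deg, numeric(1))
  # one row per (pixel, plane) assignment
  parts <- vector("list", length(sweep$frames))
  for (i in seq_along(sweep$frames)) {
    th <- ang[i] * pi / 180
    y <- r * sin(th); z <- r * cos(th)
    jlo <- ceiling((y - bin_halfwidth_mm) / plane_spacing_mm - 1e-9)
    jhi <- floor((y + bin_halfwidth_mm) / plane_spacing_mm + 1e-9)
    iz <- as.integer(round(z / su))
    val <- sweep$frames[[i]]$pixels          # nu x nv
    reps <- pmax(jhi - jlo + 1L, 0L)
    uidx <- rep(seq_len(nu), reps)           # depth index per assignment
    j <- unlist(lapply(seq_len(nu), function(k)
      if (reps[k] > 0) jlo[k]:jhi[k] else integer(0)), use.names = FALSE)
    if (!length(uidx)) next
    parts[[i]] <- data.table::data.table(
      j = rep(j, times = nv),
      iz = rep(iz[uidx], times = nv),
      ix = rep(seq_len(nv), each = length(uidx)),
      val = as.vector(val[uidx, ]))
  }
  dt <- data.table::rbindlist(parts)
  if (!nrow(dt)) stop("no samples fell within any plane bin")
  # deterministic within-bin order so the mean is independent of frame order
  data.table::setorder(dt, j, ix, iz, val)
  agg <- dt[, list(val = mean(val)), by = c("j", "ix", "iz")]
  jr <- range(agg$j); izr <- range(agg$iz); ixr <- range(agg$ix)
  ny <- jr[2] - jr[1] + 1L
  nz <- izr[2] - izr[1] + 1L
  nxo <- ixr[2] - ixr[1] + 1L
  if (ny == 1L && length(sweep$frames) > 1L &&
      length(unique(round(ang, 6))) == 1L)
    warning("all frames at identical angle: single-plane volume")
  vox <- array(NA_real_, c(nxo, ny, nz))
  vox[cbind(agg$ix - ixr[1] + 1L, agg$j - jr[1] + 1L,
            agg$iz - izr[1] + 1L)] <- agg$val
  support <- !is.na(vox)
  if (fill_holes) {
    for (p in seq_len(ny)) {
      plane <- vox[, p, ]
      if (all(is.na(plane))) next
      plane <- apply(plane, 1, fill_line_na)  # along z; result is [z, x]
      plane <- apply(plane, 1, fill_line_na)  # along x; result is [x, z]
      vox[, p, ] <- plane
    }
    support <- !is.na(vox)
  }
  vox[is.na(vox)] <- 0
  origin <- c((ixr[1] - 1) * sv, jr[1] * plane_spacing_mm, izr[1] * su)
  out <- image_volume(vox, c(sv, plane_spacing_mm, su), origin, background = 0)
  out$support <- support
  out
}

# Linear interpolation of interior NA runs of a vector; no extrapolation.
fill_line_na <- function(vals) {
  ok <- which(!is.na(vals))
  if (length(ok) < 2) return(vals)
  nas <- which(is.na(vals))
  nas <- nas[nas > ok[1] & nas < ok[length(ok)]]
  if (length(nas))
    vals[nas] <- approx(ok, vals[ok], xout = nas)$y
  vals
}
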