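# Smooth synthetic deformation fields.
#
# A deformation field stands in for tissue deformation between acquisitions:
# a smooth TPS (or affine) map p -> p + d(p), invertible on the gland
# support for the magnitudes simulated here. Because the TPS solution is
# linear in its displacement targets, the field is scaled exactly so that
# the maximum displacement over the stated support equals magnitude_mm.

#' Deformation field
#'
#' @param kind one of `"affine"`, `"tps"`, `"composite"`.
#' @param transform the underlying `coreg_transform` realising the forward map.
#' @param magnitude_mm maximum displacement over the support used to build it.
#' @export
deformation_field <- function(kind = c("tps", "affine", "composite"),
                              transform, magnitude_mm) {
  kind <- match.arg(kind)
  structure(list(kind = kind, transform = transform,
                 magnitude_mm = magnitude_mm,
                 dimension = transform_dimension(transform)),
            class = c("deformation_field", "coreg_transform"))
}

#' @export
apply_transform.deformation_field <- function(transform, points) {
  apply_transform(transform$transform, check_dim(transform, points))
}

#' Build a random smooth TPS deformation of given magnitude
#'
#' Control points are drawn uniformly in `bbox`; random control
#' displacements are rescaled (exactly, by TPS linearity) so that the
#' maximum displacement over `support_points` plus a dense sample of the
#' box equals `magnitude_mm`.
#'
#' @param bbox 2 x d matrix, rows = lower and upper corners (mm).
#' @param magnitude_mm maximum displacement (mm); 0 gives the identity.
#' @param n_control number of TPS control points.
#' @param seed integer; fully determines the field.
#' @param support_points optional points that must respect the magnitude
#'   bound (e.g. fiducials).
#' @return a [deformation_field()].
#' @export
make_smooth_deformation <- function(bbox, magnitude_mm, n_control = 10,
                                    seed = 1, support_points = NULL) {
  bbox <- as.matrix(bbox)
  d <- ncol(bbox)
  if (magnitude_mm < 0) stop("magnitude_mm must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  ctrl <- sapply(seq_len(d), function(k) runif(n_control, bbox[1, k], bbox[2, k]))
  ctrl <- matrix(ctrl, ncol = d)
  raw <- matrix(rnorm(n_control * d), ncol = d)
  if (magnitude_mm == 0) raw[] <- 0
  tps <- fit_tps(ctrl, ctrl + raw, dimension = d)
  # dense probe sample of the box (+ any caller-supplied support points)
  m <- 7L
  grid <- as.matrix(expand.grid(lapply(seq_len(d), function(k)
    seq(bbox[1, k], bbox[2, k], length.out = m))))
  probe <- rbind(grid, if (!is.null(support_points)) as_point_matrix(support_points, d))
  disp <- apply_transform(tps, probe) - probe
  mx <- max(sqrt(rowSums(disp^2)))
  scale <- if (mx > 0) magnitude_mm / mx else 0
  tps <- fit_tps(ctrl, ctrl + raw * scale, dimension = d)
  deformation_field("tps", tps, magnitude_mm)
}

#' Invert a deformation field at given points
#'
#' Fixed-point iteration on `q <- p - d(q)`; converges for the smooth,
#' small-magnitude fields simulated here.
#'
#' @param field a [deformation_field()].
#' @param points n x d matrix of deformed-space points.
#' @param tol convergence tolerance (mm).
#' @param maxit iteration cap.
#' @export
invert_deformation <- function(field, points, tol = 1e-6, maxit = 100) {
  pts <- check_dim(field, points)
  q <- pts
  for (it in seq_len(maxit)) {
    disp <- apply_transform(field, q) - q
    qn <- pts - disp
    if (max(abs(qn - q)) < tol) return(qn)
    q <- qn
  }
  warning("deformation inversion did not reach tolerance")
  q
}

# Numerical invertibility check used by the MRI simulator: forward then
# inverse must return within tol (default 0.01 mm) at the probe points.
check_invertible <- function(field, points, tol = 0.01) {
  fwd <- apply_transform(field, points)
  back <- invert_deformation(field, fwd)
  max(sqrt(rowSums((back - points)^2))) <= tol
}

# Save/restore the global RNG state so seeded simulators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
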