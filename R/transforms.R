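# Transform classes and the thin-plate-spline solver.
#
# All transforms act on n x d point matrices via apply_transform(). The
# stored chain from micro-ultrasound to whole-mount pathology is a
# composite_transform whose elements are applied in order.

#' Rigid transform (rotation + translation)
#'
#' @param rotation d x d rotation matrix (orthogonal, det +1).
#' @param translation length-d translation vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  stopifnot(ncol(rotation) == d, length(translation) == d)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 dimension = d),
            class = c("rigid_transform", "coreg_transform"))
}

#' Identity transform
#' @param dimension 2 or 3.
#' @export
identity_transform <- function(dimension = 3) {
  rigid_transform(diag(dimension), rep(0, dimension))
}

#' 2D similarity transform (scale, rotation, translation)
#'
#' Reflection is disallowed (`scale > 0`, proper rotation), matching the
#' in-plane "rigid + scaling" alignment used before the capsule TPS.
#'
#' @param scale positive scalar.
#' @param rotation_deg rotation angle, degrees, counter-clockwise.
#' @param translation mm pair.
#' @export
similarity_transform_2d <- function(scale, rotation_deg, translation) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 translation = as.numeric(translation), dimension = 2L),
            class = c("similarity_transform_2d", "coreg_transform"))
}

#' Composite transform (applied left to right)
#'
#' @param ... transforms of matching dimension.
#' @export
composite_transform <- function(...) {
  elements <- list(...)
  if (length(elements) == 1 && is.list(elements[[1]]) &&
      !inherits(elements[[1]], "coreg_transform"))
    elements <- elements[[1]]
  dims <- vapply(elements, transform_dimension, integer(1))
  if (length(unique(dims)) > 1) stop("composite elements differ in dimension")
  structure(list(elements = elements, dimension = dims[1]),
            class = c("composite_transform", "coreg_transform"))
}

#' @export
transform_dimension <- function(x) UseMethod("transform_dimension")
#' @export
transform_dimension.coreg_transform <- function(x) as.integer(x$dimension)

# ---- thin-plate spline -----------------------------------------------------

tps_kernel <- function(r, dimension) {
  if (dimension == 2) {
    u <- r^2 * log(r)
    u[r == 0] <- 0
    u
  } else {
    r
  }
}

#' Fit a thin-plate-spline landmark transform
#'
#' Solves the standard TPS interpolation system with polyharmonic kernel
#' `U(r) = r^2 log r` in 2D and `U(r) = r` in 3D. With `regularization = 0`
#' the warp maps each source control point exactly onto its target; the
#' side conditions (kernel weights sum to zero and have zero first moment)
#' hold by construction of the bordered linear system.
#'
#' @param source n x d matrix of source control points (mm).
#' @param target n x d matrix of target control points (mm).
#' @param dimension 2 or 3; defaults to `ncol(source)`.
#' @param regularization smoothing lambda >= 0 added to the kernel diagonal.
#' @return object of class `tps_transform` with fields `control`, `affine`
#'   (`(d+1) x d`, first row the intercept), `weights` (`n x d`), `lambda`.
#' @export
fit_tps <- function(source, target, dimension = ncol(as.matrix(source)),
                    regularization = 0) {
  d <- as.integer(dimension)
  if (!d %in% c(2L, 3L)) stop("dimension must be 2 or 3")
  X <- as_point_matrix(source, d)
  Y <- as_point_matrix(target, d)
  n <- nrow(X)
  if (nrow(Y) != n) stop("source and target must have equal point counts")
  if (n < d + 1) stop(sprintf("need at least %d control points", d + 1))
  if (regularization < 0) stop("regularization must be >= 0")
  D <- as.matrix(dist(X))
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop(sprintf("coincident control points %d and %d", dup[1, 1], dup[1, 2]))
  if (qr(cbind(1, X))$rank < d + 1)
    stop("degenerate control-point configuration (affinely dependent)")
  # solve in centred, unit-scaled source coordinates: the bordered system
  # is badly conditioned for landmarks spread over tens of mm and plain
  # solve() leaves ~1e-8 mm control residuals; normalisation plus one
  # refinement step keeps them below 1e-10 mm
  ctr <- colMeans(X)
  scl <- mean(sqrt(rowSums(sweep(X, 2, ctr)^2)))
  if (scl <= 0) scl <- 1
  Xn <- sweep(X, 2, ctr) / scl
  P <- cbind(1, Xn)
  K <- tps_kernel(as.matrix(dist(Xn)), d) + diag(regularization, n)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- rbind(Y, matrix(0, d + 1, d))
  lu <- qr(M, LAPACK = TRUE)
  sol <- solve(lu, rhs)
  sol <- sol + solve(lu, rhs - M %*% sol)
  structure(list(control = X, norm_center = ctr, norm_scale = scl,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + seq_len(d + 1), , drop = FALSE],
                 lambda = regularization, dimension = d),
            class = c("tps_transform", "coreg_transform"))
}

# ---- application -----------------------------------------------------------

#' Apply a transform (or stored chain) to a point set
#'
#' Applying a [composite_transform()] equals applying its elements in
#' sequence.
#'
#' @param transform a `coreg_transform` (rigid, similarity, TPS, composite,
#'   or deformation field).
#' @param points n x d matrix matching the transform dimension.
#' @return n x d matrix of transformed points.
#' @export
apply_transform <- function(transform, points) UseMethod("apply_transform")

check_dim <- function(transform, points) {
  d <- transform_dimension(transform)
  pts <- as_point_matrix(points, d)
  pts
}

#' @export
apply_transform.rigid_transform <- function(transform, points) {
  pts <- check_dim(transform, points)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @export
apply_transform.similarity_transform_2d <- function(transform, points) {
  pts <- check_dim(transform, points)
  a <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(transform$scale * pts %*% t(R), 2, transform$translation, "+")
}

#' @export
apply_transform.tps_transform <- function(transform, points) {
  pts <- check_dim(transform, points)
  ctr <- transform$norm_center %||% rep(0, transform$dimension)
  scl <- transform$norm_scale %||% 1
  ptsn <- sweep(pts, 2, ctr) / scl
  ctrln <- sweep(transform$control, 2, ctr) / scl
  out <- cbind(1, ptsn) %*% transform$affine
  n <- nrow(pts)
  chunk <- max(1L, floor(2e6 / nrow(ctrln)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    D <- cross_dist(ptsn[idx, , drop = FALSE], ctrln)
    out[idx, ] <- out[idx, ] +
      tps_kernel(D, transform$dimension) %*% transform$weights
  }
  out
}

#' @export
apply_transform.composite_transform <- function(transform, points) {
  pts <- check_dim(transform, points)
  for (el in transform$elements) pts <- apply_transform(el, pts)
  pts
}

# Pairwise Euclidean distances between rows of A (n x d) and B (m x d).
# Computed per column of B from explicit differences: the usual
# |a|^2+|b|^2-2ab expansion cancels catastrophically near r = 0, which
# matters because the TPS kernel is evaluated at its own control points.
cross_dist <- function(A, B) {
  m <- nrow(B)
  out <- matrix(0, nrow(A), m)
  for (j in seq_len(m)) {
    d2 <- (A[, 1] - B[j, 1])^2
    for (k in 2:ncol(A)) d2 <- d2 + (A[, k] - B[j, k])^2
    out[, j] <- sqrt(d2)
  }
  out
}
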