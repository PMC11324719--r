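# 3D landmark registration utilities: rigid initialization, TRE
# evaluation with outlier exclusion, and quadrature error combination.

#' Rigid initialization by centroid and principal axes
#'
#' Stands in for the manual visual alignment step: aligns centroids and
#' principal axes of the two corresponding capsule point sets (rotation +
#' translation, no scaling). The four proper-rotation sign assignments of
#' the principal axes are disambiguated by the summed squared point
#' distance; an externally supplied rigid transform may be used instead.
#'
#' @param moving_capsule_points n x 3 matrix.
#' @param fixed_capsule_points n x 3 matrix, corresponding order.
#' @return a [rigid_transform()] mapping moving onto fixed.
#' @export
initialize_alignment <- function(moving_capsule_points, fixed_capsule_points) {
  M <- as_point_matrix(moving_capsule_points, 3)
  F <- as_point_matrix(fixed_capsule_points, 3)
  if (nrow(M) < 3 || nrow(F) < 3) stop("need at least 3 points per set")
  if (nrow(M) != nrow(F)) stop("point sets must correspond (equal counts)")
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F, 2, cf)
  em <- eigen(stats::cov(Mc), symmetric = TRUE)
  ef <- eigen(stats::cov(Fc), symmetric = TRUE)
  if (em$values[2] < 1e-9 * max(em$values[1], 1) ||
      ef$values[2] < 1e-9 * max(ef$values[1], 1))
    stop("degenerate (collinear) point set")
  best <- NULL; best_cost <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    Vm <- em$vectors %*% diag(c(s1, s2, s3))
    R <- ef$vectors %*% t(Vm)
    if (det(R) < 0) next
    cost <- sum((Mc %*% t(R) - Fc)^2)
    if (cost < best_cost) { best_cost <- cost; best <- R }
  }
  rigid_transform(best, cf - as.numeric(best %*% cm))
}

#' Target registration error over evaluation landmark pairs
#'
#' Computes the Euclidean distance between each transformed moving
#' landmark and its fixed counterpart. Only evaluation landmarks (held
#' out from the warp fit) give a meaningful TRE: control points map
#' exactly under an interpolating TPS.
#'
#' @param moving n x d matrix of moving evaluation landmarks.
#' @param fixed n x d matrix of fixed evaluation landmarks.
#' @param transform transform applied to `moving` (`NULL` = identity).
#' @return object of class `tre_report` with `per_pair_mm`, `mean_mm`,
#'   `se_mm`, `excluded` (indices, empty here; see
#'   [exclude_tre_outliers()]).
#' @export
compute_tre <- function(moving, fixed, transform = NULL) {
  d <- ncol(as.matrix(moving))
  M <- as_point_matrix(moving, d)
  F <- as_point_matrix(fixed, d)
  if (nrow(M) == 0) stop("empty landmark pair list")
  if (nrow(M) != nrow(F)) stop("pair counts differ")
  if (!is.null(transform)) M <- apply_transform(transform, M)
  dist_mm <- sqrt(rowSums((M - F)^2))
  tre_report(dist_mm, excluded = integer(0))
}

tre_report <- function(per_pair_mm, excluded = integer(0)) {
  kept <- if (length(excluded)) per_pair_mm[-excluded] else per_pair_mm
  n <- length(kept)
  structure(list(per_pair_mm = per_pair_mm,
                 mean_mm = mean(kept),
                 se_mm = if (n > 1) sd(kept) / sqrt(n) else 0,
                 n = n, excluded = excluded),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> TRE %.2f +/- %.2f mm (mean +/- SE, n = %d%s)\n",
              x$mean_mm, x$se_mm, x$n,
              if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded))
              else ""))
  invisible(x)
}

#' Exclude TRE outliers beyond mean + k standard deviations
#'
#' A single pass: values `d_i > mean + k*sd` (mean and sd over all
#' inputs) are excluded. With fewer than 3 values no exclusion is
#' performed (warning).
#'
#' @param distances numeric vector of nonnegative distances.
#' @param k threshold multiplier, default 2.
#' @return list with `kept`, `excluded_indices`, `threshold`.
#' @export
exclude_tre_outliers <- function(distances, k = 2) {
  if (any(distances < 0)) stop("distances must be nonnegative")
  if (length(distances) < 3) {
    warning("fewer than 3 distances: no outlier exclusion performed")
    return(list(kept = distances, excluded_indices = integer(0),
                threshold = Inf))
  }
  thr <- mean(distances) + k * sd(distances)
  idx <- which(distances > thr)
  list(kept = if (length(idx)) distances[-idx] else distances,
       excluded_indices = idx, threshold = thr)
}

#' Combine per-step registration errors in quadrature
#'
#' Independent step errors combine as the square root of the sum of
#' squares, applied to the means and to the standard errors separately.
#'
#' @param step_means nonnegative mm vector.
#' @param step_ses nonnegative mm vector of equal length.
#' @return list with `mean_mm` and `se_mm`.
#' @export
combine_quadrature <- function(step_means, step_ses) {
  if (length(step_means) != length(step_ses)) stop("length mismatch")
  if (any(step_means < 0) || any(step_ses < 0)) stop("inputs must be nonnegative")
  list(mean_mm = sqrt(sum(step_means^2)), se_mm = sqrt(sum(step_ses^2)))
}
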