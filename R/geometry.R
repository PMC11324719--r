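# Internal geometry and raster helpers shared across modules.
# All coordinates are in mm unless a function says otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

as_point_matrix <- function(p, d) {
  if (is.null(dim(p))) p <- matrix(p, ncol = d)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != d)
    stop(sprintf("expected a %d-column point matrix, got %d columns", d, ncol(p)))
  if (any(!is.finite(p))) stop("point coordinates must be finite")
  p
}

# Signed polygon area (shoelace); positive for counter-clockwise rings.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(poly) {
  d <- sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), , drop = FALSE])^2))
  sum(d)
}

orient_ccw <- function(poly) {
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

polygon_centroid <- function(poly) {
  # area-weighted centroid of a simple polygon
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Even-odd point-in-polygon, vectorised over query points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Simplicity check: no two non-adjacent edges properly intersect.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_intersect(ring[i, ], ring[i + 1, ], ring[j, ], ring[j + 1, ]))
        return(FALSE)
    }
  }
  TRUE
}

# Resample a closed polygon to n points equally spaced in arc length.
# anchor = "posterior": start at the boundary point with minimum second
# coordinate (ties broken by minimum first coordinate); orientation is
# normalised counter-clockwise first.
resample_closed_polygon <- function(poly, n, anchor = c("posterior", "first"),
                                    dense = 4096) {
  anchor <- match.arg(anchor)
  poly <- orient_ccw(as_point_matrix(poly, 2))
  ring <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(ring)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate polygon with zero perimeter")
  at <- function(sq) {
    sq <- sq %% L
    cbind(approx(s, ring[, 1], xout = sq)$y,
          approx(s, ring[, 2], xout = sq)$y)
  }
  s0 <- 0
  if (anchor == "posterior") {
    sd_ <- seq(0, L, length.out = dense + 1)[-(dense + 1)]
    pd <- at(sd_)
    k <- which(pd[, 2] == min(pd[, 2]))
    if (length(k) > 1) k <- k[which.min(pd[k, 1])]
    s0 <- sd_[k]
    # parabolic refinement of the minimum between the neighbouring dense
    # samples, so the anchor does not quantise to the dense step
    step <- L / dense
    zm <- at(s0 - step)[2]; z0 <- pd[k, 2]; zp <- at(s0 + step)[2]
    den <- zm - 2 * z0 + zp
    # refine only at a genuine interior minimum; on a flat plateau (e.g.
    # the bottom edge of a square) the tie-broken vertex stands
    if (zm > z0 && zp > z0 && is.finite(den) && den > 1e-12) {
      delta <- 0.5 * step * (zm - zp) / den
      s0 <- s0 + max(-step / 2, min(step / 2, delta))
    }
  }
  at(s0 + (0:(n - 1)) * L / n)
}

# Resample an open polyline to points spaced ~spacing apart (includes ends).
polyline_resample <- function(pts, spacing) {
  pts <- as.matrix(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  sq <- seq(0, L, length.out = max(2L, ceiling(L / spacing) + 1L))
  out <- sapply(seq_len(ncol(pts)), function(k) approx(s, pts[, k], xout = sq)$y)
  matrix(out, ncol = ncol(pts))
}

convex_hull_polygon <- function(pts) {
  pts <- as_point_matrix(pts, 2)
  h <- chull(pts)
  orient_ccw(pts[h, , drop = FALSE])
}

ellipse_polygon <- function(center, semiaxes, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + semiaxes[1] * cos(th),
        center[2] + semiaxes[2] * sin(th))
}

# Cross-section of an axis-aligned ellipsoid by the plane x = x0.
# Returns NULL when the plane misses the ellipsoid (or is tangent).
ellipsoid_cross_section <- function(center, semiaxes, x0) {
  t <- (x0 - center[1]) / semiaxes[1]
  if (abs(t) >= 1) return(NULL)
  f <- sqrt(1 - t^2)
  list(center = center[2:3], semiaxes = semiaxes[2:3] * f)
}

# Regular raster grid of pixel centres covering [xlim] x [ylim].
make_raster_grid <- function(xlim, ylim, spacing) {
  x <- seq(xlim[1] + spacing / 2, xlim[2], by = spacing)
  y <- seq(ylim[1] + spacing / 2, ylim[2], by = spacing)
  list(x = x, y = y, spacing = spacing)
}

# Logical matrix [length(x) x length(y)]: pixel centre inside polygon.
rasterize_polygon <- function(poly, grid) {
  nx <- length(grid$x); ny <- length(grid$y)
  px <- rep(grid$x, times = ny)
  py <- rep(grid$y, each = nx)
  matrix(point_in_polygon(px, py, poly), nrow = nx, ncol = ny)
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

fnv1a32 <- function(txt) {
  # small stable content hash for report provenance (FNV-1a, 32-bit);
  # h is carried as a double, split into 16-bit halves for xor/multiply
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 65536; hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
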