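# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default phantom at 1 mm voxels; seed fixed for the whole suite.
fixture_scene <- function() {
  if (is.null(.fixtures$scene))
    .fixtures$scene <- generate_scene(phantom_spec(seed = 42))
  .fixtures$scene
}

# Coarse, fast sweep of the fixture scene (noise-free).
fixture_sweep <- function() {
  if (is.null(.fixtures$sweep))
    .fixtures$sweep <- simulate_fan_sweep(fixture_scene(), n_frames = 120,
                                          in_plane_spacing = c(1, 1),
                                          noise_sd = 0, seed = 7)
  .fixtures$sweep
}

gland_bbox <- function(scene) {
  rbind(scene$spec$gland_center - scene$spec$gland_semiaxes,
        scene$spec$gland_center + scene$spec$gland_semiaxes)
}

# Rotation matrix about the x axis (degrees).
rot_x <- function(deg) {
  a <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# A prostate-like teardrop: ellipse with a pronounced posterior vertex,
# so the posterior-most anchor is a stable material point under modest
# rotations.
teardrop_polygon <- function(n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 10 + 1.5 * cos(th)
  pts <- cbind(r * cos(th), 8 / 10 * r * sin(th))
  # pull the bottom vertex down into a sharp posterior notch
  k <- which.min(pts[, 2])
  pts[k, ] <- c(pts[k, 1], pts[k, 2] - 5)
  pts
}

# Independent dense TPS solve used as an oracle: raw (uncentred) bordered
# system, evaluated directly.
oracle_tps_predict <- function(src, tgt, probe, dimension = ncol(src)) {
  n <- nrow(src)
  U <- function(r) if (dimension == 2) ifelse(r > 0, r^2 * log(r), 0) else r
  K <- U(as.matrix(dist(src)))
  P <- cbind(1, src)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, dimension + 1, dimension + 1)))
  sol <- solve(M, rbind(tgt, matrix(0, dimension + 1, dimension)))
  w <- sol[1:n, , drop = FALSE]
  a <- sol[(n + 1):(n + dimension + 1), , drop = FALSE]
  D <- matrix(0, nrow(probe), n)
  for (j in 1:n)
    D[, j] <- sqrt(rowSums(sweep(probe, 2, src[j, ])^2))
  cbind(1, probe) %*% a + U(D) %*% w
}
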