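# Annotation transport: point-clouds, chain application, DBSCAN, ROIs.

make_frame <- function(nu = 60, nv = 60, angle = 0, sp = c(0.5, 0.5)) {
  fan_frame(matrix(0, nu, nv), angle, sp, offset_mm = 2)
}

test_that("polygon sampling is area-consistent and translation-covariant", {
  fr <- make_frame()
  # 10 x 10 mm square in pixel units (0.5 mm spacing -> 20 px)
  sq <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
  ann <- annotation_polygon(1, sq, "r1", "microUS")
  cl <- polygon_to_pointcloud(ann, fr, sample_spacing_mm = 1)
  expect_lt(abs(nrow(cl$points) - 100) / 100, 0.10)
  expect_equal(cl$reviewer_id, "r1")

  # translation changes coordinates, not the count
  ann2 <- annotation_polygon(1, sq + 7, "r1", "microUS")
  cl2 <- polygon_to_pointcloud(ann2, fr, 1)
  expect_equal(nrow(cl2$points), nrow(cl$points))
  expect_false(isTRUE(all.equal(cl$points, cl2$points)))

  degen <- annotation_polygon(1, rbind(c(1, 1), c(2, 2), c(3, 3)), "r1")
  expect_error(polygon_to_pointcloud(degen, fr, 1), "degenerate")
  outside <- annotation_polygon(1, sq + 500, "r1")
  expect_error(polygon_to_pointcloud(outside, fr, 1), "outside")
})

test_that("transform_chain partitions points, conserves counts, drops rest", {
  fr <- make_frame()
  sq <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
  cl <- polygon_to_pointcloud(annotation_polygon(1, sq, "r1", "microUS"), fr, 1)
  ident2 <- identity_transform(2)
  windows <- data.frame(slide_id = c("A", "B"), mri_x_mm = c(5, 12))
  out <- transform_chain(cl, identity_transform(3), windows,
                         list(A = ident2, B = ident2), mri_spacing_mm = 1.5)
  n_out <- sum(vapply(out$per_slide, nrow, integer(1)))
  expect_equal(n_out + out$n_dropped, nrow(cl$points))
  expect_equal(out$provenance$reviewer_id, "r1")
  # identity chain: per-slide output equals the input rows it claims
  x <- cl$points[, 1]
  inA <- abs(x - 5) <= 2.25 & (abs(x - 5) <= abs(x - 12) | abs(x - 12) > 2.25)
  expect_equal(nrow(out$per_slide$A), sum(inA))
  expect_equal(out$per_slide$A, cl$points[inA, 2:3], ignore_attr = TRUE)

  expect_error(transform_chain(cl, identity_transform(3), windows,
                               list(A = ident2), 1.5), "missing per-slide")
})

test_that("chained application equals stepwise application", {
  set.seed(61)
  src <- matrix(runif(30, 0, 50), 10)
  tps3 <- fit_tps(src, src + matrix(rnorm(30, 0, 2), 10))
  sim2 <- similarity_transform_2d(0.9, 12, c(1, -2))
  pts <- matrix(runif(3000, 0, 50), 1000)
  joint <- apply_transform(composite_transform(tps3,
                                               rigid_transform(rot_x(10), c(1, 1, 1))), pts)
  step <- apply_transform(rigid_transform(rot_x(10), c(1, 1, 1)),
                          apply_transform(tps3, pts))
  expect_lt(max(abs(joint - step)), 1e-9)
  p2 <- matrix(runif(200, -10, 10), 100)
  expect_lt(max(abs(apply_transform(composite_transform(sim2, sim2), p2) -
                      apply_transform(sim2, apply_transform(sim2, p2)))), 1e-9)
})

# Brute-force DBSCAN oracle: core rule + connected components of the
# eps-neighbourhood graph over cores; border points may attach to any
# cluster owning a core within eps.
oracle_dbscan <- function(pts, eps, min_pts) {
  skip_if_not_installed("igraph")
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  deg <- rowSums(D <= eps)          # includes self
  core <- deg >= min_pts
  g <- igraph::graph_from_adjacency_matrix(
    (D <= eps) & outer(core, core, "&"), mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  comp[!core] <- NA
  # candidate clusters per border point
  border_opts <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    unique(comp[core & D[i, ] <= eps])
  })
  list(core = core, comp = comp, border_opts = border_opts)
}

test_that("DBSCAN equals the brute-force neighbourhood-graph oracle", {
  expect_equal(dbscan_cluster(matrix(numeric(0), 0, 2), 1, 3)$clusters,
               list())
  # a chain of points within eps forms one cluster
  chain <- cbind(seq(0, 10, 0.5), 0)
  res <- dbscan_cluster(chain, eps_mm = 0.6, min_pts = 2)
  expect_length(res$clusters, 1)
  expect_equal(nrow(res$clusters[[1]]), nrow(chain))

  # two blobs + isolated point
  set.seed(62)
  pts <- rbind(matrix(rnorm(80, 0, 0.8), 40),
               matrix(rnorm(80, 10, 0.8), 40),
               c(30, 30))
  res2 <- dbscan_cluster(pts, 2, 5)
  expect_length(res2$clusters, 2)
  expect_true(any(attr(res2$noise, "indices") == 81))

  # seeded property suite against the oracle, n <= 500
  for (s in 1:12) {
    set.seed(100 + s)
    n <- sample(20:500, 1)
    k <- sample(1:4, 1)
    centers <- matrix(runif(2 * k, 0, 40), k)
    pts <- centers[sample(k, n, replace = TRUE), ] +
      matrix(rnorm(2 * n, 0, 1.2), n)
    eps <- runif(1, 0.5, 3); mp <- sample(2:8, 1)
    got <- dbscan_cluster(pts, eps, mp)
    ora <- oracle_dbscan(pts, eps, mp)
    labels <- integer(n)
    for (ci in seq_along(got$clusters))
      labels[attr(got$clusters[[ci]], "indices")] <- ci
    # noise agrees exactly: not core and no core neighbour within eps
    expect_equal(which(labels == 0),
                 unname(which(!ora$core & lengths(ora$border_opts) == 0)))
    # core partition agrees up to label permutation
    core_idx <- which(ora$core)
    expect_equal(length(unique(labels[core_idx])),
                 length(unique(ora$comp[core_idx])))
    tab <- table(labels[core_idx], ora$comp[core_idx])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # every border point is assigned to a legal owning cluster
    for (i in which(labels > 0 & !ora$core)) {
      owners <- ora$border_opts[[i]]
      owner_here <- unique(ora$comp[intersect(
        attr(got$clusters[[labels[i]]], "indices"), core_idx)])
      expect_true(length(intersect(owners, owner_here)) >= 1)
    }
  }
})

test_that("clusters become convex-hull ROIs with provenance", {
  grid <- as.matrix(expand.grid(x = seq(0, 5, 0.5), y = seq(0, 4, 0.5)))
  rois <- clusters_to_rois(list(grid), "WM01",
                           list(reviewer_id = "r1", modality = "microUS",
                                subject_id = "s1"))
  expect_length(rois, 1)
  expect_lt(abs(abs(polygon_area(rois[[1]]$polygon)) - 20) / 20, 0.10)
  expect_equal(rois[[1]]$provenance$reviewer_id, "r1")
  expect_equal(rois[[1]]$slide_id, "WM01")

  expect_message(r2 <- clusters_to_rois(list(grid[1:2, ]), "WM01"),
                 "discarded")
  expect_length(r2, 0)
  two <- clusters_to_rois(list(grid, grid + 20), "WM02",
                          list(reviewer_id = "r2", modality = "pMRI",
                               subject_id = "s1"))
  expect_length(two, 2)
  expect_true(all(vapply(two, function(r) r$provenance$modality, "") == "pMRI"))
})

test_that("annotation centroid survives the ground-truth chain within 1 mm", {
  scene <- fixture_scene()
  sweep <- fixture_sweep()
  idx <- prostacoreg:::index_lesion_id(scene)
  polys <- trace_lesion_annotation(scene, sweep, idx, frame_stride = 2)
  expect_gt(length(polys), 3)
  clouds <- lapply(polys, function(p)
    polygon_to_pointcloud(p, sweep$frames[[p$frame_index]], 1))
  cloud <- merge_pointclouds(clouds)
  defo <- make_smooth_deformation(gland_bbox(scene), 4, seed = 9,
                                  support_points = scene$fiducials)
  wm <- suppressMessages(simulate_wm_slides(scene, seed = 5))
  windows <- data.frame(
    slide_id = vapply(wm$slides, `[[`, character(1), "slide_id"),
    mri_x_mm = vapply(wm$slides, `[[`, numeric(1), "x_center"))
  truth2d <- setNames(lapply(wm$slides, `[[`, "truth_transform"),
                      windows$slide_id)
  # ground-truth chain: deformation (US -> MRI), then per-slide truth;
  # but WM truth maps scene coords, so compose with the deformation inverse
  out <- transform_chain(cloud, NULL, windows, truth2d, 1.5)
  ls <- scene$spec$lesion_specs[[idx]]
  for (sid in names(out$per_slide)) {
    sl <- wm$slides[[which(windows$slide_id == sid)]]
    les <- Filter(function(l) l$lesion_id == idx, sl$lesions)
    if (!length(les)) next
    if (abs(sl$x_center - ls$center[1]) > 0.7 * ls$semiaxes[1]) next
    got <- colMeans(out$per_slide[[sid]])
    want <- polygon_centroid(les[[1]]$polygon)
    expect_lt(sqrt(sum((got - want)^2)), 1)
  }
  # conservation through the chain
  n_out <- sum(vapply(out$per_slide, nrow, integer(1)))
  expect_equal(n_out + out$n_dropped, nrow(cloud$points))
})
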