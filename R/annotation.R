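# Annotation transport: polygons drawn on native fan frames become 3D
# point-clouds, travel through the stored transform chain into per-slide
# 2D coordinates, and are condensed into outlined regions of interest
# with DBSCAN.

#' Reviewer annotation polygon on a native frame
#'
#' @param frame_index 1-based index of the frame within its sweep.
#' @param vertices n x 2 polygon in frame pixel coordinates `(u, v)`
#'   (0-based depth row, along-probe column), n >= 3.
#' @param reviewer_id label.
#' @param modality one of `"microUS"`, `"pMRI"`, `"rMRI"`.
#' @param subject_id label.
#' @export
annotation_polygon <- function(frame_index, vertices, reviewer_id,
                               modality = c("microUS", "pMRI", "rMRI"),
                               subject_id = "subject") {
  modality <- match.arg(modality)
  vertices <- as_point_matrix(vertices, 2)
  if (nrow(vertices) < 3) stop("annotation polygon needs at least 3 vertices")
  structure(list(frame_index = as.integer(frame_index), vertices = vertices,
                 reviewer_id = reviewer_id, modality = modality,
                 subject_id = subject_id),
            class = "annotation_polygon")
}

annotation_provenance <- function(ann) {
  list(reviewer_id = ann$reviewer_id, modality = ann$modality,
       subject_id = ann$subject_id)
}

#' Convert a frame annotation polygon to a 3D point-cloud
#'
#' The polygon interior is sampled on a regular grid of `sample_spacing_mm`
#' anchored at the polygon's own bounding box (so translating the polygon
#' within the frame preserves the sample count); each sample is mapped to
#' world coordinates through the frame geometry.
#'
#' @param annotation an [annotation_polygon()].
#' @param frame the [fan_frame()] it was drawn on.
#' @param sample_spacing_mm interior sample spacing, default 1 mm.
#' @return object of class `annotation_pointcloud`: `points` (n x 3 mm)
#'   plus provenance.
#' @export
polygon_to_pointcloud <- function(annotation, frame, sample_spacing_mm = 1) {
  stopifnot(inherits(annotation, "annotation_polygon"),
            inherits(frame, "fan_frame"))
  su <- frame$in_plane_spacing[1]; sv <- frame$in_plane_spacing[2]
  dm <- dim(frame$pixels)
  vtx <- annotation$vertices
  if (all(vtx[, 1] < 0) || all(vtx[, 1] > dm[1] - 1) ||
      all(vtx[, 2] < 0) || all(vtx[, 2] > dm[2] - 1))
    stop("annotation polygon lies fully outside the frame")
  # polygon in frame mm coordinates (depth, along-probe)
  poly_mm <- cbind(vtx[, 1] * su, vtx[, 2] * sv)
  if (abs(polygon_area(poly_mm)) < sample_spacing_mm^2 / 100)
    stop("degenerate annotation polygon (empty interior)")
  lo <- apply(poly_mm, 2, min); hi <- apply(poly_mm, 2, max)
  us <- seq(lo[1], hi[1], by = sample_spacing_mm)
  vs <- seq(lo[2], hi[2], by = sample_spacing_mm)
  gu <- rep(us, times = length(vs)); gv <- rep(vs, each = length(us))
  inside <- point_in_polygon(gu, gv, poly_mm)
  if (!any(inside)) stop("no interior samples: polygon smaller than spacing")
  u_idx <- gu[inside] / su; v_idx <- gv[inside] / sv
  keep <- u_idx >= 0 & u_idx <= dm[1] - 1 & v_idx >= 0 & v_idx <= dm[2] - 1
  pts <- frame_pixel_to_world(frame, u_idx[keep], v_idx[keep])
  structure(c(list(points = pts), annotation_provenance(annotation),
              list(frame_index = annotation$frame_index,
                   sample_spacing_mm = sample_spacing_mm)),
            class = "annotation_pointcloud")
}

#' Merge point-clouds with identical provenance
#' @param clouds list of `annotation_pointcloud`s.
#' @export
merge_pointclouds <- function(clouds) {
  stopifnot(length(clouds) > 0)
  prov <- lapply(clouds, function(cl)
    cl[c("reviewer_id", "modality", "subject_id")])
  if (length(unique(prov)) != 1)
    stop("refusing to merge point-clouds with different provenance")
  structure(c(list(points = do.call(rbind, lapply(clouds, `[[`, "points"))),
              prov[[1]],
              list(frame_index = NA_integer_,
                   sample_spacing_mm = clouds[[1]]$sample_spacing_mm)),
            class = "annotation_pointcloud")
}

#' Carry a point-cloud through the stored transform chain to WM slides
#'
#' Applies the 3D US-to-MRI transform, assigns each point to the WM slide
#' whose matched MRI window (`+/- window_factor * MRI spacing` about the
#' matched slice position) contains its axial coordinate (ties broken
#' toward the nearer window centre), then applies that slide's 2D
#' transform to the in-plane `(y, z)` coordinates. Points outside every
#' window are dropped and counted, so
#' `|input| = sum per-slide |output| + n_dropped`.
#'
#' @param cloud an [polygon_to_pointcloud()] result.
#' @param us_mri_transform 3D transform (TPS/rigid/composite).
#' @param slide_windows data.frame with columns `slide_id` and
#'   `mri_x_mm` (axial position of the matched MRI slice).
#' @param slide_transforms named list of 2D transforms keyed by slide_id.
#' @param mri_spacing_mm MRI slice spacing.
#' @param window_factor half-width of the match window in MRI slices,
#'   default 1.5 (covers a 4.5 mm section at 1.5 mm spacing).
#' @return list with `per_slide` (named list of n x 2 matrices),
#'   `n_dropped`, and `provenance`.
#' @export
transform_chain <- function(cloud, us_mri_transform, slide_windows,
                            slide_transforms, mri_spacing_mm = 1.5,
                            window_factor = 1.5) {
  stopifnot(inherits(cloud, "annotation_pointcloud"))
  pts <- cloud$points
  if (!is.null(us_mri_transform))
    pts <- apply_transform(us_mri_transform, pts)
  half <- window_factor * mri_spacing_mm
  centers <- slide_windows$mri_x_mm
  ids <- as.character(slide_windows$slide_id)
  dx <- abs(outer(pts[, 1], centers, "-"))
  dx[dx > half] <- NA
  assign <- apply(dx, 1, function(r) if (all(is.na(r))) NA_integer_
                                     else which.min(r))
  per_slide <- list()
  for (k in seq_along(ids)) {
    sel <- which(!is.na(assign) & assign == k)
    if (!length(sel)) next
    tr <- slide_transforms[[ids[k]]]
    if (is.null(tr))
      stop(sprintf("missing per-slide 2D transform for slide %s", ids[k]))
    per_slide[[ids[k]]] <- apply_transform(tr, pts[sel, 2:3, drop = FALSE])
  }
  list(per_slide = per_slide, n_dropped = sum(is.na(assign)),
       provenance = cloud[c("reviewer_id", "modality", "subject_id")])
}

#' DBSCAN clustering of a 2D point set
#'
#' Standard density-based clustering: a point with at least `min_pts`
#' neighbours within `eps_mm` (itself included) is a core point; clusters
#' are the density-connected components of core points, border points are
#' assigned to the first cluster that reaches them in a fixed scan order,
#' and the remainder is noise. Every input point lands in exactly one
#' cluster or in noise; the output is deterministic.
#'
#' @param points n x 2 matrix (n may be 0).
#' @param eps_mm neighbourhood radius (> 0).
#' @param min_pts core-point threshold (>= 1).
#' @return list with `clusters` (list of point matrices, with row-index
#'   attribute `indices`) and `noise` (matrix, attribute `indices`).
#' @export
dbscan_cluster <- function(points, eps_mm, min_pts = 5) {
  if (eps_mm <= 0) stop("eps_mm must be > 0")
  if (min_pts < 1) stop("min_pts must be >= 1")
  if (is.null(points) || NROW(points) == 0) {
    empty <- matrix(numeric(0), 0, 2)
    attr(empty, "indices") <- integer(0)
    return(list(clusters = list(), noise = empty))
  }
  pts <- as_point_matrix(points, 2)
  n <- nrow(pts)
  labels <- integer(n)            # 0 = unassigned/noise
  visited <- logical(n)
  nb <- neighbours_within(pts, eps_mm)
  core <- lengths(nb) >= min_pts
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (!core[i]) next
    cid <- cid + 1L
    labels[i] <- cid
    queue <- nb[[i]]
    qpos <- 1L
    while (qpos <= length(queue)) {
      q <- queue[qpos]; qpos <- qpos + 1L
      if (labels[q] == 0L) labels[q] <- cid
      if (!visited[q]) {
        visited[q] <- TRUE
        if (core[q]) queue <- c(queue, nb[[q]][labels[nb[[q]]] == 0L |
                                                 !visited[nb[[q]]]])
      }
    }
  }
  clusters <- lapply(seq_len(max(labels, 0L)), function(k) {
    idx <- which(labels == k)
    m <- pts[idx, , drop = FALSE]
    attr(m, "indices") <- idx
    m
  })
  idx0 <- which(labels == 0L)
  noise <- pts[idx0, , drop = FALSE]
  attr(noise, "indices") <- idx0
  list(clusters = clusters, noise = noise)
}

# eps-neighbour index lists (self included), chunked to bound memory.
neighbours_within <- function(pts, eps) {
  n <- nrow(pts)
  out <- vector("list", n)
  chunk <- max(1L, floor(4e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    D <- cross_dist(pts[idx, , drop = FALSE], pts)
    for (r in seq_along(idx)) out[[idx[r]]] <- which(D[r, ] <= eps)
  }
  out
}

#' Convert DBSCAN clusters into outlined regions of interest
#'
#' Each cluster with at least 3 non-collinear points becomes one ROI
#' whose polygon is the cluster's convex hull and whose mask is its
#' rasterization on a 0.2 mm grid; smaller or collinear clusters are
#' discarded with a message.
#'
#' @param clusters list of point matrices from [dbscan_cluster()].
#' @param slide_id slide identifier carried into each ROI.
#' @param provenance list(reviewer_id, modality, subject_id).
#' @param pixel_mm rasterization pixel size.
#' @return list of `region_of_interest` objects.
#' @export
clusters_to_rois <- function(clusters, slide_id, provenance = NULL,
                             pixel_mm = 0.2) {
  rois <- list()
  for (k in seq_along(clusters)) {
    pts <- clusters[[k]]
    if (nrow(pts) < 3) {
      message(sprintf("cluster %d discarded: fewer than 3 points", k))
      next
    }
    hull <- convex_hull_polygon(pts)
    if (nrow(hull) < 3 || abs(polygon_area(hull)) < 1e-9) {
      message(sprintf("cluster %d discarded: collinear points", k))
      next
    }
    rois[[length(rois) + 1]] <- region_of_interest(slide_id, hull,
                                                   provenance, pixel_mm)
  }
  rois
}

#' Region of interest on a WM slide
#'
#' @param slide_id slide identifier.
#' @param polygon closed simple polygon, n x 2 mm.
#' @param provenance list(reviewer_id, modality, subject_id) or NULL.
#' @param pixel_mm grid resolution for the stored mask.
#' @export
region_of_interest <- function(slide_id, polygon, provenance = NULL,
                               pixel_mm = 0.2) {
  polygon <- as_point_matrix(polygon, 2)
  if (nrow(polygon) < 3) stop("ROI polygon needs at least 3 vertices")
  structure(list(slide_id = slide_id, polygon = polygon,
                 provenance = provenance, pixel_mm = pixel_mm),
            class = "region_of_interest")
}
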