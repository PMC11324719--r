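# End-to-end orchestration of the synthetic pipeline:
# simulate -> reconstruct -> register (3D landmarks, then per-slide 2D
# capsule) -> map annotations -> evaluate. Every parameter that affects
# output lives in the config and is echoed (with a content hash) into the
# report, and all randomness derives from the single config seed, so a
# rerun with the same config is byte-identical.

#' Default pipeline configuration
#'
#' Defaults encode the stated acquisition world: a 300-frame fan sweep
#' with a 2 mm probe offset reconstructed at 1 mm plane spacing, MRI at
#' 1.5 mm slices under a smooth 4 mm deformation, 4.5 mm whole-mount
#' sections with 0.95 linear shrinkage and 3 mm per-slide deformation.
#'
#' @param seed integer master seed.
#' @return nested config list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    phantom = list(voxel_spacing = c(1, 1, 1), fiducial_count = 5),
    sweep = list(n_frames = 300, angle_range = c(-70, 70), offset_mm = 2,
                 in_plane_spacing = c(0.5, 0.5), noise_sd = 0.02),
    reconstruction = list(plane_spacing_mm = 1, bin_halfwidth_mm = 0.5),
    mri = list(slice_spacing_mm = 1.5, deformation_magnitude_mm = 4),
    wm = list(section_thickness_mm = 4.5, shrink_factor = 0.95,
              deformation_magnitude_mm = 3),
    registration = list(lambda = 0, n_capsule_landmarks = 8,
                        tps_control_stride = 4, outlier_k = 2),
    annotation = list(sample_spacing_mm = 1, frame_stride = 2,
                      eps_factor = 2, min_pts = 5,
                      reviewer_id = "sim_reviewer_1"),
    metrics = list(pixel_mm = 0.2, include_reviewers = NULL),
    version = as.character(utils::packageVersion("prostacoreg")))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Trace a lesion on native fan frames (simulated reviewer)
#'
#' Produces the annotation a reviewer would draw by exactly outlining a
#' phantom lesion's intersection with each native frame plane, in frame
#' pixel coordinates. Frames that miss the lesion yield no annotation.
#'
#' @param scene a [generate_scene()] result.
#' @param sweep the [fan_sweep()] acquired from it.
#' @param lesion_index which lesion to trace.
#' @param frame_stride trace every stride-th frame.
#' @param reviewer_id,subject_id provenance labels.
#' @return list of [annotation_polygon()]s.
#' @export
trace_lesion_annotation <- function(scene, sweep, lesion_index = 1,
                                    frame_stride = 1,
                                    reviewer_id = "sim_reviewer_1",
                                    subject_id = "phantom") {
  ls <- scene$spec$lesion_specs[[lesion_index]]
  out <- list()
  for (i in seq(1, length(sweep$frames), by = frame_stride)) {
    fr <- sweep$frames[[i]]
    su <- fr$in_plane_spacing[1]; sv <- fr$in_plane_spacing[2]
    nu <- nrow(fr$pixels); nv <- ncol(fr$pixels)
    th <- fr$angle_deg * pi / 180
    xg <- (0:(nv - 1)) * sv
    rg <- (0:(nu - 1)) * su + fr$offset_mm
    t1 <- ((xg - ls$center[1]) / ls$semiaxes[1])^2
    t2 <- ((rg * sin(th) - ls$center[2]) / ls$semiaxes[2])^2 +
          ((rg * cos(th) - ls$center[3]) / ls$semiaxes[3])^2
    Fm <- outer(t1, t2, "+")
    if (min(Fm) >= 1) next
    cl <- contourLines(xg, rg, Fm, levels = 1)
    if (!length(cl)) next
    # largest closed contour
    areas <- vapply(cl, function(c0) abs(polygon_area(cbind(c0$x, c0$y))),
                    numeric(1))
    c0 <- cl[[which.max(areas)]]
    u <- (c0$y - fr$offset_mm) / su
    v <- c0$x / sv
    u <- pmin(pmax(u, 0), nu - 1); v <- pmin(pmax(v, 0), nv - 1)
    if (length(u) < 3) next
    out[[length(out) + 1]] <- annotation_polygon(
      i, cbind(u, v), reviewer_id, "microUS", subject_id)
  }
  out
}

# Index lesion: highest grade group, ties broken by largest volume.
index_lesion_id <- function(scene) {
  specs <- scene$spec$lesion_specs
  gg <- vapply(specs, `[[`, numeric(1), "grade_group")
  vol <- vapply(specs, function(s) prod(s$semiaxes), numeric(1))
  order(-gg, -vol)[1]
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, reconstruct, register-us-mri, register-mri-wm,
#' map-annotations, and evaluate in order; returns (and optionally
#' writes) a single machine-readable report with both step TREs, their
#' quadrature combination, transition-zone Dice, and the detection /
#' pixel metrics for the traced index-lesion annotation.
#'
#' @param config a [default_pipeline_config()]-shaped list.
#' @param out_dir optional directory for the report and stage artifacts
#'   (transform JSONs, contour JSONs, ROI JSONs, correspondence CSV).
#' @return the report list, invisibly containing all stage objects in
#'   `attr(report, "objects")`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  # ---- simulate ----
  sim <- with_stage("phantom", {
    spec <- phantom_spec(voxel_spacing = config$phantom$voxel_spacing,
                         fiducial_count = config$phantom$fiducial_count,
                         seed = seed)
    scene <- generate_scene(spec)
    sweep <- do.call(simulate_fan_sweep,
                     c(list(scene = scene), config$sweep,
                       list(seed = (seed + 101) %% 2147483647)))
    list(scene = scene, sweep = sweep)
  })
  scene <- sim$scene; sweep <- sim$sweep

  recon <- with_stage("fan_reconstruction",
    reconstruct_volume(sweep, config$reconstruction$plane_spacing_mm,
                       config$reconstruction$bin_halfwidth_mm))

  # ---- MRI + 3D landmark registration ----
  usmri <- with_stage("landmark_registration", {
    ctr <- scene$spec$gland_center; a <- scene$spec$gland_semiaxes
    bbox <- rbind(ctr - a, ctr + a)
    defo <- make_smooth_deformation(
      bbox, config$mri$deformation_magnitude_mm, n_control = 10,
      seed = (seed + 202) %% 2147483647, support_points = scene$fiducials)
    mri <- simulate_mri_volume(scene, defo, config$mri$slice_spacing_mm)
    lm <- phantom_landmarks(scene, config$registration$n_capsule_landmarks)
    ctrl <- as.matrix(lm[lm$role == "control", c("x", "y", "z")])
    ctrl_fixed <- apply_transform(defo, ctrl)
    init <- initialize_alignment(ctrl, ctrl_fixed)
    tps <- fit_tps(apply_transform(init, ctrl), ctrl_fixed, dimension = 3,
                   regularization = config$registration$lambda)
    xf <- composite_transform(init, tps)
    tre_pre <- compute_tre(scene$fiducials, mri$landmarks)
    tre1 <- compute_tre(scene$fiducials, mri$landmarks, xf)
    list(mri = mri, deformation = defo, transform = xf,
         tre = tre1, tre_pre = tre_pre, landmarks = lm)
  })

  # ---- WM slides + per-slide capsule registration ----
  if (is.null(config$wm))
    stop("stage capsule_registration failed: missing WM contours",
         call. = FALSE)
  wmreg <- with_stage("capsule_registration", {
    wm <- simulate_wm_slides(
      scene, section_thickness_mm = config$wm$section_thickness_mm,
      shrink_factor = config$wm$shrink_factor,
      deformation_magnitude_mm = config$wm$deformation_magnitude_mm,
      seed = (seed + 303) %% 2147483647)
    mri_x <- vol_axis(usmri$mri$volume, 1)
    entries <- data.frame(
      wm_slide_id = vapply(wm$slides, `[[`, character(1), "slide_id"),
      mri_slice_index = vapply(wm$slides, function(s)
        which.min(abs(mri_x - s$x_center)), integer(1)))
    entries$mri_x_mm <- mri_x[entries$mri_slice_index]
    corr <- slide_correspondence(entries, config$mri$slice_spacing_mm,
                                 config$wm$section_thickness_mm)
    corr_check <- validate_slide_correspondence(corr)
    slide_transforms <- list(); dists <- c(); dice <- c()
    mri_contours <- list()
    for (s in wm$slides) {
      x_m <- entries$mri_x_mm[entries$wm_slide_id == s$slide_id]
      cs <- scene_cross_section(scene, x_m)
      if (is.null(cs)) next
      proj <- function(poly2) {
        p3 <- cbind(x_m, poly2)
        apply_transform(usmri$deformation, p3)[, 2:3, drop = FALSE]
      }
      mri_caps <- proj(cs$capsule)
      xf2 <- register_slice(mri_caps, s$capsule,
                            config$registration$tps_control_stride,
                            config$registration$lambda)
      slide_transforms[[s$slide_id]] <- xf2
      mri_contours[[s$slide_id]] <- mri_caps
      if (!is.null(cs$transition_zone) && !is.null(s$transition_zone))
        dice <- c(dice, transition_zone_dice(s$transition_zone,
                                             proj(cs$transition_zone), xf2,
                                             config$metrics$pixel_mm))
      if (!is.null(s$fiducials) && nrow(s$fiducials)) {
        mv <- usmri$mri$landmarks[rownames(s$fiducials), 2:3, drop = FALSE]
        d <- compute_tre(mv, s$fiducials, xf2)$per_pair_mm
        dists <- c(dists, d)
      }
    }
    excl <- exclude_tre_outliers(dists, config$registration$outlier_k)
    tre2 <- tre_report(dists, excl$excluded_indices)
    list(wm = wm, correspondence = corr, corr_check = corr_check,
         slide_transforms = slide_transforms, tre = tre2,
         dice = dice, mri_contours = mri_contours)
  })

  combined <- combine_quadrature(c(usmri$tre$mean_mm, wmreg$tre$mean_mm),
                                 c(usmri$tre$se_mm, wmreg$tre$se_mm))

  # ---- annotation transport ----
  ann <- with_stage("annotation_pipeline", {
    idx <- index_lesion_id(scene)
    polys <- trace_lesion_annotation(scene, sweep, idx,
                                     config$annotation$frame_stride,
                                     config$annotation$reviewer_id)
    if (!length(polys)) stop("traced lesion intersects no frame")
    clouds <- lapply(polys, function(p)
      polygon_to_pointcloud(p, sweep$frames[[p$frame_index]],
                            config$annotation$sample_spacing_mm))
    cloud <- merge_pointclouds(clouds)
    windows <- data.frame(
      slide_id = wmreg$correspondence$entries$wm_slide_id,
      mri_x_mm = wmreg$correspondence$entries$mri_x_mm)
    chain <- transform_chain(cloud, usmri$transform, windows,
                             wmreg$slide_transforms,
                             config$mri$slice_spacing_mm)
    eps <- config$annotation$eps_factor * config$annotation$sample_spacing_mm
    rois <- list()
    for (sid in names(chain$per_slide)) {
      cl <- dbscan_cluster(chain$per_slide[[sid]], eps,
                           config$annotation$min_pts)
      rois <- c(rois, clusters_to_rois(cl$clusters, sid, chain$provenance,
                                       config$metrics$pixel_mm))
    }
    list(index_lesion = idx, cloud = cloud, chain = chain, rois = rois)
  })

  # ---- evaluate ----
  ev <- with_stage("concordance_metrics", {
    idx <- ann$index_lesion
    lesions <- list()
    for (s in wmreg$wm$slides) for (l in s$lesions)
      lesions[[length(lesions) + 1]] <- lesion_cross_section(
        s$slide_id, l$lesion_id, l$polygon, l$grade_group,
        is_index = l$lesion_id == idx, pixel_mm = config$metrics$pixel_mm)
    hits_p <- detect_hits(lesions, ann$rois, "patient")
    hits_c <- detect_hits(lesions, ann$rois, "cross_section")
    # pixel metrics for the traced lesion: per slide, lesion cross-section
    # vs the union of same-slide ROIs, on a shared grid
    per_slide <- list()
    lesion_px <- 0; inter_px <- 0
    for (l in Filter(function(l) l$lesion_id == idx, lesions)) {
      r_here <- Filter(function(r) identical(r$slide_id, l$slide_id),
                       ann$rois)
      polys <- c(list(l$polygon), lapply(r_here, `[[`, "polygon"))
      masks <- shared_masks(polys, config$metrics$pixel_mm)
      lm_ <- masks[[1]]
      rm_ <- if (length(r_here)) Reduce(`|`, masks[-1])
             else array(FALSE, dim(lm_))
      per_slide[[l$slide_id]] <- list(
        overlap = overlap_percent(lm_, rm_),
        dice = if (sum(lm_) + sum(rm_) > 0) dice_percent(lm_, rm_) else NA,
        fp = if (sum(rm_) > 0) false_positive_percent(lm_, rm_) else NA)
      lesion_px <- lesion_px + sum(lm_)
      inter_px <- inter_px + sum(lm_ & rm_)
    }
    ovl <- vapply(per_slide, `[[`, numeric(1), "overlap")
    list(lesions = lesions, hits_patient = hits_p, hits_cross = hits_c,
         per_slide = per_slide,
         traced_overlap_pooled_pct = 100 * inter_px / lesion_px,
         traced_overlap_mean_pct = mean(ovl))
  })

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  report <- list(
    package_version = config$version,
    config = config,
    config_hash = fnv1a32(cfg_json),
    reconstruction = list(
      n_frames = length(sweep),
      n_planes = dim(recon$voxels)[2],
      plane_spacing_mm = config$reconstruction$plane_spacing_mm),
    tre = list(
      us_mri = list(mean_mm = usmri$tre$mean_mm, se_mm = usmri$tre$se_mm,
                    n = usmri$tre$n,
                    pre_registration_mean_mm = usmri$tre_pre$mean_mm),
      mri_wm = list(mean_mm = wmreg$tre$mean_mm, se_mm = wmreg$tre$se_mm,
                    n = wmreg$tre$n,
                    n_excluded = length(wmreg$tre$excluded)),
      combined = combined),
    transition_zone_dice = list(mean = mean(wmreg$dice),
                                se = if (length(wmreg$dice) > 1)
                                  sd(wmreg$dice) / sqrt(length(wmreg$dice))
                                else 0,
                                n = length(wmreg$dice)),
    correspondence_valid = wmreg$corr_check$valid,
    annotation = list(index_lesion = ann$index_lesion,
                      n_points = nrow(ann$cloud$points),
                      n_dropped = ann$chain$n_dropped,
                      n_rois = length(ann$rois)),
    detection = list(
      patient = ev$hits_patient$record,
      cross_section = ev$hits_cross$record,
      completely_false_rois = sum(ev$hits_cross$completely_false),
      n_rois = ev$hits_cross$n_rois),
    pixel_metrics = list(
      traced_overlap_pooled_pct = ev$traced_overlap_pooled_pct,
      traced_overlap_mean_pct = ev$traced_overlap_mean_pct,
      per_slide = ev$per_slide))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_transform_json(usmri$transform,
                         file.path(out_dir, "xform_us_mri.json"))
    for (sid in names(wmreg$slide_transforms))
      write_transform_json(wmreg$slide_transforms[[sid]],
                           file.path(out_dir,
                                     sprintf("xform_mri_%s.json", sid)))
    write_correspondence_csv(wmreg$correspondence,
                             file.path(out_dir, "correspondence.csv"))
    write_rois_json(ann$rois, file.path(out_dir, "rois.json"))
    write_landmarks_csv(usmri$landmarks, file.path(out_dir, "landmarks.csv"))
  }
  attr(report, "objects") <- list(scene = scene, sweep = sweep,
                                  recon = recon, usmri = usmri,
                                  wmreg = wmreg, ann = ann, ev = ev)
  invisible(report)
}
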