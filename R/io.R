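# Plain-text interchange: landmarks (CSV/JSON), contours (JSON),
# transforms (JSON), slide correspondence (CSV). Every file records the
# package coordinate convention so downstream consumers need no side
# channel. Volume containers are exported as JSON-described raw text
# rather than DICOM/NIfTI; see the methods vignette for the rationale.

coordinate_convention <- function() {
  paste("mm; x = probe long axis, y = left-right (plane stacking),",
        "z = distance from probe axis; right-handed")
}

#' Write / read landmarks
#'
#' CSV columns: name, role (control/evaluation), x, y, z (mm).
#'
#' @param landmarks data.frame with those columns.
#' @param path file path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(all(c("name", "role", "x", "y", "z") %in% names(landmarks)))
  write.csv(landmarks[, c("name", "role", "x", "y", "z")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  lm <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "role", "x", "y", "z") %in% names(lm)))
  lm
}

#' Write / read contour sets as JSON
#'
#' @param contours list of [capsule_contour()]s (or lists with slice_id,
#'   kind, vertices).
#' @param path file path.
#' @export
write_contours_json <- function(contours, path) {
  payload <- list(
    convention = coordinate_convention(),
    contours = lapply(contours, function(ct) list(
      slice_id = ct$slice_id, kind = ct$kind,
      vertices = unclass(contour_vertices(ct)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(length(payload$contours$slice_id)), function(i)
    capsule_contour(payload$contours$slice_id[i],
                    payload$contours$kind[i],
                    payload$contours$vertices[[i]]))
}

#' Serialize / restore a transform (or stored chain) as JSON
#'
#' @param transform any `coreg_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_list <- function(tr) {
  if (inherits(tr, "rigid_transform"))
    list(type = "rigid", rotation = unclass(tr$rotation),
         translation = tr$translation, dimension = tr$dimension)
  else if (inherits(tr, "similarity_transform_2d"))
    list(type = "similarity2d", scale = tr$scale,
         rotation_deg = tr$rotation_deg, translation = tr$translation)
  else if (inherits(tr, "tps_transform"))
    list(type = "tps", dimension = tr$dimension,
         control = unclass(tr$control), affine = unclass(tr$affine),
         weights = unclass(tr$weights), lambda = tr$lambda,
         norm_center = tr$norm_center, norm_scale = tr$norm_scale)
  else if (inherits(tr, "deformation_field"))
    list(type = "deformation", kind = tr$kind,
         magnitude_mm = tr$magnitude_mm,
         transform = transform_to_list(tr$transform))
  else if (inherits(tr, "composite_transform"))
    list(type = "composite",
         elements = lapply(tr$elements, transform_to_list))
  else stop("unknown transform class")
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

transform_from_list <- function(x) {
  switch(x$type,
    rigid = rigid_transform(matrix(unlist(x$rotation), x$dimension,
                                   x$dimension),
                            unlist(x$translation)),
    similarity2d = similarity_transform_2d(x$scale, x$rotation_deg,
                                           unlist(x$translation)),
    tps = structure(list(control = as_matrix_d(x$control, x$dimension),
                         norm_center = unlist(x$norm_center),
                         norm_scale = x$norm_scale,
                         weights = as_matrix_d(x$weights, x$dimension),
                         affine = as_matrix_d(x$affine, x$dimension),
                         lambda = x$lambda,
                         dimension = as.integer(x$dimension)),
                    class = c("tps_transform", "coreg_transform")),
    deformation = deformation_field(x$kind, transform_from_list(x$transform),
                                    x$magnitude_mm),
    composite = composite_transform(lapply(
      if (is.data.frame(x$elements)) split(x$elements, seq_len(nrow(x$elements)))
      else x$elements, transform_from_list)),
    stop("unknown transform type ", x$type))
}

as_matrix_d <- function(x, d) {
  m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
  storage.mode(m) <- "double"
  m
}

#' Write / read a slide-to-MRI correspondence table
#'
#' CSV columns: wm_slide_id, mri_slice_index (plus mri_x_mm when known).
#'
#' @param corr a [slide_correspondence()].
#' @param path file path.
#' @export
write_correspondence_csv <- function(corr, path) {
  write.csv(corr$entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence_csv
#' @param mri_slice_spacing_mm,wm_thickness_mm geometry the table refers to.
#' @export
read_correspondence_csv <- function(path, mri_slice_spacing_mm = 1.5,
                                    wm_thickness_mm = 4.5) {
  slide_correspondence(read.csv(path, stringsAsFactors = FALSE),
                       mri_slice_spacing_mm, wm_thickness_mm)
}

#' Export ROIs as JSON polygons
#'
#' @param rois list of [region_of_interest()]s.
#' @param path file path.
#' @export
write_rois_json <- function(rois, path) {
  payload <- list(
    convention = coordinate_convention(),
    rois = lapply(rois, function(r) list(
      slide_id = r$slide_id, polygon = unclass(r$polygon),
      provenance = r$provenance)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
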