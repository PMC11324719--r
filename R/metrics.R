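# Concordance metrics between reviewer ROIs and ground-truth lesion
# cross-sections: pixel-level overlap / false-positive / Dice /
# per-slide sensitivity, hit rules at patient and cross-section level
# with the grade-group >= 2 significance filter, and reviewer
# aggregation with optional area stratification.

#' Lesion cross-section on a WM slide
#'
#' @param slide_id slide identifier.
#' @param lesion_id lesion identifier (shared across its slides).
#' @param polygon closed 2D mm polygon of the cross-section.
#' @param grade_group ISUP grade group 1..5.
#' @param is_index whether this lesion is the subject's index lesion.
#' @param pixel_mm grid resolution used when a mask is rasterized.
#' @export
lesion_cross_section <- function(slide_id, lesion_id, polygon, grade_group,
                                 is_index = FALSE, pixel_mm = 0.2) {
  polygon <- as_point_matrix(polygon, 2)
  if (!grade_group %in% 1:5) stop("grade_group must be in 1..5")
  structure(list(slide_id = slide_id, lesion_id = lesion_id,
                 polygon = polygon, grade_group = as.integer(grade_group),
                 is_index = isTRUE(is_index), pixel_mm = pixel_mm,
                 area_mm2 = abs(polygon_area(polygon))),
            class = "lesion_cross_section")
}

# Rasterize a set of polygons on one shared grid covering them all.
shared_masks <- function(polys, pixel_mm = 0.2) {
  if (!length(polys)) stop("no polygons to rasterize")
  lo <- apply(do.call(rbind, polys), 2, min) - pixel_mm
  hi <- apply(do.call(rbind, polys), 2, max) + pixel_mm
  grid <- make_raster_grid(c(lo[1], hi[1]), c(lo[2], hi[2]), pixel_mm)
  lapply(polys, rasterize_polygon, grid = grid)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must share one raster grid")
}

#' Lesion overlap percentage
#'
#' `100 * |lesion n roi| / |lesion|`: how much of the lesion
#' cross-section the ROI encapsulates.
#'
#' @param lesion_mask,roi_mask logical matrices on the same grid.
#' @export
overlap_percent <- function(lesion_mask, roi_mask) {
  check_same_grid(lesion_mask, roi_mask)
  nl <- sum(lesion_mask)
  if (nl == 0) stop("empty lesion mask")
  100 * sum(lesion_mask & roi_mask) / nl
}

#' False-positive percentage
#'
#' `100 * (1 - |lesion n roi| / |roi|)`: the fraction of the ROI not
#' covering lesion, the surrogate for specificity at pixel granularity.
#'
#' @param lesion_mask union of lesion masks on the slide.
#' @param roi_mask ROI mask on the same grid; must be nonempty.
#' @export
false_positive_percent <- function(lesion_mask, roi_mask) {
  check_same_grid(lesion_mask, roi_mask)
  nr <- sum(roi_mask)
  if (nr == 0) stop("empty ROI mask")
  100 * (1 - sum(lesion_mask & roi_mask) / nr)
}

#' Dice percentage
#'
#' `100 * 2|A n B| / (|A| + |B|)`.
#'
#' @param lesion_mask,roi_mask logical matrices on the same grid; at
#'   least one nonempty.
#' @export
dice_percent <- function(lesion_mask, roi_mask) {
  check_same_grid(lesion_mask, roi_mask)
  tot <- sum(lesion_mask) + sum(roi_mask)
  if (tot == 0) stop("both masks empty")
  100 * 2 * sum(lesion_mask & roi_mask) / tot
}

#' Per-slide sensitivity
#'
#' `100 * |(U lesions) n (U rois)| / |U lesions|`; lesion foci on one
#' slide are grouped. Slides without lesions are not applicable (error
#' here; the caller skips them).
#'
#' @param lesion_masks list of logical matrices (same grid).
#' @param roi_masks list of logical matrices (same grid); may be empty.
#' @export
slide_sensitivity <- function(lesion_masks, roi_masks) {
  if (!length(lesion_masks)) stop("no lesions on slide")
  lu <- Reduce(`|`, lesion_masks)
  if (sum(lu) == 0) stop("empty lesion union")
  if (!length(roi_masks)) return(0)
  ru <- Reduce(`|`, roi_masks)
  check_same_grid(lu, ru)
  100 * sum(lu & ru) / sum(lu)
}

polys_intersect <- function(a, b, pixel_mm = 0.2) {
  m <- shared_masks(list(a, b), pixel_mm)
  any(m[[1]] & m[[2]])
}

#' Detection hits at patient or cross-section level
#'
#' Only clinically significant cross-sections (grade group >= 2) count.
#' At the patient level the single opportunity is the index lesion,
#' hit iff any ROI intersects any of its cross-sections ("any part of an
#' ROI" rule). At the cross-section level every significant
#' cross-section is an opportunity, hit iff any same-slide ROI
#' intersects it. Each ROI that intersects no significant cross-section
#' on its slide is flagged completely false.
#'
#' @param lesions list of [lesion_cross_section()]s for one subject.
#' @param rois list of [region_of_interest()]s for one subject/review.
#' @param level `"patient"` or `"cross_section"`.
#' @param provenance list(reviewer_id, modality, subject_id) echoed into
#'   the record (taken from the first ROI when NULL).
#' @return list with `record` (one-row data.frame: subject_id,
#'   reviewer_id, modality, level, hits, opportunities),
#'   `per_item` (logical hit per opportunity), `completely_false`
#'   (logical per ROI), `n_rois`.
#' @export
detect_hits <- function(lesions, rois, level = c("patient", "cross_section"),
                        provenance = NULL) {
  level <- match.arg(level)
  sig <- Filter(function(l) l$grade_group >= 2, lesions)
  if (is.null(provenance))
    provenance <- if (length(rois)) rois[[1]]$provenance else
      list(reviewer_id = NA, modality = NA, subject_id = NA)
  # ROI x significant-cross-section intersection table
  inter <- matrix(FALSE, nrow = length(rois), ncol = length(sig))
  if (length(rois) && length(sig)) {
    for (r in seq_along(rois)) for (s in seq_along(sig)) {
      if (!identical(rois[[r]]$slide_id, sig[[s]]$slide_id)) next
      inter[r, s] <- polys_intersect(rois[[r]]$polygon, sig[[s]]$polygon,
                                     rois[[r]]$pixel_mm)
    }
  }
  completely_false <- if (length(rois)) rowSums(inter) == 0 else logical(0)
  if (level == "patient") {
    idx <- vapply(sig, function(l) l$is_index, logical(1))
    if (!any(idx)) stop("no index lesion defined among significant lesions")
    per_item <- any(inter[, idx, drop = FALSE])
    hits <- as.integer(per_item); opp <- 1L
  } else {
    per_item <- if (length(sig)) colSums(inter) > 0 else logical(0)
    hits <- sum(per_item); opp <- length(sig)
  }
  record <- data.frame(subject_id = provenance$subject_id %||% NA,
                       reviewer_id = provenance$reviewer_id %||% NA,
                       modality = provenance$modality %||% NA,
                       level = level, hits = hits, opportunities = opp,
                       stringsAsFactors = FALSE)
  list(record = record, per_item = per_item,
       completely_false = completely_false, n_rois = length(rois))
}

#' Mean and standard error of percentages
#'
#' SE is `sd / sqrt(n)`; a single value reports SE 0 with a flag.
#'
#' @param pct numeric vector of percentages.
#' @return list(mean, se, n, single).
#' @export
mean_se_percent <- function(pct) {
  n <- length(pct)
  if (!n) stop("empty input")
  list(mean = mean(pct), se = if (n > 1) sd(pct) / sqrt(n) else 0,
       n = n, single = n == 1)
}

#' Aggregate detection records into a metrics report
#'
#' Per-group (reviewer or modality) detection rates are averaged with
#' standard error `sd/sqrt(n)` across group members; the pooled fraction
#' (total hits / total opportunities) is reported alongside, since with
#' few reviewers the two can differ. `include_reviewers`, when given, is
#' a declared inclusion config echoed into the report (e.g. dropping a
#' non-expert reviewer from the combined analysis).
#'
#' @param records data.frame with columns subject_id, reviewer_id,
#'   modality, level, hits, opportunities (rbind of [detect_hits()]
#'   records).
#' @param by `"reviewer"` or `"modality"`.
#' @param include_reviewers optional character vector of reviewer_ids
#'   kept in the aggregation.
#' @return list with `group_rates_pct` (per group-member rate),
#'   `mean_pct`, `se_pct`, `pooled_pct`, `hits`, `opportunities`, and the
#'   echoed `include_reviewers`.
#' @export
aggregate_detection <- function(records, by = c("reviewer", "modality"),
                                include_reviewers = NULL) {
  by <- match.arg(by)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!is.null(include_reviewers))
    records <- records[records$reviewer_id %in% include_reviewers, ,
                       drop = FALSE]
  if (!nrow(records)) stop("no records left after reviewer filter")
  key <- if (by == "reviewer") records$reviewer_id else records$modality
  groups <- split(records, key)
  rates <- vapply(groups, function(g)
    100 * sum(g$hits) / sum(g$opportunities), numeric(1))
  ms <- mean_se_percent(rates)
  list(group_rates_pct = rates, mean_pct = ms$mean, se_pct = ms$se,
       pooled_pct = 100 * sum(records$hits) / sum(records$opportunities),
       hits = sum(records$hits), opportunities = sum(records$opportunities),
       n_groups = ms$n, single_group = ms$single,
       include_reviewers = include_reviewers)
}

#' Stratify per-cross-section metric values by lesion area
#'
#' Default bins are quartiles of the observed cross-sectional areas
#' (declared in the output); explicit bin edges may be supplied.
#'
#' @param areas_mm2 lesion cross-section areas.
#' @param values metric values aligned with `areas_mm2`.
#' @param area_bins optional increasing vector of bin edges (mm^2)
#'   covering the data; `NULL` for observed quartiles.
#' @return data.frame with bin label, n, mean, se.
#' @export
stratify_by_area <- function(areas_mm2, values, area_bins = NULL) {
  stopifnot(length(areas_mm2) == length(values))
  if (is.null(area_bins))
    area_bins <- unique(quantile(areas_mm2, probs = seq(0, 1, 0.25)))
  area_bins[1] <- min(area_bins[1], min(areas_mm2))
  area_bins[length(area_bins)] <- max(area_bins[length(area_bins)],
                                      max(areas_mm2))
  bin <- cut(areas_mm2, area_bins, include.lowest = TRUE)
  out <- do.call(rbind, lapply(split(values, bin), function(v) {
    if (!length(v)) return(data.frame(n = 0L, mean = NA_real_, se = NA_real_))
    ms <- mean_se_percent(v)
    data.frame(n = ms$n, mean = ms$mean, se = ms$se)
  }))
  out$bin <- rownames(out)
  rownames(out) <- NULL
  out[, c("bin", "n", "mean", "se")]
}
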