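# Concordance metrics: pixel-level identities, hit rules, aggregation.

rand_mask_pair <- function(n = 64, p = 0.2) {
  a <- matrix(runif(n * n) < p, n)
  b <- matrix(runif(n * n) < p, n)
  list(a = a, b = b)
}

test_that("overlap, false-positive and dice match per-pixel counting", {
  a <- matrix(FALSE, 20, 20); a[5:14, 5:14] <- TRUE     # 100 px lesion
  b <- matrix(FALSE, 20, 20); b[10:19, 5:14] <- TRUE    # 100 px roi, 50 shared
  expect_equal(overlap_percent(a, b), 50)
  expect_equal(overlap_percent(a, a | b), 100)          # roi superset
  expect_equal(overlap_percent(a, !a & b), 0)           # disjoint
  expect_equal(false_positive_percent(a, b), 50)
  expect_equal(false_positive_percent(a, a & b), 0)     # roi inside lesion
  roi200 <- matrix(FALSE, 20, 20); roi200[1:10, 1:20] <- TRUE
  les <- matrix(FALSE, 20, 20); les[6:10, 1:10] <- TRUE # 50 px intersection
  expect_equal(false_positive_percent(les, roi200), 75)
  expect_equal(dice_percent(a, a), 100)
  expect_equal(dice_percent(a, !a & b), 0)
  expect_error(overlap_percent(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)),
               "empty lesion")
  expect_error(false_positive_percent(a, matrix(FALSE, 20, 20)), "empty ROI")
  expect_error(dice_percent(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               "both")

  # brute-force counting oracle + harmonic-mean identity on 100 pairs
  set.seed(71)
  tested <- 0
  while (tested < 100) {
    m <- rand_mask_pair()
    inter <- sum(m$a & m$b)
    if (sum(m$a) == 0 || sum(m$b) == 0 || inter == 0) next
    tested <- tested + 1
    O <- overlap_percent(m$a, m$b)
    P <- 100 - false_positive_percent(m$a, m$b)
    Dc <- dice_percent(m$a, m$b)
    expect_equal(O, 100 * inter / sum(m$a))
    expect_equal(Dc, 100 * 2 * inter / (sum(m$a) + sum(m$b)))
    expect_equal(Dc, 2 * O * P / (O + P))               # harmonic identity
    expect_true(all(c(O, P, Dc) >= 0 & c(O, P, Dc) <= 100))
    expect_lte(Dc, 100 * min(1, 2 * (O / 100) / (1 + O / 100)) + 1e-9)
  }
})

test_that("slide sensitivity groups lesion foci per slide", {
  f1 <- matrix(FALSE, 30, 30); f1[1:10, 1:10] <- TRUE
  f2 <- matrix(FALSE, 30, 30); f2[20:29, 20:29] <- TRUE
  roi <- f1
  expect_equal(slide_sensitivity(list(f1, f2), list(roi)), 50)
  expect_equal(slide_sensitivity(list(f1, f2), list(f1, f2)), 100)
  expect_equal(slide_sensitivity(list(f1), list()), 0)
  expect_error(slide_sensitivity(list(), list(roi)), "no lesions")
})

test_that("hit rules: any-overlap detection and completely-false ROIs", {
  les_idx <- lesion_cross_section("WM01", 1, ellipse_polygon(c(0, 0), c(5, 5)),
                                  grade_group = 3, is_index = TRUE)
  les_gg1 <- lesion_cross_section("WM02", 2, ellipse_polygon(c(0, 0), c(4, 4)),
                                  grade_group = 1)
  # ROI overlapping one sliver of the index lesion counts as a hit
  roi_hit <- region_of_interest("WM01", ellipse_polygon(c(4.8, 0), c(2, 2)),
                                list(reviewer_id = "r1", modality = "microUS",
                                     subject_id = "s1"))
  hp <- detect_hits(list(les_idx, les_gg1), list(roi_hit), "patient")
  expect_equal(hp$record$hits, 1)
  expect_equal(hp$record$opportunities, 1)
  expect_false(any(hp$completely_false))

  # ROI intersecting only a GG1 lesion is completely false
  roi_gg1 <- region_of_interest("WM02", ellipse_polygon(c(0, 0), c(2, 2)),
                                list(reviewer_id = "r1", modality = "microUS",
                                     subject_id = "s1"))
  hc <- detect_hits(list(les_idx, les_gg1), list(roi_gg1), "cross_section")
  expect_equal(hc$record$hits, 0)
  expect_equal(hc$record$opportunities, 1)   # only the significant lesion
  expect_true(all(hc$completely_false))

  # no ROIs: zero hits, opportunities unchanged
  h0 <- detect_hits(list(les_idx, les_gg1), list(), "cross_section",
                    provenance = list(reviewer_id = "r1",
                                      modality = "microUS",
                                      subject_id = "s1"))
  expect_equal(h0$record$hits, 0)
  expect_equal(h0$record$opportunities, 1)
  expect_length(h0$completely_false, 0)
  expect_error(detect_hits(list(les_gg1), list(), "patient",
                           provenance = list()), "index")

  # monotonicity: adding an ROI never decreases hits
  h1 <- detect_hits(list(les_idx, les_gg1), list(roi_gg1, roi_hit),
                    "cross_section")
  expect_gte(h1$record$hits, hc$record$hits)
})

test_that("reviewer aggregation reproduces rate means and pooled fractions", {
  rec <- data.frame(subject_id = "all",
                    reviewer_id = c("r1", "r2", "r3"),
                    modality = "microUS", level = "patient",
                    hits = c(7, 8, 7), opportunities = 8)
  agg <- aggregate_detection(rec, by = "reviewer")
  expect_equal(round(agg$mean_pct, 1), 91.7)
  expect_equal(round(agg$se_pct, 1), 4.2)
  expect_equal(agg$pooled_pct, 100 * 22 / 24)

  # reviewer inclusion config is honoured and echoed
  rec4 <- rbind(rec, data.frame(subject_id = "all", reviewer_id = "r4",
                                modality = "microUS", level = "patient",
                                hits = 4, opportunities = 8))
  agg2 <- aggregate_detection(rec4, by = "reviewer",
                              include_reviewers = c("r1", "r2", "r3"))
  expect_equal(round(agg2$mean_pct, 1), 91.7)
  expect_equal(agg2$include_reviewers, c("r1", "r2", "r3"))

  single <- aggregate_detection(rec[1, ], by = "reviewer")
  expect_equal(single$mean_pct, 87.5)
  expect_equal(single$se_pct, 0)
  expect_true(single$single_group)

  ms <- mean_se_percent(rep(42.0, 5))
  expect_equal(ms$mean, 42)
  expect_equal(ms$se, 0)
})

test_that("area stratification bins cross-sections and reports n/mean/se", {
  set.seed(72)
  areas <- runif(40, 1, 200)
  vals <- runif(40, 0, 100)
  tab <- stratify_by_area(areas, vals)
  expect_equal(sum(tab$n), 40)
  expect_true(all(tab$se >= 0))
  tab2 <- stratify_by_area(areas, vals, area_bins = c(0, 50, 100, 200))
  expect_equal(nrow(tab2), 3)
  expect_equal(sum(tab2$n), 40)
})
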