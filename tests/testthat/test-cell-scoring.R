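test_that("membrane assignment measures rings, half-rings and absence", {
  # empty skeleton: every cell unstained
  fx <- ring_fixture(arc_fraction = 1, od = 1.2)
  empty <- fx$skeleton
  empty$skeleton_mask[] <- FALSE
  empty$pixels <- empty$pixels[0, ]
  rec0 <- assign_membrane_to_cells(fx$nuclei, empty, fx$dab_od)
  expect_equal(rec0$membrane_mean_od, 0)
  expect_equal(rec0$completeness, 0)

  # full ring of OD 1.2 around the nucleus
  rec <- assign_membrane_to_cells(fx$nuclei, fx$skeleton, fx$dab_od)
  expect_equal(nrow(rec), 1L)
  expect_gte(rec$completeness, 0.95)
  expect_lt(abs(rec$membrane_mean_od - 1.2), 0.05)
  expect_equal(rec$membrane_area_px, sum(fx$skeleton$skeleton_mask))

  # half ring -> completeness about one half
  fx2 <- ring_fixture(arc_fraction = 0.5, od = 1.2)
  rec2 <- assign_membrane_to_cells(fx2$nuclei, fx2$skeleton, fx2$dab_od)
  expect_lt(abs(rec2$completeness - 0.5), 0.1)

  # no nuclei -> empty record list
  none <- nuclei_from_labels(matrix(0L, 64, 64))
  expect_equal(nrow(assign_membrane_to_cells(none, fx$skeleton,
                                             fx$dab_od)), 0L)
})

test_that("skeleton beyond the assignment radius is not attributed", {
  fx <- ring_fixture(ring_radius = 15, od = 1.0)
  rec <- assign_membrane_to_cells(fx$nuclei, fx$skeleton, fx$dab_od,
                                  max_radius_px = 4)
  expect_equal(rec$membrane_area_px, 0L)
  expect_equal(rec$completeness, 0)
})

test_that("cell classification follows the four-tier guideline logic", {
  t <- c(0.15, 0.40, 0.70)
  expect_equal(classify_cell(0, 0, t), 0L)
  expect_equal(classify_cell(0.1, 1, t), 0L)                # below t1
  expect_equal(classify_cell(0.2, 0.3, t), 1L)              # faint
  expect_equal(classify_cell(0.40, 0.9, t), 2L)             # left-closed t2
  expect_equal(classify_cell(0.69, 0.85, t), 2L)
  expect_equal(classify_cell(0.70, 1.0, t), 3L)             # left-closed t3
  expect_equal(classify_cell(0.95, 1.0, t), 3L)
  # strong but incomplete staining cannot be 2+/3+
  expect_equal(classify_cell(0.95, 0.3, t, complete_threshold = 0.8), 1L)
  expect_equal(classify_cell(0.5, 0.5, t), 1L)
  expect_error(classify_cells(0.5, 0.5, od_thresholds = c(0.4, 0.2, 0.7)),
               "increasing")
})

test_that("field score applies the proportion cut-offs", {
  expect_equal(field_score(rep(3, 100)), 3L)
  expect_equal(field_score(c(rep(3, 35), rep(0, 65))), 3L)  # 0.35 > 0.30
  expect_equal(field_score(c(rep(3, 30), rep(0, 70))), 2L)  # 0.30 not > 0.30
  expect_equal(field_score(c(rep(3, 5), rep(2, 20), rep(0, 75))), 2L)
  expect_equal(field_score(c(rep(1, 10), rep(0, 90))), 1L)
  expect_equal(field_score(c(rep(1, 9), rep(0, 91))), 0L)
  for (k in 0:3) expect_equal(field_score(rep(k, 50)), k)
  expect_error(field_score(integer(0)), "no cells")
})

test_that("H-score is the class-weighted percentage sum", {
  expect_equal(h_score(rep(0, 10)), 0)
  expect_equal(h_score(rep(3, 7)), 300)
  cls <- c(rep(1, 20), rep(2, 30), rep(3, 10), rep(0, 40))
  expect_equal(h_score(cls), 110)
  # raising any cell's class never lowers the H-score
  set.seed(8)
  for (i in 1:20) {
    cls <- sample(0:3, 50, replace = TRUE)
    j <- sample(which(cls < 3), 1)
    up <- cls; up[j] <- up[j] + 1L
    expect_gt(h_score(up), h_score(cls))
  }
})

test_that("LO-CMA sums skeleton area per class and conserves totals", {
  cells <- data.table::data.table(
    cell_id = 1:4, ihc_class = c(2L, 1L, 1L, 0L),
    membrane_area_px = c(120L, 30L, 25L, 0L))
  cma <- lo_cma(cells)
  expect_equal(cma$area_px, c(0, 55, 120, 0))
  expect_equal(sum(cma$area_px), sum(cells$membrane_area_px))
  cma_um <- lo_cma(cells, pixel_size_um = 0.5)
  expect_equal(cma_um$area_um2, cma$area_px * 0.25)
})

test_that("core aggregation pools cells across ROIs", {
  mk <- function(classes) {
    cells <- data.table::data.table(
      cell_id = seq_along(classes), ihc_class = classes,
      membrane_area_px = rep(10L, length(classes)))
    score_roi(cells)
  }
  one <- mk(rep(3, 40))
  core1 <- aggregate_core(list(one))
  expect_equal(core1$pooled$prop, one$prop)
  expect_equal(core1$core_field_score, one$field_score)

  two <- aggregate_core(list(mk(rep(3, 50)), mk(rep(0, 50))))
  expect_equal(two$pooled$n_cells, 100L)
  expect_equal(unname(two$pooled$prop["p3"]), 0.5)

  # max-ROI variant
  mx <- aggregate_core(list(mk(rep(3, 50)), mk(rep(0, 350))),
                       method = "max")
  expect_equal(mx$core_field_score, 3L)
})

test_that("recovered class proportions match a generated cohort design", {
  # draw cell-level measurements straight from the class design and
  # verify proportion recovery through classification + scoring
  set.seed(21)
  des <- class_design()
  p_true <- c(0.3, 0.2, 0.3, 0.2)
  n <- 400
  cls_true <- sample(0:3, n, replace = TRUE, prob = p_true)
  od <- des$membrane_od[cls_true + 1] + rnorm(n, 0, 0.02)
  comp <- pmin(1, pmax(0, des$completeness[cls_true + 1] +
                         rnorm(n, 0, 0.03)))
  got <- classify_cells(od, comp)
  expect_lt(max(abs(tabulate(got + 1, 4) / n -
                      tabulate(cls_true + 1, 4) / n)), 0.05)
})
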