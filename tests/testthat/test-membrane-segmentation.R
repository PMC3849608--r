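test_that("a constant image is one spot with no borders", {
  p <- partition_spots(matrix(5, 30, 30), smoothing_sigma = 0)
  expect_equal(p$n_spots, 1L)
  expect_equal(nrow(p$edges), 0L)
})

test_that("a dark line splits two plateaus and the border sits on it", {
  img <- matrix(1, 24, 24)
  img[, 12] <- 0 # dark vertical line: the membrane mid-line
  p <- partition_spots(img, smoothing_sigma = 0)
  expect_equal(p$n_spots, 2L)
  cols <- (p$border_pixels$px - 1L) %/% 24L # 0-based column
  expect_true(all(abs(cols - 11) <= 1))
})

test_that("a ring cell yields interior/exterior spots split on the ring", {
  h <- 64
  dy <- outer(seq_len(h) - 1 - 31.5, rep(1, h))
  dx <- outer(rep(1, h), seq_len(h) - 1 - 31.5)
  dist <- sqrt(dy^2 + dx^2)
  dab <- matrix(0, h, h)
  dab[abs(dist - 15) <= 1.2] <- 0.9
  p <- partition_spots(-dab, smoothing_sigma = 1, dab_od = dab)
  pm <- merge_spots(p)
  inner <- pm$spot_labels[32, 32]
  outer_lab <- pm$spot_labels[2, 2]
  expect_false(inner == outer_lab)
  bp <- pm$border_pixels[(pm$border_pixels$a == min(inner, outer_lab) &
                            pm$border_pixels$b == max(inner, outer_lab)), ]
  r <- (bp$px - 1L) %% h; c <- (bp$px - 1L) %/% h
  radial <- sqrt((r - 31.5)^2 + (c - 31.5)^2)
  expect_true(all(abs(radial - 15) <= 1.5))
})

test_that("partition matches the brute-force steepest-ascent oracle", {
  set.seed(99)
  for (rep in 1:5) {
    x <- matrix(round(runif(15 * 12), 2), 15, 12)
    p <- partition_spots(x, smoothing_sigma = 0)
    oracle <- brute_force_basins(x)
    # same partition up to label naming
    expect_equal(length(unique(as.vector(p$spot_labels))),
                 length(unique(as.vector(oracle))))
    key <- paste(p$spot_labels, oracle)
    expect_equal(length(unique(key)),
                 length(unique(as.vector(oracle))))
  }
})

test_that("undersized spots merge into their longest-border neighbour", {
  # 10 x 10 map: spot 2 has area 5 and its longest border is with spot 1
  labels <- matrix(1L, 10, 10)
  labels[, 6:10] <- 3L
  labels[5, 4:6] <- 2L
  labels[6, 5:6] <- 2L
  od <- matrix(0, 10, 10)
  p <- partition_from_labels(labels, od)
  m <- merge_spots(p, min_spot_area = 20, min_border_length = 0)
  expect_equal(m$n_spots, 2L)
  # spot 2's pixels joined spot 1 (relabelled 1 after compaction)
  expect_equal(unique(as.vector(m$spot_labels[5, 4:5])), 1L)

  # a partition already above thresholds is a fixed point
  ok <- partition_from_labels(matrix(rep(1:2, each = 50), 10, 10), od)
  m2 <- merge_spots(ok, min_spot_area = 20, min_border_length = 5)
  expect_equal(m2$spot_labels, ok$spot_labels)
})

test_that("a chain of tiny spots collapses to a single spot", {
  labels <- matrix(rep(1:8, each = 24), 12, 16) # 8 strips of 24 px
  od <- matrix(0, 12, 16)
  p <- partition_from_labels(labels, od)
  m <- merge_spots(p, min_spot_area = 30, min_border_length = 0)
  expect_equal(m$n_spots, 1L)
  expect_equal(sum(tabulate(m$spot_labels)), 12 * 16) # pixel conservation
})

test_that("merging dissolves borders lying over nuclei", {
  labels <- matrix(1L, 20, 20)
  labels[, 11:20] <- 2L
  od <- matrix(0, 20, 20)
  p <- partition_from_labels(labels, od)

  # nucleus covering the full border -> spots merged
  nuc <- matrix(0L, 20, 20); nuc[, 9:12] <- 1L
  m <- merge_over_nuclei(p, nuclei_from_labels(nuc),
                         over_nucleus_threshold = 0.5)
  expect_equal(m$n_spots, 1L)

  # nucleus far from the border -> unchanged
  nuc2 <- matrix(0L, 20, 20); nuc2[1:4, 1:4] <- 1L
  m2 <- merge_over_nuclei(p, nuclei_from_labels(nuc2),
                          over_nucleus_threshold = 0.5)
  expect_equal(m2$spot_labels, p$spot_labels)

  # fraction below threshold -> retained
  nuc3 <- matrix(0L, 20, 20); nuc3[1:6, 9:12] <- 1L # ~30% of border
  m3 <- merge_over_nuclei(p, nuclei_from_labels(nuc3),
                          over_nucleus_threshold = 0.5)
  expect_equal(m3$n_spots, 2L)
})

test_that("skeleton extraction subtracts nuclei and filters segments", {
  # vertical border of length 40 with high OD
  labels <- matrix(1L, 40, 20)
  labels[, 11:20] <- 2L
  od <- matrix(0, 40, 20)
  bdr <- partition_from_labels(labels, od)$border_pixels$px
  od[bdr] <- 0.8
  p <- partition_from_labels(labels, od)
  none <- nuclei_from_labels(matrix(0L, 40, 20))

  sk <- extract_skeleton(p, none, min_segment_length = 10,
                         min_mean_od = 0.1)
  expect_equal(nrow(sk$segments), 1L)
  expect_equal(sk$segments$length, 40L)
  expect_equal(sk$segments$mean_dab_od, 0.8)

  # 10 border pixels inside a nucleus -> 30 retained
  nuc <- matrix(0L, 40, 20)
  nuc[16:25, 9:12] <- 1L
  sk2 <- extract_skeleton(p, nuclei_from_labels(nuc),
                          min_segment_length = 5, min_mean_od = 0.1)
  expect_equal(sum(sk2$segments$length), 30L)

  # intensity filter removes everything
  od0 <- matrix(0, 40, 20); od0[bdr] <- 0.05
  p0 <- partition_from_labels(labels, od0)
  sk3 <- extract_skeleton(p0, none, min_segment_length = 10,
                          min_mean_od = 0.1)
  expect_equal(nrow(sk3$segments), 0L)
  expect_false(any(sk3$skeleton_mask))
})

test_that("border OD measurement is the arithmetic mean along pixels", {
  od <- matrix(0, 8, 8)
  od[3, 3] <- 0.2; od[4, 3] <- 0.6; od[5:8, 5] <- 0.9
  segs <- data.table::data.table(
    segment = c(1L, 1L, 2L, 2L, 2L, 2L),
    px = c(which(row(od) == 3 & col(od) == 3),
           which(row(od) == 4 & col(od) == 3),
           which(row(od) >= 5 & col(od) == 5)))
  m <- measure_border_od(segs, od)
  expect_equal(m$mean_dab_od[m$segment == 1], 0.4)
  expect_equal(m$mean_dab_od[m$segment == 2], 0.9)
  expect_error(measure_border_od(segs[0, ], od), "empty")
})

test_that("pixels are conserved and spot counts are monotone", {
  set.seed(5)
  x <- matrix(runif(40 * 40), 40, 40)
  dab <- matrix(runif(40 * 40, 0, 0.3), 40, 40)
  p <- partition_spots(-dab + 0.2 * x, smoothing_sigma = 1, dab_od = dab)
  expect_equal(sum(tabulate(p$spot_labels)), 1600)
  m <- merge_spots(p, min_spot_area = 15, min_border_length = 4)
  expect_equal(sum(tabulate(m$spot_labels)), 1600)
  expect_lte(m$n_spots, p$n_spots)
  nuc <- matrix(0L, 40, 40); nuc[15:22, 15:22] <- 1L
  m2 <- merge_over_nuclei(m, nuclei_from_labels(nuc), 0.5)
  expect_lte(m2$n_spots, m$n_spots)
  expect_equal(sum(tabulate(m2$spot_labels)), 1600)
  sk_loose <- extract_skeleton(m2, nuclei_from_labels(nuc),
                               min_segment_length = 1, min_mean_od = 0)
  sk_tight <- extract_skeleton(m2, nuclei_from_labels(nuc),
                               min_segment_length = 8, min_mean_od = 0.1)
  expect_lte(sum(sk_tight$skeleton_mask), sum(sk_loose$skeleton_mask))
})
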