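test_that("tile generator bookkeeping matches its own design", {
  tile <- generate_tile(n_cells = 1, class_proportions = c(0, 0, 0, 1),
                        image_size = c(96, 96), noise_sigma = 0, seed = 2)
  expect_equal(tile$truth$intended_field_score, 3L)
  expect_equal(tile$truth$intended_h_score, 300)
  expect_equal(nrow(tile$truth$cells), 1L)

  tile2 <- generate_tile(n_cells = 200, seed = 3,
                         nucleus_radius = 5, cell_radius = 10)
  counts <- tabulate(tile2$truth$cells$ihc_class + 1, 4)
  expect_equal(sum(counts), 200)
  expect_equal(unname(tile2$truth$proportions), counts / 200)
  expect_equal(tile2$truth$intended_h_score,
               100 * sum(0:3 * counts / 200))
  # masks are disjoint
  expect_false(any(tile2$truth$nucleus_mask & tile2$truth$membrane_mask))
})

test_that("tile generation is deterministic under the seed", {
  a <- generate_tile(n_cells = 30, seed = 11)
  b <- generate_tile(n_cells = 30, seed = 11)
  expect_identical(a$image, b$image)
  expect_equal(a$truth$cells, b$truth$cells)
  c <- generate_tile(n_cells = 30, seed = 12)
  expect_false(identical(a$image, c$image))
})

test_that("infeasible packing requests fail cleanly", {
  expect_error(generate_tile(n_cells = 500, image_size = c(128, 128),
                             seed = 1), "infeasible")
  expect_error(generate_tile(n_cells = 10,
                             class_proportions = c(0.5, 0.5, 0.5, -0.5)),
               "proportions")
})

test_that("score pair generator hits its designed agreement", {
  # diagonal joint: perfect agreement
  D <- diag(c(0.4, 0.2, 0.2, 0.2))
  sp <- generate_score_pairs(200, D, seed = 4)
  expect_true(all(sp$a == sp$b))
  expect_equal(sp$expected_kappa, 1)

  # independence joint: kappa near zero at large n
  m <- c(0.4, 0.3, 0.2, 0.1)
  I <- outer(m, m)
  spI <- generate_score_pairs(10000, I, seed = 5)
  expect_equal(spI$expected_kappa, 0, tolerance = 1e-12)
  kI <- cohen_kappa(confusion(spI$a, spI$b), "asymptotic")$kappa
  expect_lt(abs(kI), 0.05)

  # closed-form expectation equals the pair-counting oracle in the limit
  # of the joint itself (scaled to a count table)
  P <- default_agreement_joint()
  expect_equal(generate_score_pairs(10, P, seed = 1)$expected_kappa,
               cohen_kappa(P * 1e6, "asymptotic")$kappa,
               tolerance = 1e-9)

  expect_error(generate_score_pairs(10, matrix(1, 4, 4)), "probability")
})

test_that("sampled kappa concentrates around the population value", {
  P <- default_agreement_joint()
  ktrue <- kappa_from_joint(P)
  ks <- sapply(1:20, function(i) {
    sp <- generate_score_pairs(400, P, seed = 100 + i)
    cohen_kappa(confusion(sp$a, sp$b), "asymptotic")$kappa
  })
  expect_lt(abs(mean(ks) - ktrue), 0.03)
})

test_that("cohort generator is seeded, shaped and effect-controlled", {
  coh <- generate_cohort(9, 6, seed = 7)
  expect_equal(nrow(coh), 15L)
  expect_equal(sum(coh$fish_status == "FISH+"), 6L)
  expect_equal(ncol(coh), 8L) # id, group, six features
  expect_true(all(coh$her2_2plus_ratio >= 0 & coh$her2_2plus_ratio <= 1))
  expect_identical(coh, generate_cohort(9, 6, seed = 7))
  expect_false(identical(coh, generate_cohort(9, 6, seed = 8)))

  null_coh <- generate_cohort(20, 20, effect = "null", seed = 9)
  expect_equal(unname(attr(null_coh, "true_effects")), rep(0, 6))
  expect_error(generate_cohort(1, 6), ">= 2")
})
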