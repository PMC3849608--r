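test_that("confusion tabulates pairs and validates input", {
  t1 <- confusion(c(3, 3, 0), c(3, 3, 0))
  expect_equal(t1["3", "3"], 2)
  expect_equal(t1["0", "0"], 1)
  expect_equal(sum(t1), 3)
  t2 <- confusion(c(0, 1), c(1, 0))
  expect_equal(t2["0", "1"], 1)
  expect_equal(t2["1", "0"], 1)
  expect_error(confusion(c(0, 1), c(0, 1, 2)), "equal length")
  expect_error(confusion(c(0, 5), c(0, 1)), "levels")
})

test_that("Cohen's kappa matches hand-computed values", {
  # perfect agreement across >= 2 categories
  tab <- confusion(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(cohen_kappa(tab, "asymptotic")$kappa, 1)

  # independence-product table -> kappa 0
  rowp <- c(0.5, 0.1, 0.2, 0.2); colp <- c(0.25, 0.25, 0.25, 0.25)
  ind <- outer(rowp, colp) * 400
  expect_lt(abs(cohen_kappa(ind, "asymptotic")$kappa), 1e-9)

  # [[45,5],[5,45]] embedded in classes {0,3}: po=0.9, pe=0.5, k=0.8
  tab <- matrix(0, 4, 4, dimnames = list(0:3, 0:3))
  tab[1, 1] <- 45; tab[1, 4] <- 5; tab[4, 1] <- 5; tab[4, 4] <- 45
  k <- cohen_kappa(tab, "asymptotic")
  expect_equal(k$kappa, 0.8, tolerance = 1e-12)
  expect_true(k$ci_low <= 0.8 && 0.8 <= k$ci_high)

  # degenerate: a single category on both margins
  one <- matrix(0, 4, 4); one[2, 2] <- 50
  expect_error(cohen_kappa(one), "undefined")
})

test_that("quadratic weights reproduce the printed clinical weights", {
  w <- quadratic_weights(4)
  expect_true(isTRUE(all.equal(w, t(w))))
  expect_equal(diag(w), rep(1, 4))
  expect_equal(w[1, 2], 8 / 9)
  expect_equal(w[1, 3], 5 / 9)
  expect_equal(w[1, 4], 0)
  expect_equal(round(unique(as.vector(w)), 2), c(1, 0.89, 0.56, 0))
  expect_error(quadratic_weights(1), ">= 2")
})

test_that("weighted kappa generalizes Cohen's kappa", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(16, 6), 4, 4)
    if (sum(diag(tab)) == sum(tab)) tab[1, 2] <- tab[1, 2] + 1
    k0 <- cohen_kappa(tab, "asymptotic")$kappa
    kI <- weighted_kappa(tab, diag(4), "asymptotic")$kappa
    expect_equal(kI, k0, tolerance = 1e-12)
  }
  # diagonal table: weighted kappa 1
  dtab <- diag(c(10, 20, 5, 15))
  expect_equal(weighted_kappa(dtab, ci_method = "asymptotic")$kappa, 1)
  # adjacent-only disagreement is discounted by quadratic weights
  adj <- matrix(0, 4, 4)
  diag(adj) <- 20
  adj[cbind(1:3, 2:4)] <- 5; adj[cbind(2:4, 1:3)] <- 5
  kw <- weighted_kappa(adj, quadratic_weights(4), "asymptotic")$kappa
  ku <- cohen_kappa(adj, "asymptotic")$kappa
  expect_gt(kw, ku)
})

test_that("table-based kappa equals pair-counting over raw vectors", {
  set.seed(23)
  for (i in 1:20) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- ifelse(runif(60) < 0.7, a, sample(0:3, 60, replace = TRUE))
    tab <- confusion(a, b)
    expect_equal(cohen_kappa(tab, "asymptotic")$kappa,
                 kappa_pair_counting(a, b), tolerance = 1e-12)
    w <- quadratic_weights(4)
    expect_equal(weighted_kappa(tab, w, "asymptotic")$kappa,
                 kappa_pair_counting(a, b, w = w), tolerance = 1e-12)
  }
})

test_that("the bootstrap interval brackets the point estimate", {
  sp <- generate_score_pairs(120, seed = 5)
  tab <- confusion(sp$a, sp$b)
  k <- cohen_kappa(tab, "bootstrap", n_boot = 500, seed = 9)
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
  # seeded: identical on repeat
  k2 <- cohen_kappa(tab, "bootstrap", n_boot = 500, seed = 9)
  expect_identical(k[c("kappa", "ci_low", "ci_high")],
                   k2[c("kappa", "ci_low", "ci_high")])
})

test_that("Landis-Koch bands label kappa strength", {
  expect_equal(landis_koch(0.857), "almost perfect")
  expect_equal(landis_koch(0.5), "moderate")
  expect_equal(landis_koch(-0.1), "poor")
  expect_equal(landis_koch(c(0.1, 0.3, 0.7)),
               c("slight", "fair", "substantial"))
  expect_error(landis_koch(1.2), "\\[-1, 1\\]")
})

test_that("Spearman correlation with Fisher-z interval", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_ci(x, x)$rho, 1)
  expect_equal(spearman_ci(x, -x)$rho, -1)
  r <- spearman_ci(x, c(1, 2, 3, 5, 4))
  expect_equal(r$rho, 0.9)                      # 1 - 6*2/(5*24)
  expect_equal(r$rho, unname(cor(x, c(1, 2, 3, 5, 4),
                                 method = "spearman")))
  expect_true(r$ci_low < 0.9 && 0.9 < r$ci_high)
  expect_error(spearman_ci(rep(1, 5), x), "constant")
  expect_error(spearman_ci(1:3, 1:3), "at least 4")
})

test_that("group comparison reports moments and a two-sided p-value", {
  f <- data.frame(a = c(1, 2, 3, 4, 10, 20, 30, 40),
                  b = c(0, 0, 0, 0, 1, 1, 1, 1) + rep(c(0, 1e-3), 4))
  g <- rep(c("FISH-", "FISH+"), each = 4)
  res <- group_compare(f, g)
  expect_equal(nrow(res), 2L)
  expect_equal(res$`mean_FISH-`[1], 2.5)
  expect_lt(res$p_value[res$feature == "b"], 0.01)

  # identical groups: Mann-Whitney p = 1
  f2 <- data.frame(x = rep(c(1, 2, 3), 2))
  res2 <- group_compare(f2, rep(c("A", "B"), each = 3),
                        test = "mann-whitney")
  expect_equal(res2$p_value, 1)

  # constant feature flagged degenerate with p = 1
  res3 <- group_compare(data.frame(x = rep(2, 6)),
                        rep(c("A", "B"), each = 3))
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)

  expect_error(group_compare(f, rep("A", 8)), "two levels")
  expect_error(group_compare(f, c(rep("A", 7), "B")), "at least 2")
})
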