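#' Cross-tabulate two ordinal score vectors
#'
#' @param scores_a,scores_b equal-length vectors of scores in `levels`.
#' @param levels ordered category levels (default `0:3`).
#' @return k x k integer matrix of counts, rows = rater A, columns =
#'   rater B, dimnames = levels.
#' @export
confusion <- function(scores_a, scores_b, levels = 0:3) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length")
  if (length(scores_a) < 1L) stop("empty score vectors")
  if (!all(scores_a %in% levels) || !all(scores_b %in% levels))
    stop("scores outside the category levels ", paste(levels, collapse = ","))
  k <- length(levels)
  ia <- match(scores_a, levels)
  ib <- match(scores_b, levels)
  m <- matrix(tabulate((ib - 1L) * k + ia, nbins = k * k), k, k,
              dimnames = list(levels, levels))
  m
}

# kappa point estimate from a count table and weight matrix
kappa_stat <- function(tab, w) {
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  pe <- outer(pr, pc)
  do <- sum((1 - w) * p)
  de <- sum((1 - w) * pe)
  if (de <= .Machine$double.eps)
    stop("kappa undefined: expected agreement is 1 (single category used)")
  1 - do / de
}

# Fleiss-Cohen-Everitt asymptotic variance of (weighted) kappa
kappa_asymptotic_se <- function(tab, w) {
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  pe_w <- sum(w * outer(pr, pc))
  po_w <- sum(w * p)
  k <- (po_w - pe_w) / (1 - pe_w)
  wi <- as.vector(w %*% pc)    # E_j w_ij over column margin
  wj <- as.vector(pr %*% w)    # E_i w_ij over row margin
  term <- outer(wi, wj, function(a, b) a + b)
  v <- (sum(p * (w - term * (1 - k))^2) -
          (k - pe_w * (1 - k))^2) / (n * (1 - pe_w)^2)
  sqrt(max(v, 0))
}

# multinomial bootstrap over cases from the observed table
kappa_bootstrap_ci <- function(tab, w, n_boot, conf_level, seed) {
  n <- sum(tab)
  k <- nrow(tab)
  pvec <- as.vector(tab) / n
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draws <- stats::rmultinom(n_boot, n, pvec)
  kb <- apply(draws, 2L, function(cnt) {
    tryCatch(kappa_stat(matrix(cnt, k, k), w), error = function(e) NA_real_)
  })
  a <- (1 - conf_level) / 2
  stats::quantile(kb, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

new_agreement_result <- function(kappa, ci, weighted, weights, n, method) {
  structure(list(kappa = kappa, ci_low = ci[1], ci_high = ci[2],
                 weighted = weighted, weights = weights, n = n,
                 ci_method = method,
                 strength_label = landis_koch(kappa)),
            class = "agreement_result")
}

#' Cohen's kappa with confidence interval
#'
#' Chance-corrected agreement between two raters:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed diagonal
#' proportion and `pe` the product-margin expectation. The default 95%
#' interval is a seeded nonparametric bootstrap over cases (percentile,
#' 2000 resamples); the Fleiss-Cohen asymptotic interval is available.
#'
#' @param tab square count matrix from [confusion()].
#' @param ci_method `"bootstrap"` (default) or `"asymptotic"`.
#' @param conf_level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap (default 20130930).
#' @return An `agreement_result`: `kappa`, `ci_low`, `ci_high`,
#'   `weighted`, `weights`, `n`, `strength_label` (Landis-Koch).
#' @export
cohen_kappa <- function(tab, ci_method = c("bootstrap", "asymptotic"),
                        conf_level = 0.95, n_boot = 2000, seed = 20130930) {
  ci_method <- match.arg(ci_method)
  check_pair_table(tab)
  w <- diag(nrow(tab))
  k <- kappa_stat(tab, w)
  ci <- kappa_ci(tab, w, k, ci_method, conf_level, n_boot, seed)
  new_agreement_result(k, ci, FALSE, w, sum(tab), ci_method)
}

#' Quadratic disagreement weights
#'
#' `w[i, j] = 1 - (i - j)^2 / (k - 1)^2` for categories `0..k-1`: full
#' credit on the diagonal, 8/9 (0.89) for one-step disagreement, 5/9
#' (0.56) for two steps and 0 for the extreme 0-vs-3+ disagreement when
#' `k = 4`.
#'
#' @param k number of ordered categories (>= 2; default 4).
#' @return k x k symmetric weight matrix with unit diagonal.
#' @export
quadratic_weights <- function(k = 4) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) stop("k must be >= 2")
  i <- seq_len(k) - 1
  1 - outer(i, i, function(a, b) (a - b)^2) / (k - 1)^2
}

#' Weighted kappa
#'
#' `kappa_w = 1 - sum((1 - w) * p_obs) / sum((1 - w) * p_exp)`. With the
#' identity weight matrix this reduces exactly to Cohen's kappa; with
#' [quadratic_weights()] near-miss disagreements are discounted.
#'
#' @inheritParams cohen_kappa
#' @param weights symmetric weight matrix with unit diagonal and entries
#'   in \[0, 1\] (default [quadratic_weights()] of the table size).
#' @return An `agreement_result` with `weighted = TRUE`.
#' @export
weighted_kappa <- function(tab, weights = quadratic_weights(nrow(tab)),
                           ci_method = c("bootstrap", "asymptotic"),
                           conf_level = 0.95, n_boot = 2000,
                           seed = 20130930) {
  ci_method <- match.arg(ci_method)
  check_pair_table(tab)
  if (!isTRUE(all.equal(weights, t(weights))) ||
      any(abs(diag(weights) - 1) > 1e-12) ||
      any(weights < -1e-12 | weights > 1 + 1e-12))
    stop("weights must be symmetric with unit diagonal and entries in [0,1]")
  k <- kappa_stat(tab, weights)
  ci <- kappa_ci(tab, weights, k, ci_method, conf_level, n_boot, seed)
  new_agreement_result(k, ci, TRUE, weights, sum(tab), ci_method)
}

kappa_ci <- function(tab, w, k, ci_method, conf_level, n_boot, seed) {
  if (ci_method == "bootstrap") {
    kappa_bootstrap_ci(tab, w, n_boot, conf_level, seed)
  } else {
    se <- kappa_asymptotic_se(tab, w)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    c(max(-1, k - z * se), min(1, k + z * se))
  }
}

check_pair_table <- function(tab) {
  if (!is.matrix(tab) || nrow(tab) != ncol(tab))
    stop("tab must be a square count matrix")
  if (any(tab < 0) || sum(tab) < 1) stop("tab must hold counts with n > 0")
  invisible(tab)
}

#' Landis-Koch verbal interpretation of kappa
#'
#' @param kappa numeric value(s) in \[-1, 1\].
#' @return character: "poor" (< 0), "slight" (0-0.20), "fair"
#'   (0.21-0.40), "moderate" (0.41-0.60), "substantial" (0.61-0.80) or
#'   "almost perfect" (0.81-1.00).
#' @export
landis_koch <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1 | kappa > 1))
    stop("kappa must lie in [-1, 1]")
  cut_pts <- c(-1, 0, 0.20, 0.40, 0.60, 0.80, 1)
  labs <- c("poor", "slight", "fair", "moderate", "substantial",
            "almost perfect")
  as.character(cut(kappa, cut_pts, labs, right = TRUE,
                   include.lowest = TRUE))
}

#' Spearman rank correlation with Fisher-z interval
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged); the
#' two-sided p-value uses the t approximation with n - 2 degrees of
#' freedom and the confidence interval the Fisher z transform with
#' standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y equal-length numeric vectors, n >= 4.
#' @param conf_level confidence level (default 0.95).
#' @return list with `rho`, `p_value`, `ci_low`, `ci_high`, `n`, `df`.
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined: constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  df <- n - 2L
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tt), df)
  }
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  zse <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rho = rho, p_value = p, ci_low = tanh(z - q * zse),
       ci_high = tanh(z + q * zse), n = n, df = df)
}

#' Compare per-case features between two groups
#'
#' For each feature column, reports group means, SDs, minima, maxima and
#' a two-sided p-value from Welch's t test (default) or the Mann-Whitney
#' test — the layout of a FISH+/FISH- comparison table. Features constant
#' across both groups are flagged degenerate with p = 1.
#'
#' @param features data.frame of numeric feature columns.
#' @param groups two-level factor (or coercible) of group membership,
#'   one per row of `features`; both groups need n >= 2.
#' @param test `"welch"` (default) or `"mann-whitney"`.
#' @return data.table with one row per feature: per-group `n`, `mean`,
#'   `sd`, `min`, `max` (suffixed by group level), `p_value`, `test`,
#'   `degenerate`.
#' @export
group_compare <- function(features, groups, test = c("welch", "mann-whitney")) {
  test <- match.arg(test)
  features <- as.data.frame(features)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (length(g) != nrow(features))
    stop("groups length must match feature rows")
  if (any(table(g) < 2L)) stop("both groups need at least 2 cases")
  lv <- levels(g)
  rows <- lapply(names(features), function(f) {
    v <- features[[f]]
    if (!is.numeric(v)) return(NULL)
    v1 <- v[g == lv[1]]; v2 <- v[g == lv[2]]
    degen <- stats::sd(v) == 0
    p <- if (degen) 1 else if (test == "welch") {
      stats::t.test(v1, v2)$p.value
    } else {
      stats::wilcox.test(v1, v2, exact = FALSE, correct = TRUE)$p.value
    }
    out <- data.table::data.table(
      feature = f,
      n_1 = length(v1), mean_1 = mean(v1), sd_1 = stats::sd(v1),
      min_1 = min(v1), max_1 = max(v1),
      n_2 = length(v2), mean_2 = mean(v2), sd_2 = stats::sd(v2),
      min_2 = min(v2), max_2 = max(v2),
      p_value = p, test = test, degenerate = degen)
    data.table::setnames(out, gsub("_1$", paste0("_", lv[1]),
                                   gsub("_2$", paste0("_", lv[2]),
                                        names(out))))
    out
  })
  res <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(res) == 0L) stop("no numeric feature columns")
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s kappa = %.4f (95%% CI %.4f-%.4f, n = %d): %s\n",
              if (x$weighted) "weighted" else "Cohen's",
              x$kappa, x$ci_low, x$ci_high, x$n, x$strength_label))
  invisible(x)
}
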