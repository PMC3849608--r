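#' Class design of the synthetic generator
#'
#' Maps each intended four-tier class to the membrane optical density and
#' circumferential completeness drawn for cells of that class: faint
#' partial stubs for class 0, moderate half rings for 1+, strong
#' near-complete rings for 2+, and very strong complete rings for 3+.
#'
#' @return data.frame with columns `class`, `membrane_od`,
#'   `completeness`.
#' @export
class_design <- function() {
  data.frame(class = 0:3,
             membrane_od = c(0.05, 0.25, 0.55, 0.95),
             completeness = c(0.20, 0.50, 0.90, 0.95))
}

#' Generate a synthetic brightfield IHC tile with ground truth
#'
#' Draws non-overlapping cells, each a hematoxylin nucleus disk plus a
#' DAB membrane arc whose optical density and completeness follow the
#' class design, composes the RGB image through the Beer-Lambert relation
#' with the given stain vectors, and adds Gaussian noise in OD space.
#' Deterministic for a fixed seed.
#'
#' @param n_cells number of cells (>= 1).
#' @param class_proportions length-4 probabilities p0..p3 (sum 1).
#' @param image_size `c(H, W)` in pixels (default 512 x 512).
#' @param noise_sigma OD-space Gaussian noise s.d. (default 0.03).
#' @param seed RNG seed.
#' @param nucleus_radius,cell_radius disk and membrane radii in pixels.
#' @param hem_od nuclear hematoxylin OD (default 0.7).
#' @param membrane_halfwidth half thickness of the membrane annulus in
#'   pixels (default 1.2).
#' @param design class design table, see [class_design()].
#' @param vectors stain basis, see [stain_vectors()].
#' @param min_spacing minimum free gap between cell rims in pixels.
#' @param pixel_size_um optional physical pixel size carried as metadata.
#' @return An object of class `synthetic_tile`: list with `image`
#'   (H x W x 3 8-bit array) and `truth` (cells table, `nucleus_mask`,
#'   `membrane_mask`, `dab_truth`/`hem_truth` OD maps, realized class
#'   `proportions`, `intended_field_score`, `intended_h_score`, and the
#'   generator parameters).
#' @export
generate_tile <- function(n_cells = 80,
                          class_proportions = c(0.25, 0.25, 0.25, 0.25),
                          image_size = c(512, 512), noise_sigma = 0.03,
                          seed = 1, nucleus_radius = 7, cell_radius = 15,
                          hem_od = 0.7, membrane_halfwidth = 1.2,
                          design = class_design(),
                          vectors = stain_vectors(), min_spacing = 4,
                          pixel_size_um = NULL) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0))
    stop("class_proportions must be non-negative and sum to 1")
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius")
  h <- image_size[1]; w <- image_size[2]
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  counts <- as.vector(stats::rmultinom(1, n_cells, class_proportions))
  classes <- rep(0:3, counts)

  margin <- cell_radius + ceiling(membrane_halfwidth) + 2
  if (2 * margin >= min(h, w)) stop("n_cells infeasible for image_size")
  min_d2 <- (2 * cell_radius + min_spacing)^2
  cy <- numeric(0); cx <- numeric(0)
  attempts <- 0L
  while (length(cy) < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 300L * n_cells)
      stop("n_cells infeasible for image_size: could not place all cells")
    yy <- stats::runif(1, margin, h - 1 - margin)
    xx <- stats::runif(1, margin, w - 1 - margin)
    if (length(cy) == 0L ||
        min((cy - yy)^2 + (cx - xx)^2) >= min_d2) {
      cy <- c(cy, yy); cx <- c(cx, xx)
    }
  }
  start_angle <- stats::runif(n_cells, -pi, pi)

  dab <- matrix(0, h, w)
  hem <- matrix(0, h, w)
  nucleus_mask <- matrix(FALSE, h, w)
  membrane_mask <- matrix(FALSE, h, w)
  rmax <- cell_radius + membrane_halfwidth
  for (i in seq_len(n_cells)) {
    cls <- classes[i]
    drow <- design[design$class == cls, ]
    r0 <- max(1L, floor(cy[i] - rmax)); r1 <- min(h, ceiling(cy[i] + rmax) + 1)
    c0 <- max(1L, floor(cx[i] - rmax)); c1 <- min(w, ceiling(cx[i] + rmax) + 1)
    rr <- (r0:r1) - 1; cc <- (c0:c1) - 1   # 0-based coordinates
    dy <- outer(rr - cy[i], rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - cx[i])
    dist <- sqrt(dy^2 + dx^2)
    nuc <- dist <= nucleus_radius
    hem[r0:r1, c0:c1][nuc] <- hem_od
    nucleus_mask[r0:r1, c0:c1][nuc] <- TRUE
    if (drow$membrane_od > 0 && drow$completeness > 0) {
      ring <- abs(dist - cell_radius) <= membrane_halfwidth
      if (drow$completeness < 1) {
        ang <- atan2(dy, dx)
        rel <- (ang - start_angle[i]) %% (2 * pi)
        ring <- ring & rel <= drow$completeness * 2 * pi
      }
      dab[r0:r1, c0:c1][ring] <- drow$membrane_od
      membrane_mask[r0:r1, c0:c1][ring] <- TRUE
    }
  }

  img <- synthesize_rgb(dab, hem, vectors = vectors,
                        noise_sigma = noise_sigma)
  p <- counts / n_cells
  cells <- data.table::data.table(
    cell_id = seq_len(n_cells), row = cy, col = cx, ihc_class = classes,
    membrane_od = design$membrane_od[classes + 1L],
    completeness = design$completeness[classes + 1L],
    start_angle = start_angle)
  structure(list(
    image = img,
    truth = list(
      cells = cells,
      nucleus_mask = nucleus_mask,
      membrane_mask = membrane_mask,
      dab_truth = dab, hem_truth = hem,
      proportions = stats::setNames(p, paste0("p", 0:3)),
      intended_field_score = field_score(classes),
      intended_h_score = 100 * sum((0:3) * p),
      params = list(n_cells = n_cells, image_size = image_size,
                    noise_sigma = noise_sigma, seed = seed,
                    nucleus_radius = nucleus_radius,
                    cell_radius = cell_radius, hem_od = hem_od,
                    membrane_halfwidth = membrane_halfwidth,
                    pixel_size_um = pixel_size_um))),
    class = "synthetic_tile")
}

#' @export
print.synthetic_tile <- function(x, ...) {
  cat(sprintf(
    "synthetic_tile: %d cells on %d x %d | intended field score %d, H %.0f\n",
    nrow(x$truth$cells), dim(x$image)[1], dim(x$image)[2],
    x$truth$intended_field_score, x$truth$intended_h_score))
  invisible(x)
}

#' Kappa of a joint rating distribution
#'
#' Closed-form (weighted) kappa of the population joint distribution
#' `P[i, j] = Pr(rater A = i, rater B = j)`.
#'
#' @param joint k x k joint probability matrix (sums to 1).
#' @param weights optional weight matrix; identity (Cohen's kappa) when
#'   omitted.
#' @return numeric kappa.
#' @export
kappa_from_joint <- function(joint, weights = NULL) {
  if (abs(sum(joint) - 1) > 1e-9 || any(joint < 0))
    stop("joint must be a probability matrix")
  if (is.null(weights)) weights <- diag(nrow(joint))
  kappa_stat(joint, weights)
}

#' Generate paired ordinal scores with a known agreement structure
#'
#' Draws `n_cases` iid pairs from a joint distribution over the 4 x 4
#' score grid; the population kappa (plain and quadratic-weighted) of the
#' generating distribution is returned alongside the samples.
#'
#' @param n_cases number of case pairs.
#' @param agreement_matrix 4 x 4 joint probability matrix over
#'   `{0..3} x {0..3}` (default: 0.857-kappa-like near-diagonal mix).
#' @param seed RNG seed.
#' @return list with vectors `a`, `b`, the `joint` used,
#'   `expected_kappa` and `expected_weighted_kappa`.
#' @export
generate_score_pairs <- function(n_cases,
                                 agreement_matrix = default_agreement_joint(),
                                 seed = 1) {
  P <- agreement_matrix
  if (!is.matrix(P) || nrow(P) != 4L || ncol(P) != 4L ||
      any(P < 0) || abs(sum(P) - 1) > 1e-9)
    stop("agreement_matrix must be a 4 x 4 joint probability matrix")
  if (n_cases < 1L) stop("n_cases must be >= 1")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  cat16 <- sample.int(16L, n_cases, replace = TRUE, prob = as.vector(P))
  a <- (cat16 - 1L) %% 4L          # row index -> rater A class
  b <- (cat16 - 1L) %/% 4L         # col index -> rater B class
  list(a = a, b = b, joint = P,
       expected_kappa = kappa_from_joint(P),
       expected_weighted_kappa = kappa_from_joint(P, quadratic_weights(4)))
}

#' Default high-agreement joint distribution
#'
#' A near-diagonal joint over the four classes with most mass on exact
#' agreement and the rest on one-step disagreements, giving a population
#' kappa in the "almost perfect" band.
#'
#' @return 4 x 4 probability matrix.
#' @export
default_agreement_joint <- function() {
  marg <- c(0.35, 0.15, 0.20, 0.30)
  P <- diag(marg) * 0.9
  for (i in 1:4) {
    nb <- intersect(c(i - 1, i + 1), 1:4)
    P[i, nb] <- P[i, nb] + marg[i] * 0.1 / length(nb)
  }
  P / sum(P)
}

# Table-like two-group feature moments used by the cohort generator:
# group means and SDs of the six membrane-staining features.
cohort_feature_moments <- function() {
  features <- c("her2_2plus_ratio", "her2_3plus_ratio", "h_score",
                "lo_cma_1plus", "lo_cma_2plus", "lo_cma_3plus")
  list(
    features = features,
    mean_neg = c(0.08386, 0.012607, 61.25344, 7315.882, 1317.471, 184.7127),
    sd_neg   = c(0.107272, 0.024028, 42.95535, 4898.122, 1796.785, 365.2118),
    mean_pos = c(0.152766, 0.04071, 88.80895, 25794.81, 12464.48, 2866.724),
    sd_pos   = c(0.135455, 0.047413, 48.74765, 21455.78, 15429.72, 4210.592))
}

#' Generate a two-group case-level feature cohort
#'
#' Emulates a small FISH-negative / FISH-positive comparison cohort:
#' per-case draws of the six membrane-staining features (2+ and 3+
#' proportional ratios stored as fractions, H-score, per-class LO-CMA).
#' With `effect = "table1"` (default) the group-wise Gaussian moments are
#' matched to published equivocal-cohort values and draws are truncated
#' at zero (ratios also capped at 1); with `effect = "null"` both groups
#' share the FISH-negative distribution and draws are left untruncated
#' Gaussian, the calibration mode for testing type-I error of the group
#' comparison.
#'
#' @param n_neg,n_pos group sizes (>= 2 each).
#' @param effect `"table1"`, `"null"`, or a list with elements
#'   `mean_neg`, `sd_neg`, `mean_pos`, `sd_pos` (length 6 each).
#' @param seed RNG seed.
#' @return data.frame with `case_id`, `fish_status` ("FISH-"/"FISH+")
#'   and six feature columns; the generating moments are attached as
#'   attribute `"moments"`, the mean group differences as `"true_effects"`.
#' @export
generate_cohort <- function(n_neg = 9, n_pos = 6, effect = "table1",
                            seed = 1) {
  if (n_neg < 2L || n_pos < 2L) stop("group sizes must be >= 2")
  m <- cohort_feature_moments()
  truncate <- TRUE
  if (identical(effect, "null")) {
    m$mean_pos <- m$mean_neg
    m$sd_pos <- m$sd_neg
    truncate <- FALSE
  } else if (is.list(effect)) {
    m[c("mean_neg", "sd_neg", "mean_pos", "sd_pos")] <-
      effect[c("mean_neg", "sd_neg", "mean_pos", "sd_pos")]
  } else if (!identical(effect, "table1")) {
    stop("effect must be \"table1\", \"null\" or a moments list")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draw <- function(n, means, sds) {
    x <- vapply(seq_along(means),
                function(j) stats::rnorm(n, means[j], sds[j]),
                numeric(n))
    x <- matrix(x, nrow = n)
    if (truncate) {
      x[x < 0] <- 0
      x[, 1:2][x[, 1:2] > 1] <- 1
    }
    colnames(x) <- m$features
    as.data.frame(x)
  }
  out <- rbind(
    cbind(data.frame(case_id = sprintf("neg%02d", seq_len(n_neg)),
                     fish_status = "FISH-"),
          draw(n_neg, m$mean_neg, m$sd_neg)),
    cbind(data.frame(case_id = sprintf("pos%02d", seq_len(n_pos)),
                     fish_status = "FISH+"),
          draw(n_pos, m$mean_pos, m$sd_pos)))
  rownames(out) <- NULL
  attr(out, "moments") <- m
  attr(out, "true_effects") <- stats::setNames(m$mean_pos - m$mean_neg,
                                               m$features)
  out
}
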