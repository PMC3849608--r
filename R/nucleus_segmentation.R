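#' Segment nuclei on the hematoxylin channel
#'
#' Standard counterstain nucleus pipeline: Gaussian smoothing, Otsu
#' threshold on the hematoxylin optical density, hole filling,
#' morphological opening, optional distance-transform watershed split of
#' touching nuclei, and a minimum-area filter. Labels are relabelled to a
#' contiguous 1..N. Nuclei touching the image border are kept; clipping to
#' a region of interest is the caller's responsibility.
#'
#' @param hem_od H x W non-negative hematoxylin OD matrix.
#' @param sigma Gaussian smoothing s.d. in pixels (default 1.5).
#' @param threshold `"otsu"` (default) or a numeric OD cutoff.
#' @param min_nucleus_area discard labelled regions smaller than this
#'   (pixels, default 30).
#' @param split_touching separate touching nuclei with a
#'   distance-transform watershed (default TRUE).
#' @param watershed_tolerance minimum watershed basin depth when
#'   splitting (default 1).
#' @return An object of class `nucleus_labels`: list with `labels`
#'   (H x W integer matrix, 0 = background), `centroids` (N x 2 matrix of
#'   0-based (row, col) coordinates) and `areas` (integer vector).
#' @export
segment_nuclei <- function(hem_od, sigma = 1.5, threshold = "otsu",
                           min_nucleus_area = 30, split_touching = TRUE,
                           watershed_tolerance = 1) {
  if (!is.matrix(hem_od) || nrow(hem_od) < 1L || ncol(hem_od) < 1L)
    stop("hem_od must be a non-empty matrix")
  if (any(hem_od < 0)) stop("hem_od must be non-negative")
  if (all(hem_od == 0))
    return(new_nucleus_labels(matrix(0L, nrow(hem_od), ncol(hem_od))))

  sm <- if (sigma > 0) as.matrix(EBImage::gblur(EBImage::Image(hem_od), sigma))
        else hem_od
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(sm)
    if (diff(rng) <= 0) Inf else EBImage::otsu(EBImage::Image(sm), range = rng)
  } else {
    as.numeric(threshold)
  }
  mask <- sm > thr
  if (!any(mask))
    return(new_nucleus_labels(matrix(0L, nrow(hem_od), ncol(hem_od))))

  m <- EBImage::Image(mask * 1)
  m <- EBImage::fillHull(m)
  m <- EBImage::opening(m, EBImage::makeBrush(3, shape = "diamond"))
  if (split_touching) {
    dm <- EBImage::distmap(m)
    lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  } else {
    lab <- EBImage::bwlabel(m)
  }
  labels <- matrix(as.integer(as.matrix(lab)), nrow(hem_od), ncol(hem_od))
  labels <- filter_small_labels(labels, min_nucleus_area)
  new_nucleus_labels(labels)
}

#' Binary mask of all nuclei
#'
#' @param nuclei a `nucleus_labels` object.
#' @return H x W logical matrix, TRUE where a nucleus is labelled.
#' @export
nuclei_mask <- function(nuclei) {
  stopifnot(inherits(nuclei, "nucleus_labels"))
  nuclei$labels > 0L
}

# drop regions below min area and relabel contiguously
filter_small_labels <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- which(areas >= min_area)
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- remap[labels[labels > 0L]]
  out
}

# construct the container, computing centroids (0-based) and areas
new_nucleus_labels <- function(labels) {
  n <- max(labels)
  if (n == 0L) {
    centroids <- matrix(numeric(0), 0, 2,
                        dimnames = list(NULL, c("row", "col")))
    areas <- integer(0)
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rows <- (idx - 1L) %% nrow(labels)      # 0-based
    cols <- (idx - 1L) %/% nrow(labels)
    areas <- tabulate(lab, nbins = n)
    centroids <- cbind(
      row = rowsum(as.numeric(rows), lab)[, 1] / areas,
      col = rowsum(as.numeric(cols), lab)[, 1] / areas)
  }
  structure(list(labels = labels, centroids = centroids, areas = areas,
                 n = as.integer(n)),
            class = "nucleus_labels")
}

#' @export
print.nucleus_labels <- function(x, ...) {
  cat("nucleus_labels:", x$n, "nuclei on a",
      nrow(x$labels), "x", ncol(x$labels), "image\n")
  invisible(x)
}
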