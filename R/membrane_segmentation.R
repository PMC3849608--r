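#' Partition an image into adjacent spots along membrane mid-lines
#'
#' The intensity-based linking step: the (optionally smoothed) image is
#' flooded by steepest ascent, so that every pixel is assigned to the
#' basin of the regional maximum it climbs to. Membranes are intensity
#' minima of `dab_intensity` (dark ridges of absorbance), so the borders
#' between adjacent basins trace the membrane mid-lines. Ties in the
#' ascent are broken by (row, col) lexicographic pixel order, which makes
#' the partition fully deterministic; a constant image yields one spot.
#'
#' Border pixels are computed from 4-adjacent pixel pairs with different
#' labels: of each pair the pixel with the higher DAB optical density is
#' taken, so the border curve sits on the absorbance ridge (the intensity
#' local-minimum line) and is approximately one pixel wide.
#'
#' @param dab_intensity H x W numeric matrix in which membranes are
#'   intensity minima (e.g. the negated DAB OD channel).
#' @param smoothing_sigma Gaussian smoothing s.d. in pixels applied before
#'   flooding (default 1; 0 disables). Suppresses single-pixel minima.
#' @param dab_od H x W matrix of DAB optical density used to place border
#'   pixels and measure border intensity. Defaults to
#'   `max(dab_intensity) - dab_intensity`.
#' @return An object of class `spot_partition`: list with
#'   `spot_labels` (H x W integer matrix, every pixel assigned),
#'   `border_pixels` (data.table with columns `a`, `b`, `px`: spot pair
#'   `a < b` and linear pixel index, ordered by row-major position),
#'   `edges` (data.table with `a`, `b`, `border_length`, `mean_dab_od`),
#'   `n_spots`, and the `dab_od` measurement image.
#' @export
partition_spots <- function(dab_intensity, smoothing_sigma = 1,
                            dab_od = NULL) {
  if (!is.matrix(dab_intensity)) stop("dab_intensity must be a matrix")
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  if (is.null(dab_od)) dab_od <- max(dab_intensity) - dab_intensity
  if (!identical(dim(dab_od), dim(dab_intensity)))
    stop("dab_od must match the image shape")
  h <- nrow(dab_intensity); w <- ncol(dab_intensity)
  x <- if (smoothing_sigma > 0 && h > 2 && w > 2)
    as.matrix(EBImage::gblur(EBImage::Image(dab_intensity), smoothing_sigma))
  else dab_intensity

  labels <- steepest_ascent_labels(x)
  new_spot_partition(labels, dab_od)
}

# Assign every pixel to the basin of the regional maximum reached by
# steepest ascent. Ties (plateaus) resolved by (row, col) lexicographic
# order: among equal-valued candidates the lexicographically smallest
# pixel is treated as higher. Vectorized with pointer doubling.
steepest_ascent_labels <- function(x) {
  h <- nrow(x); w <- ncol(x)
  n <- h * w
  idx <- seq_len(n)
  # row-major key encodes (row, col) lexicographic order
  r0 <- (idx - 1L) %% h
  c0 <- (idx - 1L) %/% h
  lex <- r0 * w + c0
  best_val <- as.numeric(x)
  best_lex <- lex
  best_ptr <- idx
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  xv <- as.numeric(x)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    nr <- r0 + dr; nc <- c0 + dc
    ok <- nr >= 0L & nr < h & nc >= 0L & nc < w
    nb <- nc * h + nr + 1L
    nv <- rep(-Inf, n); nl <- rep(Inf, n)
    nv[ok] <- xv[nb[ok]]
    nl[ok] <- nr[ok] * w + nc[ok]
    take <- (nv > best_val) | (nv == best_val & nl < best_lex)
    if (any(take)) {
      best_val[take] <- nv[take]
      best_lex[take] <- nl[take]
      best_ptr[take] <- nb[take]
    }
  }
  # pointer doubling to basin roots
  p <- best_ptr
  repeat {
    p2 <- p[p]
    if (identical(p2, p)) break
    p <- p2
  }
  roots <- sort(unique(p))
  labels <- matrix(match(p, roots), h, w)
  storage.mode(labels) <- "integer"
  labels
}

# build border-pixel table and edge summary from a label map
spot_border_table <- function(labels, dab_od) {
  h <- nrow(labels); w <- ncol(labels)
  li <- as.integer(labels)
  odv <- as.numeric(dab_od)
  pair_i <- integer(0); pair_j <- integer(0)
  if (h > 1L) {
    i <- which((seq_len(h * w) - 1L) %% h < (h - 1L))
    j <- i + 1L
    keep <- li[i] != li[j]
    pair_i <- c(pair_i, i[keep]); pair_j <- c(pair_j, j[keep])
  }
  if (w > 1L) {
    i <- seq_len(h * (w - 1L))
    j <- i + h
    keep <- li[i] != li[j]
    pair_i <- c(pair_i, i[keep]); pair_j <- c(pair_j, j[keep])
  }
  if (length(pair_i) == 0L) {
    return(data.table::data.table(a = integer(0), b = integer(0),
                                  px = integer(0)))
  }
  la <- li[pair_i]; lb <- li[pair_j]
  a <- pmin(la, lb); b <- pmax(la, lb)
  # border pixel = the higher-OD member of the pair (the absorbance ridge);
  # ties go to the lexicographically smaller pixel
  hi <- odv[pair_i] > odv[pair_j] |
    (odv[pair_i] == odv[pair_j] & rowmajor_key(pair_i, h, w) <=
       rowmajor_key(pair_j, h, w))
  px <- ifelse(hi, pair_i, pair_j)
  dt <- data.table::data.table(a = a, b = b, px = px,
                               key = c("a", "b", "px"))
  unique(dt)
}

rowmajor_key <- function(idx, h, w) {
  ((idx - 1L) %% h) * w + (idx - 1L) %/% h
}

new_spot_partition <- function(labels, dab_od) {
  bp <- spot_border_table(labels, dab_od)
  odv <- as.numeric(dab_od)
  if (nrow(bp) > 0L) {
    px <- NULL # data.table NSE
    edges <- bp[, list(border_length = .N,
                       mean_dab_od = mean(odv[px]),
                       median_dab_od = stats::median(odv[px])),
                by = c("a", "b")]
    data.table::setkeyv(edges, c("a", "b"))
    # deterministic border-pixel order within each edge: row-major
    data.table::setorderv(bp, c("a", "b", "px"))
  } else {
    edges <- data.table::data.table(a = integer(0), b = integer(0),
                                    border_length = integer(0),
                                    mean_dab_od = numeric(0),
                                    median_dab_od = numeric(0))
  }
  structure(list(spot_labels = labels, border_pixels = bp, edges = edges,
                 n_spots = as.integer(max(labels)), dab_od = dab_od),
            class = "spot_partition")
}

#' @export
print.spot_partition <- function(x, ...) {
  cat("spot_partition:", x$n_spots, "spots,", nrow(x$edges),
      "border edges on a", nrow(x$spot_labels), "x", ncol(x$spot_labels),
      "image\n")
  invisible(x)
}

# iterative union-find root resolution for a parent vector over 1..n
uf_resolve <- function(parent) {
  repeat {
    p2 <- parent[parent]
    if (identical(p2, parent)) return(parent)
    parent <- p2
  }
}

# merge groups of labels given (from, into) pairs; returns relabelled map
apply_merges <- function(labels, from, into) {
  n <- max(labels)
  parent <- seq_len(n)
  # sequential unions in deterministic order
  for (k in seq_along(from)) {
    ra <- parent[from[k]]; while (parent[ra] != ra) ra <- parent[ra]
    rb <- parent[into[k]]; while (parent[rb] != rb) rb <- parent[rb]
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- uf_resolve(parent)
  remap <- match(roots, sort(unique(roots)))
  out <- matrix(remap[labels], nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}

#' Merge spots by area and border-length criteria
#'
#' False membrane curves appear at intensity minima where no actual
#' immunoreaction is present; they bound spots with suboptimal features
#' and carry little DAB signal. Two rules are applied iteratively until a
#' fixed point: (1) every spot smaller than `min_spot_area` is merged
#' into the neighbour with which it shares its longest dissolvable border
#' (ties to the smallest neighbour label); (2) every dissolvable border
#' edge shorter than `min_border_length` is dissolved, merging its two
#' spots. A border is dissolvable only while its mean DAB OD is below
#' `protect_min_od`: borders that trace real membrane signal are never
#' merged away, whatever their length. Area merges run before
#' border-length merges in each round. The number of spots never
#' increases.
#'
#' @param p a `spot_partition`.
#' @param min_spot_area minimum spot area in pixels (default 25).
#' @param min_border_length minimum border length in pixels (default 5).
#' @param protect_min_od borders with median DAB OD at or above this
#'   are kept (default 0.1, matching the skeleton retention threshold).
#' @param max_iter safety cap on merge rounds (default 100).
#' @return a `spot_partition` at the merge fixed point.
#' @export
merge_spots <- function(p, min_spot_area = 25, min_border_length = 5,
                        protect_min_od = 0.1, max_iter = 100) {
  stopifnot(inherits(p, "spot_partition"))
  if (min_spot_area < 0 || min_border_length < 0)
    stop("thresholds must be >= 0")
  labels <- p$spot_labels
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # pass 1: undersized spots join their longest-border neighbour
    repeat {
      part <- new_spot_partition(labels, p$dab_od)
      if (part$n_spots <= 1L || nrow(part$edges) == 0L) break
      areas <- tabulate(part$spot_labels, nbins = part$n_spots)
      small <- which(areas < min_spot_area)
      if (length(small) == 0L) break
      e <- part$edges[part$edges$median_dab_od < protect_min_od, ]
      nb <- data.table::rbindlist(list(
        data.table::data.table(s = e$a, o = e$b, len = e$border_length),
        data.table::data.table(s = e$b, o = e$a, len = e$border_length)))
      nb <- nb[nb$s %in% small, ]
      if (nrow(nb) == 0L) break
      data.table::setorderv(nb, c("s", "len", "o"), order = c(1L, -1L, 1L))
      pick <- nb[!duplicated(nb$s), ]
      labels <- apply_merges(part$spot_labels, pick$s, pick$o)
      changed <- TRUE
    }
    # pass 2: dissolve short low-signal borders. An edge is kept when both
    # of its spots carry membrane evidence on other borders: dissolving it
    # would fuse two membrane-bounded regions and erase the real boundary
    # between them (e.g. across the small gap of a nearly complete ring).
    part <- new_spot_partition(labels, p$dab_od)
    evidence <- rep(FALSE, part$n_spots)
    prot <- part$edges$median_dab_od >= protect_min_od
    evidence[unique(c(part$edges$a[prot], part$edges$b[prot]))] <- TRUE
    short <- part$edges[part$edges$border_length < min_border_length &
                          part$edges$median_dab_od < protect_min_od &
                          !(evidence[part$edges$a] &
                              evidence[part$edges$b]), ]
    if (nrow(short) > 0L) {
      labels <- apply_merges(part$spot_labels, short$a, short$b)
      changed <- TRUE
    }
    if (!changed) break
  }
  new_spot_partition(labels, p$dab_od)
}

#' Merge spots whose shared border runs over nuclei
#'
#' A membrane mid-line cannot cross a nucleus; border segments lying
#' mostly inside the nucleus mask are false curves, so the spots they
#' separate are merged.
#'
#' @param p a `spot_partition`.
#' @param nuclei a `nucleus_labels` object (same image shape).
#' @param over_nucleus_threshold dissolve edges whose fraction of border
#'   pixels inside the nucleus mask exceeds this (default 0.5).
#' @return a `spot_partition` with the offending borders dissolved.
#' @export
merge_over_nuclei <- function(p, nuclei, over_nucleus_threshold = 0.5) {
  stopifnot(inherits(p, "spot_partition"), inherits(nuclei, "nucleus_labels"))
  if (!identical(dim(nuclei$labels), dim(p$spot_labels)))
    stop("nuclei and partition shapes differ")
  mask <- as.logical(nuclei$labels > 0L)
  labels <- p$spot_labels
  repeat {
    part <- new_spot_partition(labels, p$dab_od)
    if (nrow(part$edges) == 0L) break
    px <- NULL
    frac <- part$border_pixels[, list(f = mean(mask[px])), by = c("a", "b")]
    bad <- frac[frac$f > over_nucleus_threshold, ]
    if (nrow(bad) == 0L) break
    labels <- apply_merges(part$spot_labels, bad$a, bad$b)
  }
  out <- new_spot_partition(labels, p$dab_od)
  px <- NULL
  onf <- out$border_pixels[, list(over_nucleus_fraction = mean(mask[px])),
                           by = c("a", "b")]
  out$edges <- merge(out$edges, onf, by = c("a", "b"), all.x = TRUE)
  out
}

#' Extract the membrane skeleton from a merged spot partition
#'
#' Collects the surviving border pixels, removes those inside the nucleus
#' mask (the mask subtraction step) and those whose own DAB OD falls
#' below `min_mean_od` (border stretches carrying no signal are false
#' curves regardless of the spots they separate), splits the remainder
#' into 8-connected segments, and discloses segments that cannot
#' represent membranes: shorter than `min_segment_length` or with mean
#' DAB OD below `min_mean_od`.
#'
#' @param p a `spot_partition` (after merging).
#' @param nuclei a `nucleus_labels` object.
#' @param min_segment_length minimum retained segment length in pixels
#'   (default 10).
#' @param min_mean_od minimum mean DAB OD along a segment (default 0.1).
#' @return An object of class `membrane_skeleton`: list with
#'   `skeleton_mask` (H x W logical), `segments` (data.table: `segment`,
#'   `length`, `mean_dab_od`) and `pixels` (data.table: `segment`, `px`).
#' @export
extract_skeleton <- function(p, nuclei, min_segment_length = 10,
                             min_mean_od = 0.1) {
  stopifnot(inherits(p, "spot_partition"), inherits(nuclei, "nucleus_labels"))
  h <- nrow(p$spot_labels); w <- ncol(p$spot_labels)
  nmask <- nuclei$labels > 0L
  px <- sort(unique(p$border_pixels$px))
  px <- px[!nmask[px]]
  px <- px[p$dab_od[px] >= min_mean_od]   # per-pixel signal screen
  empty <- function() {
    structure(list(
      skeleton_mask = matrix(FALSE, h, w),
      segments = data.table::data.table(segment = integer(0),
                                        length = integer(0),
                                        mean_dab_od = numeric(0)),
      pixels = data.table::data.table(segment = integer(0),
                                      px = integer(0))),
      class = "membrane_skeleton")
  }
  if (length(px) == 0L) return(empty())
  comp <- label_components_8(px, h, w)
  odv <- as.numeric(p$dab_od)
  dt <- data.table::data.table(segment = comp, px = px)
  seg <- dt[, list(length = .N, mean_dab_od = mean(odv[px])),
            by = "segment"]
  keep <- seg[seg$length >= min_segment_length &
                seg$mean_dab_od >= min_mean_od, ]
  if (nrow(keep) == 0L) return(empty())
  # relabel retained segments 1..K in order of first pixel
  data.table::setorderv(keep, "segment")
  keep$new_id <- seq_len(nrow(keep))
  dt <- dt[dt$segment %in% keep$segment, ]
  dt$segment <- keep$new_id[match(dt$segment, keep$segment)]
  data.table::setorderv(dt, c("segment", "px"))
  mask <- matrix(FALSE, h, w)
  mask[dt$px] <- TRUE
  segs <- data.table::data.table(segment = keep$new_id,
                                 length = keep$length,
                                 mean_dab_od = keep$mean_dab_od)
  structure(list(skeleton_mask = mask, segments = segs, pixels = dt),
            class = "membrane_skeleton")
}

#' Mean DAB optical density along segments
#'
#' @param pixels data.table/data.frame with columns `segment` and `px`
#'   (linear pixel indices), e.g. the `pixels` element of a
#'   `membrane_skeleton`.
#' @param dab_od H x W DAB OD matrix.
#' @return data.table with `segment` and `mean_dab_od`.
#' @export
measure_border_od <- function(pixels, dab_od) {
  pixels <- data.table::as.data.table(pixels)
  if (nrow(pixels) == 0L) stop("empty segment list")
  if (any(pixels$px < 1L | pixels$px > length(dab_od)))
    stop("segment pixels out of image bounds")
  odv <- as.numeric(dab_od)
  px <- NULL
  pixels[, list(mean_dab_od = mean(odv[px])), by = "segment"]
}

# label an explicit pixel set into 8-connected components
label_components_8 <- function(px, h, w) {
  n <- length(px)
  pos <- integer(h * w)
  pos[px] <- seq_len(n)
  r <- (px - 1L) %% h
  co <- (px - 1L) %/% h
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_len(nrow(offs))) {
    nr <- r + offs[k, 1L]; nc <- co + offs[k, 2L]
    ok <- nr >= 0L & nr < h & nc >= 0L & nc < w
    nb <- integer(n)
    nb[ok] <- pos[nc[ok] * h + nr[ok] + 1L]
    hit <- which(nb > 0L)
    for (i in hit) {
      ra <- find(i); rb <- find(nb[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- uf_resolve(parent)
  match(roots, sort(unique(roots)))
}

#' @export
print.membrane_skeleton <- function(x, ...) {
  cat("membrane_skeleton:", nrow(x$segments), "segments,",
      sum(x$skeleton_mask), "pixels\n")
  invisible(x)
}
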