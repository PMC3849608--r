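# Independent oracles and small fixture builders used across the suite.

# Pair-by-pair counting kappa, written independently of the package's
# table-based implementation.
kappa_pair_counting <- function(a, b, levels = 0:3, w = NULL) {
  n <- length(a)
  k <- length(levels)
  if (is.null(w)) w <- diag(k)
  po_w <- 0
  for (i in seq_len(n)) {
    ia <- match(a[i], levels); ib <- match(b[i], levels)
    po_w <- po_w + w[ia, ib]
  }
  po_w <- po_w / n
  pa <- sapply(levels, function(l) sum(a == l) / n)
  pb <- sapply(levels, function(l) sum(b == l) / n)
  pe_w <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    pe_w <- pe_w + w[i, j] * pa[i] * pb[j]
  (po_w - pe_w) / (1 - pe_w)
}

# Per-pixel recursive steepest-ascent basin assignment: climbs one pixel
# at a time, preferring higher value, then smaller (row, col). Used as
# the brute-force oracle for the vectorized partition.
brute_force_basins <- function(x) {
  h <- nrow(x); w <- ncol(x)
  climb <- function(r, c) {
    repeat {
      best_r <- r; best_c <- c; best_v <- x[r, c]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nr <- r + dr; nc <- c + dc
        if (nr < 1 || nr > h || nc < 1 || nc > w) next
        better <- x[nr, nc] > best_v ||
          (x[nr, nc] == best_v &&
             ((nr < best_r) || (nr == best_r && nc < best_c)))
        if (better) { best_r <- nr; best_c <- nc; best_v <- x[nr, nc] }
      }
      if (best_r == r && best_c == c) return(c(r, c))
      r <- best_r; c <- best_c
    }
  }
  root <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rt <- climb(r, c)
    root[r, c] <- (rt[2] - 1L) * h + rt[1]
  }
  matrix(match(root, sort(unique(as.vector(root)))), h, w)
}

# hematoxylin-disk-only synthetic image (no membranes)
nuclei_only_image <- function(centres, radius = 7, hem_od = 0.7,
                              image_size = c(128, 128), noise_sigma = 0,
                              seed = 1) {
  set.seed(seed)
  h <- image_size[1]; w <- image_size[2]
  hem <- matrix(0, h, w)
  for (i in seq_len(nrow(centres))) {
    dy <- outer(seq_len(h) - 1 - centres[i, 1], rep(1, w))
    dx <- outer(rep(1, h), seq_len(w) - 1 - centres[i, 2])
    hem[dy^2 + dx^2 <= radius^2] <- hem_od
  }
  synthesize_rgb(matrix(0, h, w), hem, noise_sigma = noise_sigma)
}

# a spot partition built directly from a label map (unit-test fixture)
partition_from_labels <- function(labels, dab_od) {
  her2quant:::new_spot_partition(labels, dab_od)
}

# a nucleus_labels object built directly from a label map
nuclei_from_labels <- function(labels) {
  her2quant:::new_nucleus_labels(labels)
}

# ring skeleton fixture: one nucleus disk plus a circular arc "skeleton"
ring_fixture <- function(image_size = c(64, 64), centre = c(31.5, 31.5),
                         nucleus_radius = 7, ring_radius = 15,
                         arc_fraction = 1, od = 1.2) {
  h <- image_size[1]; w <- image_size[2]
  dy <- outer(seq_len(h) - 1 - centre[1], rep(1, w))
  dx <- outer(rep(1, h), seq_len(w) - 1 - centre[2])
  dist <- sqrt(dy^2 + dx^2)
  labels <- matrix(0L, h, w)
  labels[dist <= nucleus_radius] <- 1L
  ring <- abs(dist - ring_radius) <= 0.7
  if (arc_fraction < 1) {
    ang <- atan2(dy, dx) %% (2 * pi)
    ring <- ring & ang <= arc_fraction * 2 * pi
  }
  dab_od <- matrix(0, h, w)
  dab_od[ring] <- od
  px <- which(ring)
  skel <- structure(list(
    skeleton_mask = ring,
    segments = data.table::data.table(segment = 1L, length = length(px),
                                      mean_dab_od = od),
    pixels = data.table::data.table(segment = 1L, px = px)),
    class = "membrane_skeleton")
  list(nuclei = nuclei_from_labels(labels), skeleton = skel,
       dab_od = dab_od)
}
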