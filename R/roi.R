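#' Read region-of-interest annotations
#'
#' ROIs are stored as structured text (JSON): an array of objects with
#' `roi_id`, `core_id` and `polygon`, the polygon an ordered list of
#' 0-based `[row, col]` vertices (>= 3, not self-intersecting; the
#' closing edge back to the first vertex is implicit).
#'
#' @param path JSON file path.
#' @return list of ROI records, each a list with `roi_id`, `core_id`
#'   and a V x 2 numeric `polygon` matrix.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0L) stop("no ROIs in ", path)
  lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    if (is.null(r$roi_id) || is.null(r$polygon))
      stop("ROI ", i, " lacks roi_id or polygon")
    poly <- do.call(rbind, lapply(r$polygon, as.numeric))
    if (is.null(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
      stop("ROI ", r$roi_id, ": polygon needs >= 3 (row, col) vertices")
    colnames(poly) <- c("row", "col")
    list(roi_id = as.character(r$roi_id),
         core_id = as.character(if (is.null(r$core_id)) "core1"
                                else r$core_id),
         polygon = poly)
  })
}

#' Write ROI annotations to JSON
#'
#' @param rois list of ROI records as returned by [read_rois()] or
#'   [full_frame_roi()].
#' @param path output path.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) list(
    roi_id = r$roi_id, core_id = r$core_id,
    polygon = lapply(seq_len(nrow(r$polygon)),
                     function(i) as.numeric(r$polygon[i, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' A single ROI covering the whole image
#'
#' @param image_size `c(H, W)` in pixels.
#' @param roi_id,core_id identifiers.
#' @return a one-element list of ROI records.
#' @export
full_frame_roi <- function(image_size, roi_id = "full", core_id = "core1") {
  h <- image_size[1]; w <- image_size[2]
  list(list(roi_id = roi_id, core_id = core_id,
            polygon = cbind(row = c(0, 0, h - 1, h - 1),
                            col = c(0, w - 1, w - 1, 0))))
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd fill rule in 0-based (row, col) pixel
#' coordinates; points on a horizontal ray through a vertex follow the
#' half-open edge convention, vertices count as inside.
#'
#' @param points N x 2 matrix of (row, col) points.
#' @param polygon V x 2 matrix of (row, col) vertices.
#' @return logical vector of length N.
#' @export
point_in_polygon <- function(points, polygon) {
  points <- matrix(as.numeric(points), ncol = 2L)
  py <- points[, 1]; px <- points[, 2]
  vy <- polygon[, 1]; vx <- polygon[, 2]
  nv <- length(vy)
  inside <- rep(FALSE, nrow(points))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  # boundary vertices count as inside
  on_vertex <- rep(FALSE, nrow(points))
  for (i in seq_len(nv)) on_vertex <- on_vertex | (py == vy[i] & px == vx[i])
  inside | on_vertex
}
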