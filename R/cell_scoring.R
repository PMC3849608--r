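#' Assign membrane skeleton pixels to cells
#'
#' Every skeleton pixel is attributed to the nearest nucleus (Voronoi
#' region of the nucleus label map) provided it lies within
#' `max_radius_px` of that nucleus boundary. Per cell, the mean DAB OD
#' and pixel count of the assigned skeleton are recorded, together with
#' the circumferential completeness: the cell's perimeter is divided into
#' `n_angle_bins` equal angular sectors around the nucleus centroid, and
#' completeness is the fraction of sectors containing at least one
#' assigned skeleton pixel. Cells with no assigned pixels get mean OD 0
#' and completeness 0.
#'
#' @param nuclei a `nucleus_labels` object.
#' @param skeleton a `membrane_skeleton` object (same image shape).
#' @param dab_od H x W DAB OD matrix used for the intensity measurement.
#' @param max_radius_px maximum distance (pixels) from the nucleus
#'   boundary at which skeleton is still attributed to the cell
#'   (default 25).
#' @param n_angle_bins angular sectors for the completeness measure
#'   (default 24).
#' @return A data.table of cell records: `cell_id`, `row`, `col`
#'   (0-based nucleus centroid), `membrane_mean_od`, `completeness`,
#'   `membrane_area_px`. The per-pixel assignment is attached as
#'   attribute `"pixel_assignment"` (data.table with `px`, `cell`).
#' @export
assign_membrane_to_cells <- function(nuclei, skeleton, dab_od,
                                     max_radius_px = 25,
                                     n_angle_bins = 24) {
  stopifnot(inherits(nuclei, "nucleus_labels"),
            inherits(skeleton, "membrane_skeleton"))
  if (!identical(dim(nuclei$labels), dim(skeleton$skeleton_mask)))
    stop("nuclei and skeleton shapes differ")
  n <- nuclei$n
  if (n == 0L) {
    return(data.table::data.table(cell_id = integer(0), row = numeric(0),
                                  col = numeric(0),
                                  membrane_mean_od = numeric(0),
                                  completeness = numeric(0),
                                  membrane_area_px = integer(0)))
  }
  h <- nrow(nuclei$labels); w <- ncol(nuclei$labels)
  rec <- data.table::data.table(
    cell_id = seq_len(n),
    row = nuclei$centroids[, "row"],
    col = nuclei$centroids[, "col"],
    membrane_mean_od = 0,
    completeness = 0,
    membrane_area_px = 0L)

  px <- which(skeleton$skeleton_mask)
  if (length(px) > 0L) {
    # nearest-nucleus field and distance to the nearest nucleus boundary
    seeds <- EBImage::Image(nuclei$labels)
    vor <- EBImage::propagate(EBImage::Image(matrix(0, h, w)), seeds,
                              lambda = 1)
    vor <- matrix(as.integer(as.matrix(vor)), h, w)
    dist <- as.matrix(EBImage::distmap(
      EBImage::Image((nuclei$labels == 0L) * 1)))
    keep <- dist[px] <= max_radius_px & vor[px] > 0L
    px <- px[keep]
  }
  assignment <- data.table::data.table(px = integer(0), cell = integer(0))
  if (length(px) > 0L) {
    cell <- vor[px]
    assignment <- data.table::data.table(px = px, cell = cell)
    odv <- as.numeric(dab_od)
    pr <- (px - 1L) %% h
    pc <- (px - 1L) %/% h
    ang <- atan2(pr - rec$row[cell], pc - rec$col[cell])
    bin <- pmin(floor((ang + pi) / (2 * pi) * n_angle_bins),
                n_angle_bins - 1L)
    dt <- data.table::data.table(cell = cell, od = odv[px], bin = bin)
    smry <- dt[, list(mean_od = mean(od), area = .N,
                      cov = length(unique(bin)) / n_angle_bins),
               by = "cell"]
    rec$membrane_mean_od[smry$cell] <- smry$mean_od
    rec$membrane_area_px[smry$cell] <- smry$area
    rec$completeness[smry$cell] <- smry$cov
  }
  data.table::setattr(rec, "pixel_assignment", assignment)
  rec
}

#' Classify cells on the four-tier membrane-staining scale
#'
#' Implements the guideline logic: class 0 below the faint-intensity
#' cutoff; class 3 for strong (OD >= `t3`) circumferentially complete
#' staining; class 2 for moderate complete staining (`t2` <= OD < `t3`);
#' everything else — faint, or strong but incomplete — is class 1.
#' Intensity boundaries are left-closed (OD exactly at `t2` takes the
#' class-2 branch).
#'
#' @param cells cell-record data.table from [assign_membrane_to_cells()],
#'   or a numeric vector of membrane mean ODs (then `completeness` must
#'   be given).
#' @param completeness numeric vector when `cells` is a vector.
#' @param od_thresholds strictly increasing positive OD cutoffs
#'   `c(t1, t2, t3)` (default `c(0.15, 0.40, 0.70)`).
#' @param complete_threshold minimum completeness for classes 2 and 3
#'   (default 0.8).
#' @return With a data.table input, the table with an added integer
#'   `ihc_class` column; with vector input, an integer vector in 0..3.
#' @export
classify_cells <- function(cells, completeness = NULL,
                           od_thresholds = c(0.15, 0.40, 0.70),
                           complete_threshold = 0.8) {
  t <- as.numeric(od_thresholds)
  if (length(t) != 3L || any(t <= 0) || any(diff(t) <= 0))
    stop("od_thresholds must be three strictly increasing positive values")
  tabular <- is.data.frame(cells)
  if (tabular) {
    od <- cells$membrane_mean_od
    comp <- cells$completeness
  } else {
    od <- as.numeric(cells)
    comp <- as.numeric(completeness)
    if (length(comp) != length(od))
      stop("completeness must match the length of the OD vector")
  }
  cls <- integer(length(od))                     # 0: below t1
  cls[od >= t[1]] <- 1L                          # faint or incomplete
  cls[od >= t[2] & od < t[3] & comp >= complete_threshold] <- 2L
  cls[od >= t[3] & comp >= complete_threshold] <- 3L
  if (tabular) {
    out <- data.table::copy(data.table::as.data.table(cells))
    out$ihc_class <- cls
    out
  } else {
    cls
  }
}

#' @rdname classify_cells
#' @param membrane_mean_od scalar mean membrane OD of one cell.
#' @export
classify_cell <- function(membrane_mean_od, completeness,
                          od_thresholds = c(0.15, 0.40, 0.70),
                          complete_threshold = 0.8) {
  classify_cells(membrane_mean_od, completeness, od_thresholds,
                 complete_threshold)
}

# class proportions p0..p3 from a class vector
class_proportions <- function(classes) {
  if (length(classes) == 0L) stop("no cells")
  tabulate(classes + 1L, nbins = 4L) / length(classes)
}

#' Field Score of a cell population
#'
#' Combines per-cell classes into the region-level ordinal score per the
#' clinical guideline logic: 3+ when the fraction of strongly and
#' completely stained cells exceeds `strong_complete_min`; otherwise 2+
#' when at least `weak_complete_min` of cells are class 2 or above;
#' otherwise 1+ when at least `weak_complete_min` are class 1 or above;
#' otherwise 0.
#'
#' @param classes integer vector of per-cell classes in 0..3 (a cell
#'   record table with an `ihc_class` column is also accepted).
#' @param weak_complete_min proportion cutoff for 1+/2+ (default 0.10).
#' @param strong_complete_min proportion cutoff for 3+ (default 0.30,
#'   the >30% guideline variant; set to 0.10 for the 10% variant).
#' @return integer field score in 0..3.
#' @export
field_score <- function(classes, weak_complete_min = 0.10,
                        strong_complete_min = 0.30) {
  classes <- as_class_vector(classes)
  p <- class_proportions(classes)
  if (p[4] > strong_complete_min) return(3L)
  if (p[3] + p[4] >= weak_complete_min) return(2L)
  if (p[2] + p[3] + p[4] >= weak_complete_min) return(1L)
  0L
}

#' H-Score of a cell population
#'
#' `H = 100 * (1*p1 + 2*p2 + 3*p3)` on the 0-300 scale, where `pk` is
#' the fraction of cells in class k.
#'
#' @inheritParams field_score
#' @return numeric in \[0, 300\].
#' @export
h_score <- function(classes) {
  classes <- as_class_vector(classes)
  p <- class_proportions(classes)
  100 * (p[2] + 2 * p[3] + 3 * p[4])
}

as_class_vector <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$ihc_class
  classes <- as.integer(classes)
  if (length(classes) == 0L) stop("no cells in region")
  if (any(classes < 0L | classes > 3L)) stop("classes must be in 0..3")
  classes
}

#' Per-class membrane mask area (LO-CMA)
#'
#' Total skeleton pixel area of the cells in each class; converted to
#' square micrometres when the pixel size is known.
#'
#' @param cells classified cell records (columns `ihc_class`,
#'   `membrane_area_px`).
#' @param pixel_size_um optional physical pixel size in micrometres.
#' @return data.table with `ihc_class` (0..3), `area_px` and, when the
#'   pixel size is given, `area_um2`.
#' @export
lo_cma <- function(cells, pixel_size_um = NULL) {
  cells <- data.table::as.data.table(cells)
  area <- numeric(4)
  if (nrow(cells) > 0L) {
    s <- rowsum(as.numeric(cells$membrane_area_px), cells$ihc_class)
    area[as.integer(rownames(s)) + 1L] <- s[, 1]
  }
  out <- data.table::data.table(ihc_class = 0:3, area_px = area)
  if (!is.null(pixel_size_um) && !is.na(pixel_size_um))
    out$area_um2 <- area * pixel_size_um^2
  out
}

#' Score one region of interest
#'
#' Bundles the per-cell classes of one ROI into the region-level report:
#' cell count, class proportions, Field Score, H-Score and LO-CMA.
#'
#' @param cells classified cell records of the ROI.
#' @param pixel_size_um optional pixel size for LO-CMA in micrometres.
#' @param weak_complete_min,strong_complete_min Field Score cutoffs, see
#'   [field_score()].
#' @return An object of class `roi_score`: list with `n_cells`, `prop`
#'   (named p0..p3), `field_score`, `h_score`, `lo_cma`.
#' @export
score_roi <- function(cells, pixel_size_um = NULL,
                      weak_complete_min = 0.10, strong_complete_min = 0.30) {
  cells <- data.table::as.data.table(cells)
  cls <- as_class_vector(cells)
  p <- class_proportions(cls)
  structure(list(
    n_cells = length(cls),
    prop = stats::setNames(p, paste0("p", 0:3)),
    field_score = field_score(cls, weak_complete_min, strong_complete_min),
    h_score = h_score(cls),
    lo_cma = lo_cma(cells, pixel_size_um),
    cells = cells),
    class = "roi_score")
}

#' Aggregate ROI scores to a core score
#'
#' Pools the cells of all regions of one core (cell-weighted) and scores
#' the pooled population; the per-ROI scores are retained. Set
#' `method = "max"` to use the maximum ROI field score instead of the
#' pooled one.
#'
#' @param rois list of `roi_score` objects (each carrying its cells).
#' @param pixel_size_um optional pixel size in micrometres.
#' @param method `"pool"` (default) or `"max"` for the core field score.
#' @param weak_complete_min,strong_complete_min Field Score cutoffs.
#' @return An object of class `core_score`: list with `roi_scores`,
#'   `pooled` (an `roi_score` over all cells) and `core_field_score`.
#' @export
aggregate_core <- function(rois, pixel_size_um = NULL,
                           method = c("pool", "max"),
                           weak_complete_min = 0.10,
                           strong_complete_min = 0.30) {
  method <- match.arg(method)
  if (length(rois) < 1L) stop("at least one ROI is required")
  stopifnot(all(vapply(rois, inherits, TRUE, "roi_score")))
  all_cells <- data.table::rbindlist(lapply(rois, `[[`, "cells"))
  pooled <- score_roi(all_cells, pixel_size_um,
                      weak_complete_min, strong_complete_min)
  cfs <- if (method == "pool") pooled$field_score
         else max(vapply(rois, `[[`, 0L, "field_score"))
  structure(list(roi_scores = rois, pooled = pooled,
                 core_field_score = as.integer(cfs)),
            class = "core_score")
}

#' @export
print.roi_score <- function(x, ...) {
  cat(sprintf(
    "roi_score: %d cells | field score %d | H-score %.1f | p0..p3 = %s\n",
    x$n_cells, x$field_score, x$h_score,
    paste(sprintf("%.2f", x$prop), collapse = " ")))
  invisible(x)
}

#' @export
print.core_score <- function(x, ...) {
  cat(sprintf("core_score: %d ROIs | core field score %d | pooled n = %d\n",
              length(x$roi_scores), x$core_field_score, x$pooled$n_cells))
  invisible(x)
}
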