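#' Score an RGB image inside regions of interest
#'
#' Runs the full chain: optical-density conversion, colour deconvolution,
#' nucleus segmentation on the hematoxylin channel, intensity-based spot
#' linking on the DAB channel with area/border/over-nucleus merging,
#' skeleton extraction, membrane-to-cell assignment, per-cell four-tier
#' classification, and per-ROI / per-core scoring. Segmentation runs once
#' on the whole frame; a cell belongs to an ROI iff its nucleus centroid
#' lies inside the ROI polygon (even-odd rule).
#'
#' @param img H x W x 3 RGB array in \[0, 255\].
#' @param rois list of ROI records (see [read_rois()]); `NULL` scores the
#'   full frame as one ROI.
#' @param config parameter list, see [default_config()].
#' @return list with `cells` (classified records plus `roi_id`), `rois`
#'   (named list of `roi_score` or error records), `cores` (named list of
#'   `core_score`), and the intermediate `nuclei`, `skeleton`,
#'   `channels`, `assignment`.
#' @export
score_image <- function(img, rois = NULL, config = default_config()) {
  img <- check_rgb(img)
  if (is.null(rois)) rois <- full_frame_roi(dim(img)[1:2])
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_along(rois)) {
    poly <- rois[[i]]$polygon
    if (any(poly[, 1] < 0 | poly[, 1] > h - 1 |
            poly[, 2] < 0 | poly[, 2] > w - 1)) {
      warning("ROI ", rois[[i]]$roi_id, " extends beyond the image; clipping")
      poly[, 1] <- pmin(pmax(poly[, 1], 0), h - 1)
      poly[, 2] <- pmin(pmax(poly[, 2], 0), w - 1)
      rois[[i]]$polygon <- poly
    }
  }
  sv <- stain_vectors(config$stains$dab, config$stains$hematoxylin)
  od <- rgb_to_od(img, config$stains$background_level)
  ch <- deconvolve(od, sv)
  np <- config$nuclei
  nuclei <- segment_nuclei(ch$hem_od, sigma = np$sigma,
                           threshold = np$threshold,
                           min_nucleus_area = np$min_nucleus_area,
                           split_touching = np$split_touching,
                           watershed_tolerance = np$watershed_tolerance)
  mp <- config$membrane
  part <- partition_spots(-ch$dab_od, smoothing_sigma = mp$smoothing_sigma,
                          dab_od = ch$dab_od)
  part <- merge_spots(part, min_spot_area = mp$min_spot_area,
                      min_border_length = mp$min_border_length,
                      protect_min_od = mp$protect_min_od)
  part <- merge_over_nuclei(part, nuclei,
                            over_nucleus_threshold = mp$over_nucleus_threshold)
  skel <- extract_skeleton(part, nuclei,
                           min_segment_length = mp$min_segment_length,
                           min_mean_od = mp$min_mean_od)
  sp <- config$scoring
  cells <- assign_membrane_to_cells(nuclei, skel, ch$dab_od,
                                    max_radius_px = sp$max_radius_px,
                                    n_angle_bins = sp$n_angle_bins)
  assignment <- attr(cells, "pixel_assignment")
  cells <- classify_cells(cells, od_thresholds = sp$od_thresholds,
                          complete_threshold = sp$complete_threshold)

  cells$roi_id <- NA_character_
  roi_scores <- list()
  core_members <- list()
  for (r in rois) {
    inside <- point_in_polygon(cbind(cells$row, cells$col), r$polygon)
    take <- inside & is.na(cells$roi_id)
    cells$roi_id[take] <- r$roi_id
    sub <- cells[take, ]
    if (nrow(sub) == 0L) {
      roi_scores[[r$roi_id]] <- list(roi_id = r$roi_id,
                                     core_id = r$core_id,
                                     error = "no cells in ROI")
      next
    }
    sc <- score_roi(sub, pixel_size_um = sp$pixel_size_um,
                    weak_complete_min = sp$weak_complete_min,
                    strong_complete_min = sp$strong_complete_min)
    sc$roi_id <- r$roi_id
    sc$core_id <- r$core_id
    roi_scores[[r$roi_id]] <- sc
    core_members[[r$core_id]] <- c(core_members[[r$core_id]],
                                   list(sc))
  }
  cores <- lapply(core_members, function(ms)
    aggregate_core(ms, pixel_size_um = sp$pixel_size_um,
                   method = sp$core_aggregation,
                   weak_complete_min = sp$weak_complete_min,
                   strong_complete_min = sp$strong_complete_min))
  list(cells = cells, rois = roi_scores, cores = cores, nuclei = nuclei,
       skeleton = skel, channels = ch, assignment = assignment,
       image = img)
}

roi_score_json <- function(sc) {
  if (!is.null(sc$error))
    return(list(roi_id = sc$roi_id, core_id = sc$core_id,
                error = sc$error))
  out <- list(roi_id = sc$roi_id, core_id = sc$core_id,
              n_cells = sc$n_cells, prop = as.list(sc$prop),
              field_score = sc$field_score, h_score = sc$h_score,
              lo_cma = stats::setNames(as.list(sc$lo_cma$area_px),
                                       paste0("class", 0:3)))
  if ("area_um2" %in% names(sc$lo_cma))
    out$lo_cma_um2 <- stats::setNames(as.list(sc$lo_cma$area_um2),
                                      paste0("class", 0:3))
  out
}

#' Score an image from disk and write the result files
#'
#' Command-style wrapper around [score_image()]: reads the image and the
#' ROI annotations, scores, and writes `cells.csv` (one row per cell),
#' `scores.json` (per-ROI and per-core reports) and `overlay.png`
#' (class-coded rendering) into `out_dir`.
#'
#' @param image_path TIFF or PNG image.
#' @param roi_path optional ROI JSON; `NULL` scores the full frame.
#' @param config configuration list or YAML path.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the [score_image()] result.
#' @export
score_command <- function(image_path, roi_path = NULL,
                          config = default_config(), out_dir = ".") {
  if (is.character(config)) config <- read_config(config)
  img <- read_image(image_path)
  rois <- if (is.null(roi_path)) NULL else read_rois(roi_path)
  res <- score_image(img, rois, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cells_out <- res$cells[, c("cell_id", "row", "col", "membrane_mean_od",
                             "completeness", "membrane_area_px",
                             "ihc_class", "roi_id")]
  data.table::fwrite(cells_out, file.path(out_dir, "cells.csv"))

  report <- list(
    rois = lapply(unname(res$rois), roi_score_json),
    cores = lapply(names(res$cores), function(cid) {
      co <- res$cores[[cid]]
      pooled <- roi_score_json(co$pooled)
      pooled$roi_id <- NULL; pooled$core_id <- NULL
      list(core_id = cid, core_field_score = co$core_field_score,
           n_rois = length(co$roi_scores), pooled = pooled)
    }))
  jsonlite::write_json(report, file.path(out_dir, "scores.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cell_of_pixel <- integer(sum(res$skeleton$skeleton_mask))
  if (nrow(res$assignment) > 0L) {
    px_all <- which(res$skeleton$skeleton_mask)
    m <- match(res$assignment$px, px_all)
    cell_of_pixel[m] <- res$assignment$cell
  }
  ov <- render_overlay(res$image, res$nuclei, res$skeleton, res$cells,
                       cell_of_pixel)
  write_image(ov, file.path(out_dir, "overlay.png"))
  invisible(res)
}

#' Agreement report for paired ordinal scores
#'
#' Reads a paired-score CSV (`case_id`, `score_a`, `score_b`, values in
#' 0..3), computes Cohen's kappa, the quadratic weighted kappa (both with
#' Landis-Koch labels and confidence intervals) and the Spearman rank
#' correlation, and writes a JSON report.
#'
#' @param pairs_csv input CSV path.
#' @param out_json output JSON path (`NULL` skips writing).
#' @param config configuration list or YAML path (stats section used).
#' @return (invisibly) the report list.
#' @export
agree_command <- function(pairs_csv, out_json = NULL,
                          config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  df <- utils::read.csv(pairs_csv)
  if (nrow(df) == 0L) stop("empty score CSV: ", pairs_csv)
  need <- c("score_a", "score_b")
  if (!all(need %in% names(df)))
    stop("CSV must have columns score_a and score_b")
  for (cn in need) {
    bad <- which(!df[[cn]] %in% 0:3)
    if (length(bad) > 0L)
      stop("malformed score in column ", cn, ", row ", bad[1],
           ": ", df[[cn]][bad[1]])
  }
  st <- config$stats
  tab <- confusion(df$score_a, df$score_b)
  kap <- cohen_kappa(tab, ci_method = st$ci_method,
                     conf_level = st$conf_level, n_boot = st$n_boot,
                     seed = config$seed)
  wk <- weighted_kappa(tab, quadratic_weights(4), ci_method = st$ci_method,
                       conf_level = st$conf_level, n_boot = st$n_boot,
                       seed = config$seed)
  sp <- spearman_ci(df$score_a, df$score_b, conf_level = st$conf_level)
  report <- list(
    n = nrow(df),
    cohen_kappa = list(kappa = kap$kappa, ci_low = kap$ci_low,
                       ci_high = kap$ci_high,
                       strength = kap$strength_label),
    weighted_kappa = list(kappa = wk$kappa, ci_low = wk$ci_low,
                          ci_high = wk$ci_high,
                          strength = wk$strength_label,
                          weights = wk$weights),
    spearman = sp,
    table = tab)
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, matrix = "rowmajor")
  invisible(report)
}

#' Two-group feature comparison table
#'
#' Reads a per-case feature CSV (`case_id`, `fish_status` with exactly
#' two levels, numeric feature columns), compares the groups per feature
#' and writes a wide comparison table: one column block per feature and
#' group, rows `p`, `Average`, `SD`, `Min.`, `Max.`.
#'
#' @param features_csv input CSV path.
#' @param out_csv output CSV path (`NULL` skips writing).
#' @param config configuration list or YAML path (stats section used).
#' @return (invisibly) the [group_compare()] result.
#' @export
compare_command <- function(features_csv, out_csv = NULL,
                            config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  df <- utils::read.csv(features_csv, check.names = FALSE)
  if (!"fish_status" %in% names(df))
    stop("CSV must have a fish_status column")
  g <- factor(df$fish_status)
  if (nlevels(g) != 2L)
    stop("fish_status must have exactly two levels, found ", nlevels(g))
  feats <- df[, !(names(df) %in% c("case_id", "fish_status")), drop = FALSE]
  res <- group_compare(feats, g, test = config$stats$group_test)
  if (!is.null(out_csv)) {
    lv <- levels(g)
    wide <- matrix("", nrow = 5L, ncol = 2L * nrow(res),
                   dimnames = list(c("p", "Average", "SD", "Min.", "Max."),
                                   NULL))
    cn <- character(2L * nrow(res))
    for (i in seq_len(nrow(res))) {
      for (j in 1:2) {
        col <- 2L * (i - 1L) + j
        cn[col] <- paste0(res$feature[i], " | ", lv[j])
        wide["p", col] <- if (j == 1L)
          format(res$p_value[i], digits = 6) else ""
        wide["Average", col] <- format(res[[paste0("mean_", lv[j])]][i],
                                       digits = 7)
        wide["SD", col] <- format(res[[paste0("sd_", lv[j])]][i],
                                  digits = 7)
        wide["Min.", col] <- format(res[[paste0("min_", lv[j])]][i],
                                    digits = 7)
        wide["Max.", col] <- format(res[[paste0("max_", lv[j])]][i],
                                    digits = 7)
      }
    }
    colnames(wide) <- cn
    out <- data.frame(statistic = rownames(wide), wide,
                      check.names = FALSE)
    data.table::fwrite(out, out_csv)
  }
  invisible(res)
}

#' Generate and write a synthetic tile with its ground truth
#'
#' Writes `tile.tiff` (RGB), `nucleus_mask.tiff` and
#' `membrane_mask.tiff` (16-bit), `truth_cells.csv` and `truth.json`
#' into `out_dir`.
#'
#' @param out_dir output directory.
#' @param ... passed to [generate_tile()].
#' @return (invisibly) the `synthetic_tile`.
#' @export
simulate_command <- function(out_dir = ".", ...) {
  tile <- generate_tile(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_image(tile$image, file.path(out_dir, "tile.tiff"))
  write_label_tiff(tile$truth$nucleus_mask * 1L,
                   file.path(out_dir, "nucleus_mask.tiff"))
  write_label_tiff(tile$truth$membrane_mask * 1L,
                   file.path(out_dir, "membrane_mask.tiff"))
  data.table::fwrite(tile$truth$cells,
                     file.path(out_dir, "truth_cells.csv"))
  jsonlite::write_json(
    list(proportions = as.list(tile$truth$proportions),
         intended_field_score = tile$truth$intended_field_score,
         intended_h_score = tile$truth$intended_h_score,
         params = tile$truth$params),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(tile)
}
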