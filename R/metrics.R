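#' Evaluate a scored synthetic tile against its ground truth
#'
#' Recovery metrics used by the validation suite:
#' \describe{
#'   \item{nucleus precision/recall}{one-to-one greedy matching of
#'     detected nucleus centroids to ground-truth cell centres within
#'     `match_radius_px`.}
#'   \item{membrane recovery}{fraction of ground-truth membrane pixels
#'     with drawn OD >= `recovery_min_od` lying within one pixel
#'     (8-neighbourhood, Chebyshev distance <= 1) of the recovered
#'     skeleton. Faint class-0 stubs sit below the pipeline's own
#'     signal-retention threshold and are excluded by the OD cutoff.}
#'   \item{proportion error}{largest absolute difference between
#'     measured and ground-truth class proportions.}
#'   \item{field score match}{whether the measured full-frame Field
#'     Score equals the generator's intended score.}
#' }
#'
#' @param tile a `synthetic_tile` from [generate_tile()].
#' @param result a [score_image()] result for `tile$image`; computed
#'   here when omitted.
#' @param match_radius_px centroid matching radius (default 3).
#' @param recovery_min_od ground-truth membrane OD cutoff for the
#'   recovery metric (default 0.4).
#' @param config configuration used when `result` is computed here.
#' @return list with `nucleus_precision`, `nucleus_recall`,
#'   `membrane_recovery`, `prop_error`, `field_score_match`,
#'   `measured_prop`, `true_prop`, `measured_field_score`,
#'   `intended_field_score`, `measured_h_score`, `intended_h_score`.
#' @export
evaluate_tile <- function(tile, result = NULL, match_radius_px = 3,
                          recovery_min_od = 0.4,
                          config = default_config()) {
  stopifnot(inherits(tile, "synthetic_tile"))
  if (is.null(result)) result <- score_image(tile$image, config = config)
  truth <- tile$truth

  det <- result$nuclei$centroids
  tru <- cbind(truth$cells$row, truth$cells$col)
  matched <- match_points(tru, det, match_radius_px)
  recall <- sum(!is.na(matched)) / nrow(tru)
  precision <- if (nrow(det) == 0L) 1 else
    sum(!is.na(matched)) / nrow(det)

  gt <- truth$membrane_mask & truth$dab_truth >= recovery_min_od
  sk <- result$skeleton$skeleton_mask
  near <- as.matrix(EBImage::dilate(EBImage::Image(sk * 1),
                                    EBImage::makeBrush(3, "box"))) > 0
  recovery <- if (!any(gt)) 1 else mean(near[gt])

  roi <- result$rois[[1]]
  prop_error <- max(abs(roi$prop - truth$proportions))
  list(nucleus_precision = precision,
       nucleus_recall = recall,
       membrane_recovery = recovery,
       prop_error = prop_error,
       field_score_match = roi$field_score == truth$intended_field_score,
       measured_prop = roi$prop,
       true_prop = truth$proportions,
       measured_field_score = roi$field_score,
       intended_field_score = truth$intended_field_score,
       measured_h_score = roi$h_score,
       intended_h_score = truth$intended_h_score)
}

# greedy one-to-one matching of truth points to detected points within a
# radius; returns, per truth point, the matched detection index or NA
match_points <- function(truth, detected, radius) {
  if (nrow(truth) == 0L)
    return(integer(0))
  out <- rep(NA_integer_, nrow(truth))
  if (is.null(detected) || nrow(detected) == 0L) return(out)
  d2 <- outer(truth[, 1], detected[, 1], "-")^2 +
    outer(truth[, 2], detected[, 2], "-")^2
  r2 <- radius^2
  used <- rep(FALSE, nrow(detected))
  ord <- order(apply(d2, 1L, min))
  for (i in ord) {
    j <- which.min(ifelse(used, Inf, d2[i, ]))
    if (length(j) == 1L && !used[j] && d2[i, j] <= r2) {
      out[i] <- j
      used[j] <- TRUE
    }
  }
  out
}
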