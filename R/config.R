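#' Default run configuration
#'
#' Full parameter schema for the scoring pipeline, in named sections:
#' `stains` (the deconvolution basis and background level), `nuclei`
#' (nucleus segmentation), `membrane` (spot linking, merging and skeleton
#' filters), `scoring` (class thresholds and Field Score cutoffs),
#' `stats` (agreement/comparison options) and `seed`. Every parameter has
#' a documented default; the list round-trips through YAML unchanged.
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    stains = list(
      dab = c(0.269, 0.568, 0.778),
      hematoxylin = c(0.650, 0.704, 0.286),
      background_level = 255),
    nuclei = list(
      sigma = 1.5,
      threshold = "otsu",
      min_nucleus_area = 30,
      split_touching = TRUE,
      watershed_tolerance = 1),
    membrane = list(
      smoothing_sigma = 1.0,
      min_spot_area = 25,
      min_border_length = 5,
      protect_min_od = 0.1,
      over_nucleus_threshold = 0.5,
      min_segment_length = 10,
      min_mean_od = 0.1),
    scoring = list(
      od_thresholds = c(0.15, 0.40, 0.70),
      complete_threshold = 0.8,
      max_radius_px = 25,
      n_angle_bins = 24,
      weak_complete_min = 0.10,
      strong_complete_min = 0.30,
      core_aggregation = "pool",
      pixel_size_um = NA),
    stats = list(
      ci_method = "bootstrap",
      n_boot = 2000,
      conf_level = 0.95,
      group_test = "welch"),
    seed = 20130930)
}

#' Read / write a run configuration
#'
#' YAML round trip of the parameter schema; missing sections or entries
#' fall back to [default_config()] values, unknown entries are an error.
#'
#' @param path YAML file path.
#' @return `read_config`: the merged configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  merge_config(default_config(), raw)
}

#' @rdname read_config
#' @param config configuration list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration entry: ", nm)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      v <- override[[nm]]
      if (is.list(v)) v <- unlist(v)
      base[[nm]] <- v
    }
  }
  base
}
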