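#' Read an 8-bit RGB image (TIFF or PNG)
#'
#' @param path image path; format chosen by extension.
#' @return H x W x 3 integer array in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)"))
  d <- dim(img)
  if (length(d) == 2L) img <- array(rep(img, 3L), c(d, 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}

#' Write an 8-bit RGB image (TIFF or PNG)
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param path output path; format chosen by extension.
#' @export
write_image <- function(img, path) {
  x <- img / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a label map as 16-bit single-channel TIFF
#'
#' @param labels H x W integer matrix (values in 0..65535).
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return H x W integer matrix.
#' @export
read_label_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

# class colour code of the result rendering (0-255 RGB)
class_colors <- function() {
  rbind(`1` = c(255, 255, 0),    # 1+: yellow
        `2` = c(255, 165, 0),    # 2+: orange
        `3` = c(255, 0, 0))      # 3+: red
}

#' Render the colour-coded scoring overlay
#'
#' Paints the classified result over the original image: nuclei in blue,
#' membrane skeleton pixels in the class colour of their cell (yellow
#' 1+, orange 2+, red 3+); class-0 cells keep the blue nucleus only.
#'
#' @param img original H x W x 3 image in \[0, 255\].
#' @param nuclei a `nucleus_labels` object.
#' @param skeleton a `membrane_skeleton` object.
#' @param cells classified cell records (with `ihc_class`).
#' @param cell_of_pixel integer vector: cell id per skeleton pixel (0 =
#'   unassigned), aligned with `which(skeleton$skeleton_mask)`.
#' @return H x W x 3 overlay array in \[0, 255\].
#' @export
render_overlay <- function(img, nuclei, skeleton, cells, cell_of_pixel) {
  out <- img
  n_px <- prod(dim(img)[1:2])
  nuc <- which(nuclei$labels > 0L)
  out[nuc] <- 40; out[nuc + n_px] <- 70; out[nuc + 2L * n_px] <- 220
  px <- which(skeleton$skeleton_mask)
  cols <- class_colors()
  if (length(px) > 0L && nrow(cells) > 0L) {
    cls <- rep(0L, length(px))
    ok <- cell_of_pixel > 0L
    cls[ok] <- cells$ihc_class[match(cell_of_pixel[ok], cells$cell_id)]
    for (k in 1:3) {
      sel <- px[cls == k]
      out[sel] <- cols[k, 1]
      out[sel + n_px] <- cols[k, 2]
      out[sel + 2L * n_px] <- cols[k, 3]
    }
  }
  out
}
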