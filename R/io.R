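#' Read and write 8-bit images and point tables
#'
#' Thin wrappers over the tiff package keeping the package's fixed 0..255
#' intensity convention: images are stored as 8-bit TIFF and come back as
#' numeric matrices in gray levels. Multi-page files return a list of
#' matrices (a z-stack ready for [max_project()]).
#'
#' @param path File path.
#' @return `read_image_8bit()`: a matrix (single page) or list of matrices.
#' @export
read_image_8bit <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB pages
    round(p * 255)
  })
  if (length(pages) == 1) pages[[1]] else pages
}

#' @rdname read_image_8bit
#' @param image Matrix (or list of matrices) with values in 0..255.
#' @export
write_image_8bit <- function(image, path) {
  if (is.matrix(image)) image <- list(image)
  tiff::writeTIFF(lapply(image, function(m) pmin(pmax(m, 0), 255) / 255),
                  path, bits.per.sample = 8L)
  invisible(path)
}

#' Import externally provided cell centers
#'
#' Supports manually placed centers (the center-dot workflow) exported as
#' CSV with columns `x_um`, `y_um` and optional `id`, `marker`.
#'
#' @param path CSV path.
#' @param window `c(width_um, height_um)` of the frame.
#' @return A [point_pattern()] with an `id` column.
#' @export
read_cell_centers <- function(path, window) {
  df <- as_tibble(read.csv(path))
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  as_point_pattern(df, window = window)
}

#' Read ROI polygons from JSON
#'
#' The interchange format is a JSON object mapping region names to rings:
#' each ring is a list of `[x_um, y_um]` vertex pairs (or an object with
#' `x`/`y` arrays).
#'
#' @param path JSON file path.
#' @return Named list of two-column vertex matrices.
#' @export
read_roi_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(js, function(r) {
    m <- if (is.list(r) && !is.null(r$x)) cbind(r$x, r$y) else as.matrix(r)
    storage.mode(m) <- "numeric"
    colnames(m) <- c("x_um", "y_um")
    m
  })
}

#' @rdname read_roi_json
#' @param rois Named list of two-column vertex matrices.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(lapply(rois, function(m) unname(as.matrix(m))),
                       path, digits = NA)
  invisible(path)
}
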