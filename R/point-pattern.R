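#' Planar point patterns in physical coordinates
#'
#' A point pattern is a tibble of cell (or punctum) centers in micrometres,
#' carrying its rectangular observation window as an attribute. Coordinates
#' are continuous; rasterisation only happens when a pattern is rendered to
#' an image. The window origin is the top-left corner of the frame, with
#' `y_um` increasing downwards (image convention).
#'
#' @param x,y Numeric vectors of coordinates in micrometres.
#' @param window Numeric length-2 vector `c(width_um, height_um)`.
#' @param ... Additional columns (e.g. `marker`, `parent_id`) recycled to the
#'   number of points.
#'
#' @return A tibble of class `point_pattern` with columns `x_um`, `y_um` and
#'   any extra columns, and attribute `window`.
#' @examples
#' pp <- point_pattern(c(10, 50), c(20, 60), window = c(100, 100))
#' pp_area(pp)
#' @export
point_pattern <- function(x, y, window, ...) {
  stopifnot(length(x) == length(y))
  check_positive(window, "window")
  if (length(window) != 2L) abort("`window` must be c(width_um, height_um)")
  if (length(x) > 0 &&
      (any(x < 0 | x > window[1]) || any(y < 0 | y > window[2]))) {
    abort("all points must lie inside the window")
  }
  out <- tibble(x_um = as.numeric(x), y_um = as.numeric(y), ...)
  attr(out, "window") <- as.numeric(window)
  class(out) <- c("point_pattern", class(out))
  out
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
pp_window <- function(pattern) {
  w <- attr(pattern, "window")
  if (is.null(w)) abort("`pattern` has no window attribute")
  w
}

#' @rdname point_pattern
#' @export
pp_area <- function(pattern) prod(pp_window(pattern))

#' Coerce a data frame of coordinates to a point pattern
#'
#' @param df Data frame with columns `x_um`, `y_um` (extra columns kept).
#' @param window Numeric `c(width_um, height_um)`.
#' @return A `point_pattern`.
#' @export
as_point_pattern <- function(df, window) {
  if (!all(c("x_um", "y_um") %in% names(df))) {
    abort("`df` must have columns `x_um` and `y_um`")
  }
  extra <- df[setdiff(names(df), c("x_um", "y_um"))]
  rlang::exec(point_pattern, x = df$x_um, y = df$y_um, window = window, !!!extra)
}
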