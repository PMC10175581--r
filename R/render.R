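#' Render a point pattern as an 8-bit fluorescence channel
#'
#' Each point becomes an isotropic Gaussian blob (a soma profile) of peak
#' `amplitude` gray levels on a flat `background`, plus i.i.d. Gaussian read
#' noise. Values are rounded and clipped to the 8-bit range on a fixed linear
#' scale (1 AU = 1 gray level), never rescaled per image, so the fixed
#' thresholds used downstream (70 for astrocyte masks, 30 for puncta) retain
#' a stable meaning across scenes.
#'
#' @param points A [point_pattern()].
#' @param soma_sigma_um Gaussian blob standard deviation in um (> 0).
#' @param amplitude Peak blob intensity above background, gray levels (> 0).
#' @param background Constant background level, gray levels (>= 0).
#' @param noise_sd Read-noise standard deviation, gray levels (>= 0).
#' @param pixel_size_um Pixel size in um/px (> 0).
#' @param seed Integer seed (only the noise consumes randomness).
#' @return Numeric matrix (rows = y, cols = x) with values in 0..255; pixel
#'   (r, c) has center coordinates `((c - 0.5) * pixel_size_um,
#'   (r - 0.5) * pixel_size_um)`.
#' @examples
#' pp <- point_pattern(50, 50, window = c(100, 100))
#' img <- render_channel(pp, soma_sigma_um = 3, amplitude = 150,
#'                       background = 10, noise_sd = 0, pixel_size_um = 1,
#'                       seed = 1)
#' which(img == max(img), arr.ind = TRUE)
#' @export
render_channel <- function(points, soma_sigma_um, amplitude, background = 0,
                           noise_sd = 0, pixel_size_um = 1, seed = 0) {
  check_positive(soma_sigma_um, "soma_sigma_um")
  check_positive(amplitude, "amplitude")
  check_positive(background, "background", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(pixel_size_um, "pixel_size_um")
  window <- pp_window(points)
  nx <- round(window[1] / pixel_size_um)
  ny <- round(window[2] / pixel_size_um)
  if (nx < 1 || ny < 1) abort("`pixel_size_um` larger than the window")
  img <- matrix(background, nrow = ny, ncol = nx)
  sig_px <- soma_sigma_um / pixel_size_um
  half <- ceiling(4 * sig_px)
  for (i in seq_len(nrow(points))) {
    cx <- points$x_um[i] / pixel_size_um + 0.5  # continuous pixel coords
    cy <- points$y_um[i] / pixel_size_um + 0.5
    cols <- max(1L, floor(cx - half)):min(nx, ceiling(cx + half))
    rows <- max(1L, floor(cy - half)):min(ny, ceiling(cy + half))
    gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
    img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(ny * nx, 0, noise_sd), ny, nx))
  }
  pmin(pmax(round(img), 0), 255)
}

#' Rasterise ellipses into a binary fascicle mask
#'
#' White-matter fascicle cross-sections are modelled as filled ellipses; a
#' pixel belongs to the mask when its center falls inside any ellipse.
#'
#' @param fascicle_specs Data frame with columns `cx_um`, `cy_um`, `a_um`,
#'   `b_um` (semi-axes) and `theta` (orientation, radians); or `NULL` for an
#'   empty mask.
#' @param window `c(width_um, height_um)`.
#' @param pixel_size_um Pixel size in um/px.
#' @return Logical matrix (rows = y, cols = x).
#' @export
fascicle_mask <- function(fascicle_specs, window, pixel_size_um) {
  check_positive(window, "window")
  check_positive(pixel_size_um, "pixel_size_um")
  nx <- round(window[1] / pixel_size_um)
  ny <- round(window[2] / pixel_size_um)
  mask <- matrix(FALSE, ny, nx)
  if (is.null(fascicle_specs) || nrow(fascicle_specs) == 0) return(mask)
  xs <- (seq_len(nx) - 0.5) * pixel_size_um
  ys <- (seq_len(ny) - 0.5) * pixel_size_um
  px <- matrix(xs, ny, nx, byrow = TRUE)
  py <- matrix(ys, ny, nx)
  for (i in seq_len(nrow(fascicle_specs))) {
    e <- fascicle_specs[i, ]
    th <- e$theta %||% 0
    dx <- px - e$cx_um
    dy <- py - e$cy_um
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- mask | ((u / e$a_um)^2 + (v / e$b_um)^2 <= 1)
  }
  mask
}
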