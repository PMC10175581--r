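# Plain-matrix polygon helpers (no simple-features stack required): shoelace
# area, Sutherland-Hodgman clipping against axis-aligned half-planes, and
# point-in-polygon lookups (delegated to mgcv's compiled in/out test).

#' Polygon area by the shoelace formula
#'
#' @param poly Two-column matrix or data frame of vertices (x_um, y_um),
#'   open or closed ring.
#' @return Absolute area in um^2.
#' @export
polygon_area <- function(poly) {
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Clip polygon by a half-plane: keep side where a*x + b*y <= c.
clip_halfplane <- function(p, a, b, c) {
  n <- nrow(p)
  if (n == 0) return(p)
  out <- matrix(numeric(0), ncol = 2)
  f <- a * p[, 1] + b * p[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cur_in <- f[i] <= 1e-12
    nxt_in <- f[j] <= 1e-12
    if (cur_in) out <- rbind(out, p[i, ])
    if (cur_in != nxt_in) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, p[i, ] + t * (p[j, ] - p[i, ]))
    }
  }
  out
}

# Clip a simple polygon to an axis-aligned rectangle c(xmin, xmax, ymin, ymax).
clip_polygon_rect <- function(poly, rect) {
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p <- clip_halfplane(p, -1, 0, -rect[1])  # x >= xmin
  p <- clip_halfplane(p, 1, 0, rect[2])    # x <= xmax
  p <- clip_halfplane(p, 0, -1, -rect[3])  # y >= ymin
  p <- clip_halfplane(p, 0, 1, rect[4])    # y <= ymax
  p
}

# Vectorised point-in-polygon (TRUE on the inside; boundary behaviour per
# mgcv::in.out's even-odd rule).
points_in_polygon <- function(x, y, poly) {
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  if (nrow(p) < 3) return(rep(FALSE, length(x)))
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  mgcv::in.out(p, cbind(as.numeric(x), as.numeric(y)))
}

# Logical pixel mask of a polygon on the frame grid (pixel-center rule).
rasterize_polygon <- function(poly, dim_rc, pixel_size_um) {
  ny <- dim_rc[1]; nx <- dim_rc[2]
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  cmin <- max(1L, floor(min(p[, 1]) / pixel_size_um))
  cmax <- min(nx, ceiling(max(p[, 1]) / pixel_size_um) + 1)
  rmin <- max(1L, floor(min(p[, 2]) / pixel_size_um))
  rmax <- min(ny, ceiling(max(p[, 2]) / pixel_size_um) + 1)
  mask <- matrix(FALSE, ny, nx)
  if (cmin > cmax || rmin > rmax) return(mask)
  cols <- cmin:cmax; rows <- rmin:rmax
  xs <- (cols - 0.5) * pixel_size_um
  ys <- (rows - 0.5) * pixel_size_um
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- points_in_polygon(gx, gy, p)
  mask[rows, cols] <- matrix(inside, length(rows), length(cols))
  mask
}
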