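#' Maximum-intensity projection of a z-stack
#'
#' Collapses a 3D acquisition to a single 2D image by taking the per-pixel
#' maximum across planes, the standard way confocal stacks are condensed
#' before thresholding.
#'
#' @param stack A 3D array (rows, cols, planes), a list of equally sized
#'   matrices, or a single matrix (returned unchanged).
#' @return A numeric matrix.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0) abort("empty stack")
    dims <- vapply(stack, dim, integer(2))
    if (any(dims != dims[, 1])) abort("stack planes differ in size")
    stack <- array(unlist(stack), dim = c(dims[, 1], length(stack)))
  }
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    abort("`stack` must be a matrix, 3D array, or list of matrices")
  }
  apply(stack, c(1, 2), max)
}

# Label connected components of a binary mask. EBImage::bwlabel is
# 4-connected; for 8-connectivity, labels touching only diagonally are merged
# with a union-find over the (small) label adjacency set.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  k <- max(lab)
  if (connectivity == 8 && k > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal pairs
    c2 <- lab[-nr, -1]; d <- lab[-1, -nc]   # down-left diagonal pairs
    pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                   cbind(as.vector(c2), as.vector(d)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0) {
      roots <- uf_components(k, unique(pairs))
      new_id <- match(roots, sort(unique(roots)))
      lab[lab > 0] <- new_id[lab[lab > 0]]
    }
  }
  lab
}

# Dilate a binary mask by a Euclidean disc of physical radius, via the exact
# distance transform: a pixel joins the dilation when its center lies within
# `radius_um` of a mask pixel center.
dilate_mask <- function(mask, radius_um, pixel_size_um) {
  if (radius_um <= 0 || !any(mask)) return(mask != 0)
  r_px <- radius_um / pixel_size_um
  dmap <- EBImage::distmap(matrix(as.numeric(mask == 0), nrow(mask), ncol(mask)))
  mask != 0 | dmap <= r_px
}

#' Threshold a channel and extract labeled objects
#'
#' Applies a fixed 8-bit threshold (`image >= threshold`), labels
#' 8-connected components, discards components below `min_area_um2`, and
#' summarises each object by its intensity-weighted centroid, area, and mean
#' intensity. The fixed thresholds in routine use are 70 gray levels for
#' astrocyte (GFAP) masks and 30 for aggregate puncta.
#'
#' @param image Numeric matrix with values in 0..255 (use [max_project()]
#'   first for stacks).
#' @param threshold Gray level in `[0, 255]`.
#' @param min_area_um2 Minimum object area retained (um^2); defaults to 20
#'   (somata). Use ~0.2 for puncta.
#' @param pixel_size_um Pixel size in um/px.
#' @param channel_name Label carried into results.
#' @return A list of class `segmentation`: `channel_name`, `threshold`,
#'   `pixel_size_um`, `label_mask` (integer matrix, 0 = background), and
#'   `objects`, a tibble (`id`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity`, `on_border`).
#' @examples
#' img <- matrix(0, 20, 20); img[5:8, 5:8] <- 200
#' seg <- segment_channel(img, threshold = 70, min_area_um2 = 1,
#'                        pixel_size_um = 1)
#' seg$objects
#' @export
segment_channel <- function(image, threshold, min_area_um2 = 20,
                            pixel_size_um = 1, channel_name = "channel") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric 2D matrix (project stacks first)")
  }
  if (min(image) < 0 || max(image) > 255) {
    abort("`image` must be 8-bit (values in 0..255)")
  }
  if (threshold < 0 || threshold > 255) abort("`threshold` must be in [0, 255]")
  check_positive(min_area_um2, "min_area_um2", strict = FALSE)
  check_positive(pixel_size_um, "pixel_size_um")

  lab <- label_components(image >= threshold, connectivity = 8)
  k <- max(lab)
  px_area <- pixel_size_um^2
  if (k == 0) {
    objects <- tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), mean_intensity = numeric(),
                      on_border = logical())
    return(structure(list(channel_name = channel_name, threshold = threshold,
                          pixel_size_um = pixel_size_um, label_mask = lab,
                          objects = objects), class = "segmentation"))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  v <- image[idx]
  row <- ((idx - 1) %% nrow(lab)) + 1
  col <- ((idx - 1) %/% nrow(lab)) + 1
  npix <- tabulate(l, nbins = k)
  wsum <- rowsum_by(v, l, k)
  # Intensity-weighted centroid in physical coordinates (pixel centers).
  cx <- rowsum_by(v * (col - 0.5), l, k) / wsum * pixel_size_um
  cy <- rowsum_by(v * (row - 0.5), l, k) / wsum * pixel_size_um
  border <- rowsum_by(as.numeric(row == 1 | row == nrow(lab) |
                                   col == 1 | col == ncol(lab)), l, k) > 0
  objects <- tibble(id = seq_len(k), x_um = cx, y_um = cy,
                    area_um2 = npix * px_area,
                    mean_intensity = wsum / npix, on_border = border)
  keep <- objects$area_um2 >= min_area_um2
  if (!all(keep)) {
    drop_ids <- objects$id[!keep]
    lab[lab %in% drop_ids] <- 0L
    remap <- integer(k)
    remap[objects$id[keep]] <- seq_len(sum(keep))
    lab[lab > 0] <- remap[lab[lab > 0]]
    objects <- objects[keep, ]
    objects$id <- seq_len(nrow(objects))
  }
  structure(list(channel_name = channel_name, threshold = threshold,
                 pixel_size_um = pixel_size_um, label_mask = lab,
                 objects = objects), class = "segmentation")
}

rowsum_by <- function(x, group, k) {
  out <- numeric(k)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s @ threshold %g: %d objects\n",
              x$channel_name, x$threshold, nrow(x$objects)))
  invisible(x)
}

#' @method tidy segmentation
#' @export
tidy.segmentation <- function(x, ...) x$objects

#' @method glance segmentation
#' @export
glance.segmentation <- function(x, ...) {
  tibble(channel_name = x$channel_name, threshold = x$threshold,
         n_objects = nrow(x$objects),
         total_area_um2 = sum(x$objects$area_um2))
}
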