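#' Per-frame cell counts normalised to a reference area
#'
#' Cells on the frame border are included (the counting rule used for the
#' tissue frames this mirrors), and the raw count is rescaled linearly to a
#' reference area, by default the 0.4 mm^2 epifluorescence frame.
#'
#' @param cells Data frame of cell records (one row per cell); only the row
#'   count is used.
#' @param frame_area_mm2 Area actually imaged, mm^2 (> 0).
#' @param reference_area_mm2 Area the count is normalised to (default 0.4).
#' @return One-row tibble: `n`, `frame_area_mm2`, `count_per_reference`.
#' @examples
#' count_cells_per_frame(data.frame(id = 1:6), frame_area_mm2 = 0.2)
#' @export
count_cells_per_frame <- function(cells, frame_area_mm2,
                                  reference_area_mm2 = 0.4) {
  check_positive(frame_area_mm2, "frame_area_mm2")
  check_positive(reference_area_mm2, "reference_area_mm2")
  n <- nrow(cells)
  tibble(n = n, frame_area_mm2 = frame_area_mm2,
         count_per_reference = n * reference_area_mm2 / frame_area_mm2)
}

#' Dual-marker colocalization by one-to-one centroid pairing
#'
#' Matches objects across two channels greedily in ascending centroid
#' distance, each object used at most once, rejecting pairs farther apart
#' than `max_pairing_dist_um` (default 5 um, about one soma radius). Ties in
#' distance are broken by lower `(a_id, b_id)` lexicographic order, making
#' the pairing fully deterministic.
#'
#' @param cells_a,cells_b Data frames with columns `id`, `x_um`, `y_um`
#'   (e.g. `tidy()` of a [segment_channel()] result).
#' @param max_pairing_dist_um Maximum centroid distance for a dual call.
#' @return A list of class `colocalization`: counts `n_marker_a`,
#'   `n_marker_b`, `n_dual`, percentages `pct_a_also_b`, `pct_b_also_a`, and
#'   `pairing`, a tibble (`a_id`, `b_id`, `dist_um`).
#' @export
colocalize <- function(cells_a, cells_b, max_pairing_dist_um = 5) {
  check_positive(max_pairing_dist_um, "max_pairing_dist_um", strict = FALSE)
  na <- nrow(cells_a); nb <- nrow(cells_b)
  pairing <- tibble(a_id = integer(), b_id = integer(), dist_um = numeric())
  if (na > 0 && nb > 0) {
    d <- outer(cells_a$x_um, cells_b$x_um, "-")^2 +
      outer(cells_a$y_um, cells_b$y_um, "-")^2
    cand <- which(d <= max_pairing_dist_um^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ai <- cand[, 1]; bi <- cand[, 2]
      dd <- sqrt(d[cand])
      ord <- order(dd, cells_a$id[ai], cells_b$id[bi])
      used_a <- logical(na); used_b <- logical(nb)
      keep_a <- integer(0); keep_b <- integer(0); keep_d <- numeric(0)
      for (k in ord) {
        if (!used_a[ai[k]] && !used_b[bi[k]]) {
          used_a[ai[k]] <- TRUE; used_b[bi[k]] <- TRUE
          keep_a <- c(keep_a, ai[k]); keep_b <- c(keep_b, bi[k])
          keep_d <- c(keep_d, dd[k])
        }
      }
      pairing <- tibble(a_id = cells_a$id[keep_a], b_id = cells_b$id[keep_b],
                        dist_um = keep_d)
    }
  }
  nd <- nrow(pairing)
  structure(list(n_marker_a = na, n_marker_b = nb, n_dual = nd,
                 pct_a_also_b = if (na > 0) 100 * nd / na else NA_real_,
                 pct_b_also_a = if (nb > 0) 100 * nd / nb else NA_real_,
                 pairing = pairing), class = "colocalization")
}

#' @export
print.colocalization <- function(x, ...) {
  cat(sprintf("<colocalization> %d/%d dual: %.1f%% of A, %.1f%% of B\n",
              x$n_dual, min(x$n_marker_a, x$n_marker_b),
              x$pct_a_also_b, x$pct_b_also_a))
  invisible(x)
}

#' @method tidy colocalization
#' @export
tidy.colocalization <- function(x, ...) x$pairing

#' @method glance colocalization
#' @export
glance.colocalization <- function(x, ...) {
  tibble(n_marker_a = x$n_marker_a, n_marker_b = x$n_marker_b,
         n_dual = x$n_dual, pct_a_also_b = x$pct_a_also_b,
         pct_b_also_a = x$pct_b_also_a)
}

#' Count puncta inside and outside a compartment mask
#'
#' A punctum belongs to the compartment when its centroid pixel lies in the
#' mask (mirroring particle removal by location in the clear/clear-outside
#' workflow). Counts are conserved exactly: `n_inside + n_outside` equals
#' the total number of puncta.
#'
#' @param puncta_seg A `segmentation` of the puncta channel, or a data frame
#'   with `x_um`, `y_um` centroids.
#' @param compartment_mask Logical/0-1 matrix in the same frame.
#' @param compartment_area_um2 Area of the compartment; defaults to the mask
#'   pixel count times the pixel area.
#' @param frame_area_um2 Total frame area; defaults to the full mask extent.
#' @param pixel_size_um Needed only when `puncta_seg` is a plain data frame.
#' @return One-row tibble: `n_inside`, `n_outside`, `area_inside_um2`,
#'   `area_outside_um2`, `density_inside`, `density_outside` (puncta/um^2;
#'   `NA` with a warning for a zero-area compartment).
#' @export
count_puncta <- function(puncta_seg, compartment_mask,
                         compartment_area_um2 = NULL, frame_area_um2 = NULL,
                         pixel_size_um = NULL) {
  if (inherits(puncta_seg, "segmentation")) {
    pts <- puncta_seg$objects
    ps <- puncta_seg$pixel_size_um
    if (any(dim(puncta_seg$label_mask) != dim(compartment_mask))) {
      abort("`compartment_mask` does not match the segmentation frame")
    }
  } else {
    pts <- puncta_seg
    ps <- pixel_size_um %||%
      abort("`pixel_size_um` required when `puncta_seg` is a data frame")
  }
  mask <- as.matrix(compartment_mask) != 0
  px_area <- ps^2
  area_in <- compartment_area_um2 %||% (sum(mask) * px_area)
  frame_area <- frame_area_um2 %||% (length(mask) * px_area)
  area_out <- frame_area - area_in
  inside <- if (nrow(pts) > 0) {
    points_in_mask(pts$x_um, pts$y_um, mask, ps)
  } else logical(0)
  n_in <- sum(inside); n_out <- length(inside) - n_in
  dens <- function(n, a) {
    if (a <= 0) {
      if (n > 0) warn("nonzero puncta count in zero-area compartment; density undefined")
      return(NA_real_)
    }
    n / a
  }
  tibble(n_inside = n_in, n_outside = n_out,
         area_inside_um2 = area_in, area_outside_um2 = area_out,
         density_inside = dens(n_in, area_in),
         density_outside = dens(n_out, area_out))
}
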