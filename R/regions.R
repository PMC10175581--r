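#' Partition a striatum polygon into four quadrants
#'
#' Splits the (user-supplied) striatum outline at the midpoints of its
#' bounding extent by a horizontal and a vertical line, yielding the four
#' quadrant polygons used for regional quantification. Quadrants are named
#' by anatomical position: `dm`/`dl` are the dorsal (top of frame, smaller
#' `y_um`) pair and `cm`/`cl` the central pair; which side is medial is
#' declared per image via `medial`, since coronal sections can be mounted
#' either way.
#'
#' @param striatum_polygon Two-column matrix/data frame of vertices
#'   (`x_um`, `y_um`), a simple (non-self-intersecting) ring.
#' @param medial `"left"` or `"right"`: the side of the frame that is
#'   anatomically medial.
#' @return A list of class `region_partition`: `regions` (named list of
#'   vertex matrices for `dm`, `dl`, `cm`, `cl`), `areas` (named areas,
#'   um^2), `striatum_area_um2`, `midpoint` (`c(x, y)`), `medial`.
#' @examples
#' sq <- cbind(c(0, 100, 100, 0), c(0, 0, 80, 80))
#' partition_striatum(sq, medial = "left")$areas
#' @export
partition_striatum <- function(striatum_polygon, medial = c("left", "right")) {
  medial <- match.arg(medial)
  p <- as.matrix(striatum_polygon)[, 1:2, drop = FALSE]
  total <- polygon_area(p)
  if (total <= 0) abort("degenerate striatum polygon (zero area)")
  xm <- (min(p[, 1]) + max(p[, 1])) / 2
  ym <- (min(p[, 2]) + max(p[, 2])) / 2
  big <- max(abs(p)) * 4 + 1
  quad_rect <- list(
    top_left = c(-big, xm, -big, ym),
    top_right = c(xm, big, -big, ym),
    bottom_left = c(-big, xm, ym, big),
    bottom_right = c(xm, big, ym, big)
  )
  name_of <- function(vert, horiz) {
    dorsal <- vert == "top"  # image y grows downwards; dorsal is the top
    med <- horiz == medial
    paste0(if (dorsal) "d" else "c", if (med) "m" else "l")
  }
  names(quad_rect) <- c(name_of("top", "left"), name_of("top", "right"),
                        name_of("bottom", "left"), name_of("bottom", "right"))
  regions <- lapply(quad_rect, function(r) clip_polygon_rect(p, r))
  areas <- vapply(regions, polygon_area, numeric(1))
  structure(list(regions = regions, areas = areas,
                 striatum_area_um2 = total, midpoint = c(x = xm, y = ym),
                 medial = medial),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> quadrant areas (um^2):\n")
  print(round(x$areas, 2))
  invisible(x)
}

#' Assign points to regions of a partition
#'
#' @param partition A [partition_striatum()] result.
#' @param points Data frame with `x_um`, `y_um`.
#' @return Character vector of region names (`NA` outside all regions).
#' @export
assign_region <- function(partition, points) {
  out <- rep(NA_character_, nrow(points))
  for (nm in names(partition$regions)) {
    hit <- points_in_polygon(points$x_um, points$y_um,
                             partition$regions[[nm]])
    out[is.na(out) & hit] <- nm
  }
  out
}

#' Area-normalised fluorescence intensity of a region
#'
#' Integrated density is the sum of pixel values inside the region polygon
#' times the pixel area; dividing by the region area gives a fluorescence
#' intensity that is comparable across regions of different size (two
#' regions over a constant image have identical intensity regardless of
#' area).
#'
#' @param image Numeric matrix (8-bit scale).
#' @param region_polygon Two-column vertex matrix in um.
#' @param pixel_size_um Pixel size, um/px.
#' @param region_name Label carried into the output.
#' @return One-row tibble: `region_name`, `integrated_density` (AU um^2),
#'   `area_um2` (pixelated region area), `intensity` (AU).
#' @export
region_intensity <- function(image, region_polygon, pixel_size_um,
                             region_name = "region") {
  mask <- rasterize_polygon(region_polygon, dim(image), pixel_size_um)
  npx <- sum(mask)
  if (npx == 0) abort("region polygon covers no pixel of the frame")
  px_area <- pixel_size_um^2
  int_dens <- sum(image[mask]) * px_area
  area <- npx * px_area
  tibble(region_name = region_name, integrated_density = int_dens,
         area_um2 = area, intensity = int_dens / area)
}

#' Classify white-matter fascicles by cross-sectional area
#'
#' Size classes: small below 1,000 um^2, large above 5,000 um^2, medium
#' between, with both boundary values (1,000 and 5,000) counted as medium.
#'
#' @param fascicle_seg A [segment_channel()] result for the white-matter
#'   channel, or a data frame with `id` and `area_um2`.
#' @return Tibble of fascicle records (`id`, `area_um2`, `size_class`
#'   factor small/medium/large plus any other input columns), with the
#'   per-class percentages available via [fascicle_class_percentages()].
#' @examples
#' classify_fascicles(data.frame(id = 1:3, area_um2 = c(800, 3000, 6000)))
#' @export
classify_fascicles <- function(fascicle_seg) {
  rec <- if (inherits(fascicle_seg, "segmentation")) fascicle_seg$objects
         else as_tibble(fascicle_seg)
  if (any(rec$area_um2 <= 0)) abort("fascicle areas must be positive")
  rec$size_class <- factor(
    ifelse(rec$area_um2 < 1000, "small",
           ifelse(rec$area_um2 > 5000, "large", "medium")),
    levels = c("small", "medium", "large"))
  rec
}

#' @rdname classify_fascicles
#' @param records Output of [classify_fascicles()].
#' @export
fascicle_class_percentages <- function(records) {
  tab <- table(records$size_class)
  tibble(size_class = factor(names(tab), levels = levels(records$size_class)),
         n = as.integer(tab),
         percent = if (sum(tab) > 0) 100 * as.integer(tab) / sum(tab)
           else rep(0, length(tab)))
}

#' Flag fascicles associated with marker-positive cells
#'
#' A fascicle is marker-positive when at least one cell centroid lies inside
#' the fascicle mask dilated by `halo_um` (default 10 um, the same scale as
#' the cluster criterion); equivalently, within `halo_um` of the nearest
#' fascicle pixel center. Counts are normalised per `reference_area_mm2`
#' frame (default the 0.34 mm^2 confocal frame).
#'
#' @param fascicle_seg A [segment_channel()] result for the fascicle channel.
#' @param cells Data frame with `x_um`, `y_um` centroids of marker-positive
#'   cells.
#' @param halo_um Association halo in um (>= 0).
#' @param frame_area_mm2 Imaged frame area, mm^2; defaults to the mask
#'   extent.
#' @param reference_area_mm2 Normalisation area (default 0.34).
#' @return List with `fascicles` (tibble: fascicle columns +
#'   `marker_positive`) and `summary` (one-row tibble: `n_positive`,
#'   `n_negative`, `positive_per_reference`, `negative_per_reference`).
#' @export
fascicle_marker_association <- function(fascicle_seg, cells, halo_um = 10,
                                        frame_area_mm2 = NULL,
                                        reference_area_mm2 = 0.34) {
  stopifnot(inherits(fascicle_seg, "segmentation"))
  check_positive(halo_um, "halo_um", strict = FALSE)
  ps <- fascicle_seg$pixel_size_um
  lab <- fascicle_seg$label_mask
  rec <- fascicle_seg$objects
  pos <- rep(FALSE, nrow(rec))
  if (nrow(rec) > 0 && nrow(cells) > 0) {
    idx <- which(lab > 0)
    frow <- ((idx - 1) %% nrow(lab)) + 1
    fcol <- ((idx - 1) %/% nrow(lab)) + 1
    fx <- (fcol - 0.5) * ps
    fy <- (frow - 0.5) * ps
    flab <- lab[idx]
    for (i in seq_len(nrow(rec))) {
      sel <- flab == rec$id[i]
      # bounding-box prefilter, then exact pixel-center distances
      cand <- which(cells$x_um >= min(fx[sel]) - halo_um - ps &
                      cells$x_um <= max(fx[sel]) + halo_um + ps &
                      cells$y_um >= min(fy[sel]) - halo_um - ps &
                      cells$y_um <= max(fy[sel]) + halo_um + ps)
      for (j in cand) {
        if (min((fx[sel] - cells$x_um[j])^2 +
                  (fy[sel] - cells$y_um[j])^2) <= halo_um^2) {
          pos[i] <- TRUE
          break
        }
      }
    }
  }
  rec$marker_positive <- pos
  area_mm2 <- frame_area_mm2 %||% (length(lab) * ps^2 / 1e6)
  summ <- tibble(
    n_positive = sum(pos), n_negative = sum(!pos),
    positive_per_reference = sum(pos) * reference_area_mm2 / area_mm2,
    negative_per_reference = sum(!pos) * reference_area_mm2 / area_mm2)
  list(fascicles = rec, summary = summ)
}

#' Puncta load in white matter versus gray matter
#'
#' Delegates to [count_puncta()] with the compartment set to the union of
#' fascicle masks: "inside" is white matter, "outside" is gray matter.
#'
#' @param fascicle_seg A [segment_channel()] result for the fascicle channel.
#' @param puncta_seg A [segment_channel()] result for the puncta channel.
#' @param frame_area_um2 Total frame area; defaults to the mask extent.
#' @return As [count_puncta()].
#' @export
wm_vs_gm_puncta <- function(fascicle_seg, puncta_seg, frame_area_um2 = NULL) {
  stopifnot(inherits(fascicle_seg, "segmentation"))
  count_puncta(puncta_seg, fascicle_seg$label_mask > 0,
               frame_area_um2 = frame_area_um2,
               pixel_size_um = fascicle_seg$pixel_size_um)
}

#' Percent of a region's area covered by a mask
#'
#' @param mask Logical/0-1 matrix.
#' @param region_polygon Optional region polygon (um); the full frame when
#'   `NULL`.
#' @param pixel_size_um Pixel size, um/px.
#' @return Percentage in `[0, 100]`.
#' @export
percent_area <- function(mask, region_polygon = NULL, pixel_size_um = 1) {
  m <- as.matrix(mask) != 0
  if (is.null(region_polygon)) return(100 * sum(m) / length(m))
  rmask <- rasterize_polygon(region_polygon, dim(m), pixel_size_um)
  if (!any(rmask)) abort("region polygon covers no pixel of the frame")
  100 * sum(m & rmask) / sum(rmask)
}
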