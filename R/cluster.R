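#' Detect astrocyte clusters by perimeter-distance dilation
#'
#' Implements the perimeter-distance cluster definition: two astrocytes
#' belong to the same cluster when their mask perimeters approach within
#' twice the dilation radius (default 10 um each side, 20 um total). Every
#' segmented mask is dilated by a Euclidean disc of `dilation_radius_um`
#' (exact distance-transform thresholding, not a square kernel), connected
#' components of the dilated union become candidate clusters, and components
#' containing exactly one object (isolated astrocytes) are removed and
#' logged. No minimum cluster-area filter is applied. Objects touching the
#' frame border participate normally.
#'
#' The radius is specified in physical um and converted to pixels; pass
#' `radius_px` instead to replicate a literal fixed-pixel enlargement.
#'
#' @param seg A [segment_channel()] result for the astrocyte channel.
#' @param dilation_radius_um Dilation radius per astrocyte, um (default 10).
#' @param radius_px Optional literal radius in pixels, overriding
#'   `dilation_radius_um`.
#' @return A list of class `cluster_set`: `clusters`, a tibble
#'   (`cluster_id`, `n_members`, `area_um2` - the merged dilated component
#'   including the margin, and `core_area_um2` - the union of undilated
#'   member masks; both are reported because either convention may be
#'   wanted); `membership` (`object_id`, `cluster_id`); `cluster_mask`
#'   (integer matrix labeling dilated cluster footprints);
#'   `singleton_ids_removed`; `dilation_radius_um`; `pixel_size_um`.
#' @examples
#' img <- matrix(0, 60, 60)
#' img[10:14, 10:14] <- 200; img[10:14, 22:26] <- 200  # 7 px gap
#' seg <- segment_channel(img, 70, min_area_um2 = 1, pixel_size_um = 1)
#' detect_clusters(seg, dilation_radius_um = 10)$clusters
#' @export
detect_clusters <- function(seg, dilation_radius_um = 10, radius_px = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  check_positive(dilation_radius_um, "dilation_radius_um", strict = FALSE)
  ps <- seg$pixel_size_um
  r_um <- if (!is.null(radius_px)) radius_px * ps else dilation_radius_um
  empty <- function() {
    structure(list(
      clusters = tibble(cluster_id = integer(), n_members = integer(),
                        area_um2 = numeric(), core_area_um2 = numeric()),
      membership = tibble(object_id = integer(), cluster_id = integer()),
      cluster_mask = matrix(0L, nrow(seg$label_mask), ncol(seg$label_mask)),
      singleton_ids_removed = seg$objects$id,
      dilation_radius_um = r_um, pixel_size_um = ps),
      class = "cluster_set")
  }
  if (nrow(seg$objects) == 0) {
    warn("empty segmentation; returning empty cluster set")
    return(empty())
  }
  dil <- dilate_mask(seg$label_mask > 0, r_um, ps)
  comp <- label_components(dil, connectivity = 8)
  # Each object's component: look up any of its pixels (objects are subsets
  # of the dilated union, so the lookup is total).
  obj_px <- which(seg$label_mask > 0)
  obj_lab <- seg$label_mask[obj_px]
  comp_lab <- comp[obj_px]
  obj_comp <- vapply(split(comp_lab, obj_lab), function(v) v[1], numeric(1))
  obj_ids <- as.integer(names(obj_comp))
  members_per_comp <- table(obj_comp)
  cluster_comps <- as.integer(names(members_per_comp)[members_per_comp >= 2])
  singleton_ids <- obj_ids[!(obj_comp %in% cluster_comps)]
  if (length(cluster_comps) == 0) return(within_empty(empty(), singleton_ids))

  # Relabel cluster components 1..k in component order.
  new_id <- integer(max(comp))
  new_id[cluster_comps] <- seq_along(cluster_comps)
  cluster_mask <- comp
  cluster_mask[cluster_mask > 0] <-
    new_id[cluster_mask[cluster_mask > 0]]

  membership <- tibble(object_id = obj_ids,
                       cluster_id = ifelse(obj_comp %in% cluster_comps,
                                           new_id[obj_comp], NA_integer_)) |>
    dplyr::filter(!is.na(.data$cluster_id)) |>
    dplyr::arrange(.data$cluster_id, .data$object_id)

  px_area <- ps^2
  dil_area <- tabulate(cluster_mask[cluster_mask > 0],
                       nbins = length(cluster_comps)) * px_area
  core <- membership |>
    dplyr::left_join(seg$objects, by = c(object_id = "id")) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(n_members = dplyr::n(),
                     core_area_um2 = sum(.data$area_um2))
  clusters <- tibble(cluster_id = seq_along(cluster_comps),
                     n_members = core$n_members,
                     area_um2 = dil_area,
                     core_area_um2 = core$core_area_um2)
  structure(list(clusters = clusters, membership = membership,
                 cluster_mask = cluster_mask,
                 singleton_ids_removed = sort(singleton_ids),
                 dilation_radius_um = r_um, pixel_size_um = ps),
            class = "cluster_set")
}

within_empty <- function(cs, singleton_ids) {
  cs$singleton_ids_removed <- sort(singleton_ids)
  cs
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d clusters (radius %g um), %d singletons removed\n",
    nrow(x$clusters), x$dilation_radius_um,
    length(x$singleton_ids_removed)))
  invisible(x)
}

#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_clustered_objects = nrow(x$membership),
         n_singletons_removed = length(x$singleton_ids_removed),
         total_area_um2 = sum(x$clusters$area_um2),
         mean_area_um2 = if (nrow(x$clusters)) mean(x$clusters$area_um2)
           else NA_real_,
         dilation_radius_um = x$dilation_radius_um)
}

#' Exact geometric cluster oracle for disc-shaped objects
#'
#' Brute-force verifier for [detect_clusters()] on synthetic scenes where
#' object shapes are known exactly: builds a graph with an edge whenever the
#' minimum boundary-to-boundary distance between two discs is at most
#' `max_gap_um`, and returns connected components with at least two members
#' (others are singletons). Works in continuous coordinates, free of pixel
#' effects.
#'
#' @param discs Data frame with columns `id`, `x_um`, `y_um`, `r_um`.
#' @param max_gap_um Maximum perimeter gap joining two objects (default 20,
#'   i.e. twice the 10 um dilation radius).
#' @return Tibble (`id`, `cluster_id`); `cluster_id` is `NA` for
#'   singletons. Cluster ids are numbered by smallest member id.
#' @export
cluster_graph_oracle <- function(discs, max_gap_um = 20) {
  n <- nrow(discs)
  if (n == 0) return(tibble(id = integer(), cluster_id = integer()))
  d <- as.matrix(dist(cbind(discs$x_um, discs$y_um)))
  gap <- d - outer(discs$r_um, discs$r_um, "+")
  adj <- which(upper.tri(gap) & gap <= max_gap_um, arr.ind = TRUE)
  roots <- uf_components(n, adj)
  sizes <- table(roots)
  in_cluster <- roots %in% as.integer(names(sizes)[sizes >= 2])
  cid <- match(roots, sort(unique(roots[in_cluster])))
  cid[!in_cluster] <- NA_integer_
  tibble(id = discs$id, cluster_id = cid)
}

#' Puncta density inside versus outside astrocyte clusters
#'
#' Delegates to [count_puncta()] with the compartment set to the union of
#' (dilated) cluster footprints; the outside area is the frame area minus
#' the cluster area.
#'
#' @param cluster_set A [detect_clusters()] result.
#' @param puncta_seg A [segment_channel()] result for the puncta channel (or
#'   data frame of centroids).
#' @param frame_area_um2 Total frame area; defaults to the mask extent.
#' @return As [count_puncta()]: inside = in clusters, outside = rest of the
#'   frame.
#' @export
puncta_by_cluster <- function(cluster_set, puncta_seg,
                              frame_area_um2 = NULL) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  mask <- cluster_set$cluster_mask > 0
  res <- count_puncta(puncta_seg, mask,
                      compartment_area_um2 = sum(cluster_set$clusters$area_um2),
                      frame_area_um2 = frame_area_um2,
                      pixel_size_um = cluster_set$pixel_size_um)
  if (!is.na(res$area_outside_um2) && res$area_outside_um2 <= 0) {
    warn("clusters cover the whole frame; outside density undefined")
  }
  res
}
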