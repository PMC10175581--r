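#' Run the full pipeline on paired synthetic cohorts
#'
#' Simulates a control-like cohort (homogeneous Poisson somata, uniform
#' puncta) and a disease-like cohort (Thomas-clustered somata at 1.5x the
#' control intensity, puncta depleted ten-fold inside cluster territory,
#' white-matter fascicle masks present), then runs every stage per image:
#' segmentation at the fixed astrocyte threshold (70) and puncta threshold
#' (30), per-frame counts, nearest-neighbor and spacing-index statistics,
#' perimeter-distance clustering, in/out-cluster and white-matter/gray-matter
#' puncta densities, and dual-marker colocalization. Image values are
#' averaged to animals and genotypes compared with the two-group scheme.
#'
#' @param seed Integer master seed.
#' @param n_animals Animals per genotype (default 5).
#' @param n_images Images per animal (default 3, averaged per animal).
#' @return A list: `images` (long image-level tibble), `animals`
#'   (animal-level tibble), `comparisons` (named list of [run_comparison()]
#'   results), `group_means` (named list of per-metric named vectors,
#'   `wt`/`zq175`), and `report` (an `analysis_report`).
#' @examples
#' \donttest{
#' demo <- run_demo_cohorts(seed = 1, n_animals = 3, n_images = 2)
#' demo$group_means$mean_nnd
#' }
#' @export
run_demo_cohorts <- function(seed = 1, n_animals = 5, n_images = 3) {
  fasc <- data.frame(cx_um = c(160, 420, 310), cy_um = c(160, 280, 500),
                     a_um = c(45, 60, 25), b_um = c(20, 28, 12),
                     theta = c(0.3, 1.2, 2.0))
  make_spec <- function(genotype, s) {
    if (genotype == "wt") {
      scene_spec(seed = s, astro_process = "poisson",
                 intensity_lambda = 7.5e-5, soma_sigma_um = 1.5,
                 puncta_density_in = 1e-3, puncta_density_out = 1e-3)
    } else {
      scene_spec(seed = s, astro_process = "thomas",
                 intensity_lambda = 2.25e-5, offspring_mean = 5,
                 offspring_sigma_um = 10, soma_sigma_um = 1.5,
                 puncta_density_in = 1e-4, puncta_density_out = 1e-3,
                 fascicle_specs = fasc)
    }
  }

  rows <- list()
  idx <- 0
  for (genotype in c("wt", "zq175")) {
    for (a in seq_len(n_animals)) {
      for (im in seq_len(n_images)) {
        idx <- idx + 1
        spec <- make_spec(genotype, derive_seed(seed, idx +
                                                  1000 * (genotype == "zq175")))
        m <- measure_scene(spec)
        rows[[idx]] <- dplyr::mutate(m,
                                     animal_id = sprintf("%s_%02d", genotype, a),
                                     genotype = genotype, image = im,
                                     .before = 1)
      }
    }
  }
  images <- purrr::list_rbind(rows)
  animals <- aggregate_to_animal(
    dplyr::filter(images, is.finite(.data$value)))

  metrics <- c("cell_count", "mean_nnd", "spacing_index", "cluster_area",
               "puncta_in_density")
  comparisons <- list()
  for (met in metrics) {
    sub <- dplyr::filter(animals, .data$metric_name == met)
    if (length(unique(sub$genotype)) == 2 && nrow(sub) >= 4) {
      comparisons[[met]] <- run_comparison(
        dplyr::rename(sub, group = "genotype"), "two_group_t")
    }
  }

  group_means <- lapply(
    setNames(unique(animals$metric_name), unique(animals$metric_name)),
    function(met) {
      sub <- dplyr::filter(animals, .data$metric_name == met)
      tapply(sub$value, sub$genotype, mean)
    })

  report <- build_report(list(demo = images[c("animal_id", "genotype",
                                              "metric_name", "value")]),
                         comparisons = comparisons)
  list(images = images, animals = animals, comparisons = comparisons,
       group_means = group_means, report = report)
}

# One image through every stage; returns a long tibble (metric_name, value).
measure_scene <- function(spec) {
  sc <- simulate_scene(spec)
  ps <- spec$pixel_size_um
  w <- spec$window_um
  seg <- segment_channel(sc$channels$marker_a, 70, min_area_um2 = 5,
                         pixel_size_um = ps, channel_name = "gfap")
  out <- list(cell_count = count_cells_per_frame(
    seg$objects, frame_area_mm2 = prod(w) / 1e6)$count_per_reference)

  if (nrow(seg$objects) >= 2) {
    st <- spacing_stats(as_point_pattern(seg$objects, window = w))
    out$mean_nnd <- st$mean_nnd_um
    out$spacing_index <- st$spacing_index
  }

  cs <- suppressWarnings(detect_clusters(seg, dilation_radius_um = 10))
  out$cluster_area <- if (nrow(cs$clusters) > 0) {
    mean(cs$clusters$area_um2)
  } else 0

  pseg <- segment_channel(sc$channels$puncta, 30, min_area_um2 = 0.2,
                          pixel_size_um = ps, channel_name = "em48")
  pb <- puncta_by_cluster(cs, pseg)
  out$puncta_in_density <- pb$density_inside
  out$puncta_out_density <- pb$density_outside

  if (!is.null(spec$fascicle_specs)) {
    seg_f <- segment_channel(sc$fascicle_mask * 200, 70, min_area_um2 = 10,
                             pixel_size_um = ps, channel_name = "mbp")
    wm <- wm_vs_gm_puncta(seg_f, pseg)
    out$puncta_wm_density <- wm$density_inside
    out$puncta_gm_density <- wm$density_outside
    out$wm_percent_area <- percent_area(sc$fascicle_mask)
  }

  seg_b <- segment_channel(sc$channels$marker_b, 70, min_area_um2 = 5,
                           pixel_size_um = ps, channel_name = "s100b")
  if (nrow(seg$objects) > 0 && nrow(seg_b$objects) > 0) {
    out$coloc_pct <- colocalize(seg$objects, seg_b$objects,
                                max_pairing_dist_um = 5)$pct_a_also_b
  }
  tibble(metric_name = names(out),
         value = vapply(out, function(v) v %||% NA_real_, numeric(1)))
}
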