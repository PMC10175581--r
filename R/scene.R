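#' Specify a synthetic striatal scene
#'
#' A `scene_spec` collects every generating parameter of a synthetic
#' immunofluorescence frame. The defaults describe the study conditions the
#' package is calibrated on: a 0.4 mm^2 analysis frame (632 x 632 um at
#' 1 um/px), a wild-type-like astrocyte density of about 30 somata per frame
#' (7.5e-5 cells/um^2), a dual-marker fraction of 0.35 (the share of
#' GFAP-positive astrocytes that also express S100B), and a puncta field
#' depleted ten-fold inside exclusion territory (0.001/um^2 outside vs
#' 0.0001/um^2 inside). Clustered scenes use a Thomas process with five
#' offspring per parent dispersed by 10 um, matching the 20 um
#' perimeter-distance scale of the cluster definition.
#'
#' @param window_um `c(width, height)` in um.
#' @param pixel_size_um Pixel size in um/px.
#' @param seed Integer master seed; every random stage derives its own
#'   sub-seed from it.
#' @param astro_process `"poisson"` (CSR, wild-type-like) or `"thomas"`
#'   (clustered, disease-like).
#' @param intensity_lambda Cells/um^2 (Poisson) or parents/um^2 (Thomas).
#' @param offspring_mean,offspring_sigma_um Thomas offspring mean and
#'   Gaussian dispersion (um); ignored for `"poisson"`.
#' @param coloc_fraction Fraction of astrocytes positive on both marker
#'   channels, in `[0, 1]`.
#' @param puncta_density_in,puncta_density_out Puncta/um^2 inside and outside
#'   the exclusion mask.
#' @param fascicle_specs Data frame of ellipses (`cx_um`, `cy_um`, `a_um`,
#'   `b_um`, `theta`) or `NULL`.
#' @param soma_sigma_um,amplitude,background,noise_sd Rendering parameters
#'   passed to [render_channel()]; puncta are rendered with a quarter of the
#'   soma width.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(window_um = c(632, 632),
                       pixel_size_um = 1,
                       seed = 1L,
                       astro_process = c("poisson", "thomas"),
                       intensity_lambda = 7.5e-5,
                       offspring_mean = 5,
                       offspring_sigma_um = 10,
                       coloc_fraction = 0.35,
                       puncta_density_in = 1e-4,
                       puncta_density_out = 1e-3,
                       fascicle_specs = NULL,
                       soma_sigma_um = 3,
                       amplitude = 180,
                       background = 10,
                       noise_sd = 0) {
  astro_process <- match.arg(astro_process)
  check_positive(window_um, "window_um")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(intensity_lambda, "intensity_lambda", strict = FALSE)
  check_positive(puncta_density_in, "puncta_density_in", strict = FALSE)
  check_positive(puncta_density_out, "puncta_density_out", strict = FALSE)
  check_fraction(coloc_fraction, "coloc_fraction")
  spec <- list(window_um = as.numeric(window_um),
               pixel_size_um = pixel_size_um, seed = as.integer(seed),
               astro_process = astro_process,
               intensity_lambda = intensity_lambda,
               offspring_mean = offspring_mean,
               offspring_sigma_um = offspring_sigma_um,
               coloc_fraction = coloc_fraction,
               puncta_density_in = puncta_density_in,
               puncta_density_out = puncta_density_out,
               fascicle_specs = fascicle_specs,
               soma_sigma_um = soma_sigma_um, amplitude = amplitude,
               background = background, noise_sd = noise_sd)
  class(spec) <- "scene_spec"
  spec
}

#' Simulate a complete synthetic scene
#'
#' Draws astrocyte somata from the configured point process, assigns
#' dual-marker status, generates a puncta field depleted inside the union of
#' astrocyte-cluster ground truth (Thomas scenes) or the fascicle mask, and
#' renders one 8-bit channel per marker plus a puncta channel. The same spec
#' (including seed) always produces a bit-identical scene.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene` with elements `spec`, `astro`
#'   (a [point_pattern()] with `dual` and, for Thomas, `parent_id` columns),
#'   `puncta` (a [point_pattern()]), `fascicle_mask` (logical matrix),
#'   `exclusion_mask` (the mask the puncta field was thinned against) and
#'   `channels` (named list of matrices: `marker_a`, `marker_b`, `puncta`).
#' @examples
#' sc <- simulate_scene(scene_spec(seed = 42))
#' nrow(sc$astro)
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$window_um
  ps <- spec$pixel_size_um
  astro <- if (spec$astro_process == "poisson") {
    simulate_poisson_pattern(spec$intensity_lambda, w,
                             seed = derive_seed(spec$seed, 1))
  } else {
    simulate_thomas_pattern(spec$intensity_lambda, spec$offspring_mean,
                            spec$offspring_sigma_um, w,
                            seed = derive_seed(spec$seed, 1))
  }
  n <- nrow(astro)
  dual <- with_seed(derive_seed(spec$seed, 2),
                    runif(n) < spec$coloc_fraction)
  astro$dual <- dual

  fmask <- fascicle_mask(spec$fascicle_specs, w, ps)

  # Puncta exclusion territory: astrocyte soma neighbourhoods (the ground
  # truth of "inside clusters") unioned with fascicles.
  excl <- fmask
  if (n > 0) {
    soma_zone <- point_disc_mask(astro$x_um, astro$y_um,
                                 radius_um = 2 * spec$soma_sigma_um +
                                   spec$offspring_sigma_um *
                                   (spec$astro_process == "thomas"),
                                 window = w, pixel_size_um = ps)
    excl <- excl | soma_zone
  }
  puncta <- generate_puncta_field(spec$puncta_density_in,
                                  spec$puncta_density_out,
                                  excl, w, seed = derive_seed(spec$seed, 3))

  idx_b <- which(astro$dual)
  astro_b <- point_pattern(astro$x_um[idx_b], astro$y_um[idx_b], window = w)
  channels <- list(
    marker_a = render_channel(astro, spec$soma_sigma_um, spec$amplitude,
                              spec$background, spec$noise_sd, ps,
                              seed = derive_seed(spec$seed, 4)),
    marker_b = render_channel(astro_b, spec$soma_sigma_um, spec$amplitude,
                              spec$background, spec$noise_sd, ps,
                              seed = derive_seed(spec$seed, 5)),
    puncta = render_channel(puncta, spec$soma_sigma_um / 4, spec$amplitude,
                            spec$background, spec$noise_sd, ps,
                            seed = derive_seed(spec$seed, 6))
  )
  structure(list(spec = spec, astro = astro, puncta = puncta,
                 fascicle_mask = fmask, exclusion_mask = excl,
                 channels = channels),
            class = "synthetic_scene")
}

# Union of discs of `radius_um` around points, rasterised on the pixel grid.
point_disc_mask <- function(x, y, radius_um, window, pixel_size_um) {
  nx <- round(window[1] / pixel_size_um)
  ny <- round(window[2] / pixel_size_um)
  seed_mask <- matrix(FALSE, ny, nx)
  col <- pmin(pmax(ceiling(x / pixel_size_um), 1L), nx)
  row <- pmin(pmax(ceiling(y / pixel_size_um), 1L), ny)
  seed_mask[cbind(row, col)] <- TRUE
  dilate_mask(seed_mask, radius_um, pixel_size_um)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %s process, %d somata (%d dual), %d puncta, %g x %g um\n",
    x$spec$astro_process, nrow(x$astro), sum(x$astro$dual), nrow(x$puncta),
    x$spec$window_um[1], x$spec$window_um[2]))
  invisible(x)
}

#' Write / read a synthetic scene on disk
#'
#' Channels go to a multi-page TIFF (one page per channel), masks to
#' single-page TIFFs, ground-truth points to CSV (`x_um`, `y_um`, `marker`,
#' `parent_id`) and the generating spec to a JSON sidecar.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(scene$channels, function(m) m / 255),
                  file.path(dir, "channels.tif"), bits.per.sample = 8L)
  tiff::writeTIFF(scene$fascicle_mask * 1, file.path(dir, "fascicle_mask.tif"),
                  bits.per.sample = 8L)
  gt <- dplyr::bind_rows(
    tibble(x_um = scene$astro$x_um, y_um = scene$astro$y_um,
           marker = ifelse(scene$astro$dual, "dual", "a"),
           parent_id = scene$astro$parent_id %||% NA_integer_),
    tibble(x_um = scene$puncta$x_um, y_um = scene$puncta$y_um,
           marker = "punctum", parent_id = NA_integer_)
  )
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  spec <- scene$spec
  spec$fascicle_specs <- if (is.null(spec$fascicle_specs)) NULL else
    as.data.frame(spec$fascicle_specs)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene_spec <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  fs <- js$fascicle_specs
  scene_spec(window_um = js$window_um, pixel_size_um = js$pixel_size_um,
             seed = js$seed, astro_process = js$astro_process,
             intensity_lambda = js$intensity_lambda,
             offspring_mean = js$offspring_mean,
             offspring_sigma_um = js$offspring_sigma_um,
             coloc_fraction = js$coloc_fraction,
             puncta_density_in = js$puncta_density_in,
             puncta_density_out = js$puncta_density_out,
             fascicle_specs = if (is.null(fs) || length(fs) == 0) NULL else
               as_tibble(fs),
             soma_sigma_um = js$soma_sigma_um, amplitude = js$amplitude,
             background = js$background, noise_sd = js$noise_sd)
}
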