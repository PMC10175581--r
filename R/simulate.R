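#' Simulate a homogeneous Poisson (CSR) point pattern
#'
#' Complete spatial randomness is the null model against which astrocyte
#' clustering is judged: the number of somata in the frame is Poisson with
#' mean `lambda * area` and locations are i.i.d. uniform.
#'
#' @param lambda Intensity in cells/um^2 (>= 0).
#' @param window `c(width_um, height_um)`, both > 0.
#' @param seed Integer seed; the same `(lambda, window, seed)` always yields
#'   the identical pattern.
#' @return A [point_pattern()].
#' @examples
#' pp <- simulate_poisson_pattern(1e-4, c(632, 632), seed = 1)
#' nrow(pp)
#' @export
simulate_poisson_pattern <- function(lambda, window, seed) {
  check_positive(lambda, "lambda", strict = FALSE)
  check_positive(window, "window")
  with_seed(seed, {
    n <- rpois(1, lambda * prod(window))
    point_pattern(runif(n, 0, window[1]), runif(n, 0, window[2]),
                  window = window)
  })
}

#' Simulate a Thomas (Neyman-Scott) clustered point pattern
#'
#' Parents are a homogeneous Poisson process of intensity `kappa`; each parent
#' emits a Poisson(`mu`) number of offspring displaced by an isotropic
#' Gaussian with standard deviation `sigma_um`. Only offspring are returned
#' as points; the generating parent of each offspring is kept as ground truth
#' (`parent_id` column) so cluster recovery can be scored exactly. This is
#' the generative stand-in for the aggregated arrangement of GFAP-positive
#' astrocytes in the diseased striatum.
#'
#' @param kappa Parent intensity in parents/um^2 (>= 0).
#' @param mu Expected offspring per parent (>= 0).
#' @param sigma_um Offspring dispersion in um (>= 0); `sigma_um = 0` stacks
#'   every offspring on its parent.
#' @param window `c(width_um, height_um)`.
#' @param seed Integer seed.
#' @param parents Optional 2-column matrix/data frame of parent coordinates in
#'   um, overriding the Poisson parent stage (used to plant parents at
#'   controlled separations).
#' @param toroidal If `TRUE`, offspring are wrapped around the window edges
#'   instead of discarded; useful for edge-free calibration only.
#' @return A [point_pattern()] with a `parent_id` column; parent coordinates
#'   are attached as attribute `parents` (tibble `parent_id`, `x_um`, `y_um`).
#' @examples
#' pp <- simulate_thomas_pattern(2e-5, mu = 5, sigma_um = 10,
#'                               window = c(1000, 1000), seed = 7)
#' table(pp$parent_id)
#' @export
simulate_thomas_pattern <- function(kappa, mu, sigma_um, window, seed,
                                    parents = NULL, toroidal = FALSE) {
  check_positive(kappa, "kappa", strict = FALSE)
  check_positive(mu, "mu", strict = FALSE)
  check_positive(sigma_um, "sigma_um", strict = FALSE)
  check_positive(window, "window")
  with_seed(seed, {
    if (is.null(parents)) {
      n_par <- rpois(1, kappa * prod(window))
      px <- runif(n_par, 0, window[1])
      py <- runif(n_par, 0, window[2])
    } else {
      parents <- as.matrix(parents)
      px <- as.numeric(parents[, 1])
      py <- as.numeric(parents[, 2])
      n_par <- length(px)
    }
    n_off <- if (n_par > 0) rpois(n_par, mu) else integer(0)
    pid <- rep.int(seq_len(n_par), n_off)
    ox <- rep.int(px, n_off) + rnorm(sum(n_off), 0, sigma_um)
    oy <- rep.int(py, n_off) + rnorm(sum(n_off), 0, sigma_um)
    if (toroidal) {
      ox <- ox %% window[1]
      oy <- oy %% window[2]
      keep <- rep.int(TRUE, length(ox))
    } else {
      keep <- ox >= 0 & ox <= window[1] & oy >= 0 & oy <= window[2]
    }
    out <- point_pattern(ox[keep], oy[keep], window = window,
                         parent_id = pid[keep])
    attr(out, "parents") <- tibble(parent_id = seq_len(n_par),
                                   x_um = px, y_um = py)
    out
  })
}

#' Simulate a puncta field with a masked intensity step
#'
#' Generates an inhomogeneous Poisson process whose intensity is
#' `density_in` on the exclusion mask and `density_out` off it, by thinning a
#' homogeneous process at the larger intensity. This emulates protein
#' aggregate (EM48-like) puncta that are depleted inside astrocyte-cluster
#' or white-matter territory.
#'
#' @param density_in,density_out Intensities in puncta/um^2 (>= 0).
#' @param exclusion_mask Logical/0-1 matrix (rows = y, cols = x) covering the
#'   window; its dimensions define the pixel size as `window / dim`.
#' @param window `c(width_um, height_um)`.
#' @param seed Integer seed.
#' @return A [point_pattern()] with a logical `inside` column (ground truth
#'   membership of each punctum in the mask).
#' @export
generate_puncta_field <- function(density_in, density_out, exclusion_mask,
                                  window, seed) {
  check_positive(density_in, "density_in", strict = FALSE)
  check_positive(density_out, "density_out", strict = FALSE)
  check_positive(window, "window")
  mask <- as.matrix(exclusion_mask) != 0
  ps_x <- window[1] / ncol(mask)
  ps_y <- window[2] / nrow(mask)
  if (abs(ps_x - ps_y) > 1e-8) {
    abort("`exclusion_mask` implies anisotropic pixels; mask and window disagree")
  }
  lam_max <- max(density_in, density_out)
  with_seed(seed, {
    n <- rpois(1, lam_max * prod(window))
    x <- runif(n, 0, window[1])
    y <- runif(n, 0, window[2])
    inside <- points_in_mask(x, y, mask, ps_x)
    p_keep <- ifelse(inside, density_in, density_out) / lam_max
    keep <- runif(n) < p_keep
    point_pattern(x[keep], y[keep], window = window, inside = inside[keep])
  })
}

# Look up mask membership of physical coordinates (pixel-center convention:
# pixel (r, c) spans ((c-1)*ps, c*ps] x ((r-1)*ps, r*ps]).
points_in_mask <- function(x, y, mask, pixel_size_um) {
  col <- pmin(pmax(ceiling(x / pixel_size_um), 1L), ncol(mask))
  row <- pmin(pmax(ceiling(y / pixel_size_um), 1L), nrow(mask))
  mask[cbind(row, col)]
}
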