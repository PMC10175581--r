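test_that("Poisson pattern respects intensity, window, and determinism", {
  expect_equal(nrow(simulate_poisson_pattern(0, c(100, 100), seed = 1)), 0)

  p1 <- simulate_poisson_pattern(1e-3, c(500, 500), seed = 11)
  p2 <- simulate_poisson_pattern(1e-3, c(500, 500), seed = 11)
  expect_identical(p1$x_um, p2$x_um)
  expect_identical(p1$y_um, p2$y_um)
  expect_true(all(p1$x_um >= 0 & p1$x_um <= 500))

  expect_error(simulate_poisson_pattern(-1, c(100, 100), 1), "lambda")
  expect_error(simulate_poisson_pattern(1e-3, c(0, 100), 1), "window")

  # Monte-Carlo mean count vs lambda * area (3 SE band)
  counts <- vapply(1:200, function(s)
    nrow(simulate_poisson_pattern(1e-3, c(1000, 1000), seed = s)),
    numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000) / sqrt(200))
})

test_that("Thomas pattern matches its generative expectations", {
  # sigma = 0: offspring coincide with parents
  th0 <- simulate_thomas_pattern(1e-4, 3, 0, c(200, 200), seed = 5)
  par <- attr(th0, "parents")
  expect_true(all(th0$x_um == par$x_um[th0$parent_id]))

  # mu = 0: empty
  expect_equal(nrow(simulate_thomas_pattern(1e-4, 0, 5, c(200, 200), 5)), 0)

  # Monte-Carlo total count vs kappa * area * mu (toroidal: no edge loss)
  counts <- vapply(1:500, function(s)
    nrow(simulate_thomas_pattern(1e-5, 5, 10, c(1000, 1000), seed = s,
                                 toroidal = TRUE)), numeric(1))
  se <- sqrt(10 * (5 + 25)) / sqrt(500)  # var per pattern = kappa*area*(mu+mu^2)
  expect_lt(abs(mean(counts) - 50), 3 * se)

  # planted parents override the Poisson parent stage
  thp <- simulate_thomas_pattern(0, 4, 2, c(300, 300), seed = 9,
                                 parents = cbind(c(100, 200), c(150, 150)))
  expect_setequal(unique(thp$parent_id), c(1L, 2L))
})

test_that("Thomas parent assignment gives spatially disjoint groups when separation >> sigma", {
  parents <- expand.grid(x = c(100, 300, 500), y = c(100, 300, 500))
  for (s in 1:20) {
    th <- simulate_thomas_pattern(0, 6, 5, c(600, 600), seed = s,
                                  parents = parents)
    # every offspring closer to own parent than to any other parent
    own <- sqrt((th$x_um - parents$x[th$parent_id])^2 +
                  (th$y_um - parents$y[th$parent_id])^2)
    other <- vapply(seq_len(nrow(th)), function(i) {
      d <- sqrt((parents$x - th$x_um[i])^2 + (parents$y - th$y_um[i])^2)
      min(d[-th$parent_id[i]])
    }, numeric(1))
    expect_true(all(own < other))
  }
})

test_that("CSR nearest-neighbor distances follow the Poisson survival law", {
  lambda <- 1e-3
  nnds <- unlist(lapply(1:20, function(s) {
    pp <- simulate_poisson_pattern(lambda, c(500, 500), seed = 100 + s)
    nearest_neighbor_distances(pp, edge = "toroidal")
  }))
  ks <- suppressWarnings(
    stats::ks.test(nnds, function(r) 1 - exp(-lambda * pi * r^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering produces calibrated 8-bit blobs", {
  w <- c(100, 100)
  empty <- point_pattern(numeric(0), numeric(0), window = w)
  img0 <- render_channel(empty, 3, 150, background = 12, noise_sd = 0,
                         pixel_size_um = 1, seed = 1)
  expect_true(all(img0 == 12))
  expect_equal(dim(img0), c(100, 100))

  # place the point exactly on a pixel center (px 51 spans 50..51 um)
  one <- point_pattern(50.5, 50.5, window = w)
  img1 <- render_channel(one, 3, 150, background = 10, noise_sd = 0,
                         pixel_size_um = 1, seed = 1)
  peak <- which(img1 == max(img1), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(51, 51))
  expect_equal(max(img1), 160)  # background + amplitude at an isolated peak

  expect_true(all(img1 == round(img1)) && max(img1) <= 255 && min(img1) >= 0)
})

test_that("detection round-trip recovers all rendered somata within 1 px", {
  w <- c(700, 700)
  set.seed(77)
  pts <- separated_points(50, w, spacing = 70)
  pp <- point_pattern(pts$x_um, pts$y_um, window = w)
  img <- render_channel(pp, 3, 180, background = 10, noise_sd = 0,
                        pixel_size_um = 1, seed = 1)
  seg <- segment_channel(img, 70, min_area_um2 = 5, pixel_size_um = 1)
  expect_equal(nrow(seg$objects), 50)
  m <- match_to_truth(seg$objects, pts)
  expect_setequal(m, 1:50)
  err <- sqrt((seg$objects$x_um - pts$x_um[m])^2 +
                (seg$objects$y_um - pts$y_um[m])^2)
  expect_lt(max(err), 1)
})

test_that("puncta field is an intensity-step Poisson process", {
  w <- c(400, 400)
  mask <- matrix(FALSE, 400, 400)
  mask[1:200, ] <- TRUE  # top half

  # density_in = 0: no punctum inside the mask
  pf0 <- generate_puncta_field(0, 1e-3, mask, w, seed = 3)
  expect_false(any(pf0$y_um <= 200))

  # equal densities reduce to CSR: counts calibrate to lambda * area
  counts <- vapply(1:100, function(s)
    nrow(generate_puncta_field(5e-4, 5e-4, mask, w, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 80), 3 * sqrt(80) / sqrt(100))

  # in/out intensity ratio recovered over replicates
  tot_in <- 0; tot_out <- 0
  for (s in 1:100) {
    pf <- generate_puncta_field(1e-4, 1e-3, mask, w, seed = 200 + s)
    tot_in <- tot_in + sum(pf$inside)
    tot_out <- tot_out + sum(!pf$inside)
  }
  ratio <- (tot_in / (100 * 8e4)) / (tot_out / (100 * 8e4))
  se_ratio <- ratio * sqrt(1 / tot_in + 1 / tot_out)
  expect_lt(abs(ratio - 0.1), 3 * se_ratio)
})

test_that("scenes are bit-identical under the same spec and obey their geometry", {
  spec <- scene_spec(seed = 21, astro_process = "thomas",
                     intensity_lambda = 2e-5,
                     fascicle_specs = data.frame(cx_um = 300, cy_um = 300,
                                                 a_um = 60, b_um = 25,
                                                 theta = 0.4))
  s1 <- simulate_scene(spec)
  s2 <- simulate_scene(spec)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$astro$x_um, s2$astro$x_um)
  expect_identical(s1$puncta$y_um, s2$puncta$y_um)

  w <- spec$window_um
  expect_true(all(s1$astro$x_um >= 0 & s1$astro$x_um <= w[1]))
  expect_equal(dim(s1$channels$marker_a),
               round(w / spec$pixel_size_um)[c(2, 1)])
  expect_true(all(vapply(s1$channels, max, numeric(1)) <= 255))
})
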