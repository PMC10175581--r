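# Disc pairs with a known perimeter gap, segmented at 0.5 um/px.
disc_pair_clusters <- function(gap_um, r = 5, ps = 0.5, radius_um = 10) {
  d <- 2 * r + gap_um
  discs <- data.frame(id = 1:2, x_um = c(50, 50 + d), y_um = c(50, 50),
                      r_um = r)
  img <- draw_discs(discs, c(150, 100), ps)
  seg <- segment_channel(img, 70, min_area_um2 = 1, pixel_size_um = ps)
  detect_clusters(seg, dilation_radius_um = radius_um)
}

test_that("the perimeter-distance rule joins and separates disc pairs correctly", {
  near <- disc_pair_clusters(gap_um = 5)   # gap 5 <= 20: one cluster of 2
  expect_equal(nrow(near$clusters), 1)
  expect_equal(near$clusters$n_members, 2)
  expect_length(near$singleton_ids_removed, 0)

  far <- disc_pair_clusters(gap_um = 30)   # gap 30 > 20: two singletons
  expect_equal(nrow(far$clusters), 0)
  expect_length(far$singleton_ids_removed, 2)

  # isolated object: singleton removed, no clusters
  lone <- data.frame(id = 1, x_um = 50, y_um = 50, r_um = 5)
  seg1 <- segment_channel(draw_discs(lone, c(100, 100), 0.5), 70, 1, 0.5)
  cs1 <- detect_clusters(seg1)
  expect_equal(nrow(cs1$clusters), 0)
  expect_equal(cs1$singleton_ids_removed, 1L)

  # empty segmentation warns and returns an empty set
  seg0 <- segment_channel(matrix(0, 50, 50), 70, 1, 1)
  expect_warning(cs0 <- detect_clusters(seg0), "empty")
  expect_equal(nrow(cs0$clusters), 0)
})

test_that("a chain of discs within the gap criterion forms one transitive cluster", {
  discs <- data.frame(id = 1:5, x_um = 30 + 15 * (0:4), y_um = 50, r_um = 5)
  # consecutive gaps 5 um; ends are 60 um apart yet share the cluster
  oracle <- cluster_graph_oracle(discs, max_gap_um = 20)
  expect_equal(unique(oracle$cluster_id), 1L)

  seg <- segment_channel(draw_discs(discs, c(150, 100), 0.5), 70, 1, 0.5)
  cs <- detect_clusters(seg, 10)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$n_members, 5)
})

test_that("oracle reports no clusters when all pairwise gaps exceed the criterion", {
  discs <- data.frame(id = 1:3, x_um = c(30, 100, 170), y_um = 50, r_um = 5)
  oracle <- cluster_graph_oracle(discs, 20)
  expect_true(all(is.na(oracle$cluster_id)))
})

test_that("dilation clustering agrees with the exact geometric oracle on random scenes", {
  n_scenes <- 15
  agree <- 0; excused <- 0
  for (s in 1:n_scenes) {
    set.seed(700 + s)
    discs <- random_disc_scene(10, c(300, 300), min_gap = 1)
    ps <- 0.5
    seg <- segment_channel(draw_discs(discs, c(300, 300), ps), 70, 1, ps)
    expect_equal(nrow(seg$objects), nrow(discs))
    m <- match_to_truth(seg$objects, discs)
    cs <- detect_clusters(seg, 10)
    det <- rep(NA_integer_, nrow(discs))
    det[m[cs$membership$object_id]] <- cs$membership$cluster_id
    orc <- cluster_graph_oracle(discs, 20)
    if (same_partition(det[order(discs$id)], orc$cluster_id)) {
      agree <- agree + 1
    } else {
      # discrepancies are excused only when some gap is within 1 px of 20 um
      d <- as.matrix(dist(cbind(discs$x_um, discs$y_um)))
      gaps <- d - outer(discs$r_um, discs$r_um, "+")
      borderline <- any(abs(gaps[upper.tri(gaps)] - 20) <= ps)
      expect_true(borderline)
      excused <- excused + 1
    }
  }
  expect_gte(agree, n_scenes - 2)
})

test_that("growing the dilation radius never loses clustered objects or area", {
  set.seed(55)
  discs <- random_disc_scene(14, c(300, 300), min_gap = 1)
  seg <- segment_channel(draw_discs(discs, c(300, 300), 0.5), 70, 1, 0.5)
  radii <- c(0, 5, 10, 20)
  res <- lapply(radii, function(r) detect_clusters(seg, r))
  n_in <- vapply(res, function(cs) nrow(cs$membership), numeric(1))
  area <- vapply(res, function(cs) sum(cs$clusters$area_um2), numeric(1))
  expect_true(all(diff(n_in) >= 0))
  expect_true(all(diff(area) >= 0))
  # radius 0: distinct segmented objects never touch, so no clusters
  expect_equal(nrow(res[[1]]$clusters), 0)
})

test_that("literal pixel-radius mode reproduces the um default at matching scales", {
  near_um <- disc_pair_clusters(gap_um = 8)
  discs <- data.frame(id = 1:2, x_um = c(50, 68), y_um = c(50, 50), r_um = 5)
  seg <- segment_channel(draw_discs(discs, c(150, 100), 0.5), 70, 1, 0.5)
  near_px <- detect_clusters(seg, radius_px = 20)  # 20 px * 0.5 um = 10 um
  expect_equal(nrow(near_px$clusters), nrow(near_um$clusters))
  expect_equal(near_px$dilation_radius_um, 10)
})

test_that("puncta partition by cluster respects planted exclusion and conservation", {
  # clusters carved by ground truth: puncta depleted 10x inside cluster zones
  spec <- scene_spec(seed = 61, astro_process = "thomas",
                     intensity_lambda = 4e-5, offspring_sigma_um = 8,
                     puncta_density_in = 1e-4, puncta_density_out = 1e-3)
  sc <- simulate_scene(spec)
  seg <- segment_channel(sc$channels$marker_a, 70, 5, 1)
  cs <- detect_clusters(seg, 10)
  pseg <- segment_channel(sc$channels$puncta, 30, 0.2, 1,
                          channel_name = "puncta")
  res <- puncta_by_cluster(cs, pseg)
  expect_identical(res$n_inside + res$n_outside, nrow(pseg$objects))
  expect_lt(res$density_inside, res$density_outside)

  # no clusters: everything is outside (same 632 x 632 frame as the puncta)
  lone <- data.frame(id = 1, x_um = 150, y_um = 150, r_um = 5)
  seg1 <- segment_channel(draw_discs(lone, c(632, 632), 1), 70, 1, 1)
  cs1 <- suppressWarnings(detect_clusters(seg1))
  r1 <- puncta_by_cluster(cs1, pseg)
  expect_equal(r1$n_inside, 0)
  expect_identical(r1$n_outside, nrow(pseg$objects))

  # uniform puncta: inside and outside densities agree within Poisson error
  spec_u <- scene_spec(seed = 62, astro_process = "thomas",
                       intensity_lambda = 4e-5, offspring_sigma_um = 8,
                       puncta_density_in = 1e-3, puncta_density_out = 1e-3)
  scu <- simulate_scene(spec_u)
  segu <- segment_channel(scu$channels$marker_a, 70, 5, 1)
  csu <- detect_clusters(segu, 10)
  pu <- count_puncta(as.data.frame(scu$puncta), csu$cluster_mask > 0,
                     pixel_size_um = 1)
  se <- pu$density_inside * sqrt(1 / max(pu$n_inside, 1) +
                                   1 / max(pu$n_outside, 1))
  expect_lt(abs(pu$density_inside - pu$density_outside), 4 * se)
})
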