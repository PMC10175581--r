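test_that("image-level values average to one row per animal, region and metric", {
  tbl <- data.frame(animal_id = "m1", genotype = "wt",
                    metric_name = "nnd", value = c(1, 2, 3))
  agg <- aggregate_to_animal(tbl)
  expect_equal(agg$value, 2)
  expect_equal(agg$n_images, 3)

  single <- aggregate_to_animal(data.frame(animal_id = "m2",
                                           metric_name = "x", value = 7))
  expect_equal(single$value, 7)

  # random tables: matches a brute-force group-by mean
  set.seed(14)
  big <- data.frame(
    animal_id = sample(paste0("m", 1:6), 120, TRUE),
    genotype = NA, region = sample(c("dm", "cm", "cl"), 120, TRUE),
    metric_name = sample(c("count", "nnd"), 120, TRUE),
    value = rnorm(120))
  big$genotype <- ifelse(big$animal_id %in% paste0("m", 1:3), "wt", "hd")
  agg2 <- aggregate_to_animal(big)
  brute <- stats::aggregate(value ~ animal_id + genotype + region + metric_name,
                            data = big, FUN = mean)
  j <- merge(agg2, brute,
             by = c("animal_id", "genotype", "region", "metric_name"))
  expect_equal(nrow(j), nrow(agg2))
  expect_equal(j$value.x, j$value.y)

  expect_error(aggregate_to_animal(data.frame(animal_id = 1, metric_name = "a",
                                              value = NA_real_)), "finite")
})

test_that("normality-test dispatch follows the sample-size rule", {
  expect_equal(choose_normality_test(8), "dagostino_pearson")
  expect_equal(choose_normality_test(20), "dagostino_pearson")
  expect_equal(choose_normality_test(5), "shapiro_wilk")
  expect_equal(choose_normality_test(7), "shapiro_wilk")
  expect_error(choose_normality_test(2), "at least 3")
})

test_that("the omnibus normality statistic reproduces reference values", {
  # reference statistics computed with an independent implementation of the
  # same skewness/kurtosis omnibus test
  x1 <- c(7.15235, 12.527457, 8.258677, 9.481654, 9.849313, 8.518231,
          7.264415, 11.297786, 10.722116, 6.094274, 14.694819, 11.936994,
          8.481226, 11.804397, 9.066094, 9.878621, 11.577689, 7.486664,
          11.151715, 12.797958)
  r1 <- dagostino_pearson_test(x1)
  expect_equal(r1$statistic, 0.32658098114494255, tolerance = 1e-10)
  expect_equal(r1$p_value, 0.84934442602671, tolerance = 1e-10)

  x2 <- c(0.040503, 0.219685, 0.993272, 0.7426, 0.37209, 0.809778,
          0.503546, 0.334647, 0.313562, 0.349161, 0.162366, 1.698813,
          2.371805, 3.19287, 1.281325)
  r2 <- dagostino_pearson_test(x2)
  expect_equal(r2$statistic, 8.987128494998561, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.011180721846093292, tolerance = 1e-10)

  expect_error(dagostino_pearson_test(rnorm(5)), "n >= 8")

  nt <- normality_test(x2)
  expect_equal(nt$test, "dagostino_pearson")
  expect_false(nt$normal)
})

test_that("group comparisons detect separation and stay quiet on identical groups", {
  same <- data.frame(group = rep(c("wt", "hd"), each = 6),
                     value = rep(c(1, 2, 3, 4, 5, 6), 2))
  r0 <- run_comparison(same, "two_group_t")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_false(r0$significant)

  set.seed(5)
  sep <- data.frame(group = rep(c("a", "b"), each = 10),
                    value = c(rnorm(10, 0, 1), rnorm(10, 3, 1)))
  r1 <- run_comparison(sep, "two_group_t")
  expect_true(r1$significant)
  expect_equal(nrow(attr(r1, "normality")), 2)
})

test_that("paired comparisons key on animal id and survive row shuffling", {
  set.seed(9)
  base <- rnorm(8, 10, 2)
  tbl <- data.frame(animal_id = rep(paste0("m", 1:8), 2),
                    group = rep(c("inside", "outside"), each = 8),
                    value = c(base, base + rnorm(8, 1.5, 0.3)))
  r <- run_comparison(tbl, "paired_t")
  shuffled <- tbl[sample(nrow(tbl)), ]
  r2 <- run_comparison(shuffled, "paired_t")
  expect_equal(r$statistic, r2$statistic)
  expect_equal(r$p_value, r2$p_value)
  expect_equal(r$df, 7)

  expect_error(run_comparison(tbl[-1, ], "paired_t"), "unbalanced")
})

test_that("ANOVA designs report omnibus and adjusted pairwise contrasts", {
  set.seed(21)
  one <- data.frame(group = rep(c("a", "b", "c"), each = 8),
                    value = c(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 4)))
  r1 <- run_comparison(one, "one_way_anova_tukey")
  expect_equal(r1$contrast[1], "omnibus")
  expect_true(r1$significant[1])
  pair <- r1[r1$test_name == "Tukey HSD", ]
  expect_equal(nrow(pair), 3)
  expect_true(pair$significant[pair$contrast == "c-a"])
  expect_false(pair$significant[pair$contrast == "b-a"])

  two <- expand.grid(animal = 1:6, group = c("wt", "hd"),
                     region = c("dm", "cl"))
  set.seed(22)
  two$value <- rnorm(nrow(two)) + 3 * (two$group == "hd" & two$region == "dm")
  r2 <- run_comparison(two, "two_way_anova_sidak")
  expect_true(all(c("group", "region", "group:region") %in% r2$term))
  sidak <- r2[r2$test_name == "Sidak pairwise", ]
  expect_equal(nrow(sidak), 2)  # one group contrast per region level
  expect_true(sidak$significant[grepl("dm", sidak$contrast)])

  expect_error(run_comparison(data.frame(group = "a", value = 1),
                              "two_group_t"), "2 groups")
})

test_that("significance flags are a pure function of p-value and alpha", {
  set.seed(33)
  tbl <- data.frame(group = rep(c("a", "b"), each = 10),
                    value = c(rnorm(10), rnorm(10, 1)))
  r05 <- run_comparison(tbl, "two_group_t", alpha = 0.05)
  r99 <- run_comparison(tbl, "two_group_t", alpha = 0.999999)
  expect_equal(r05$p_value, r99$p_value)
  expect_equal(r05$significant, r05$p_value <= 0.05)
  expect_true(r99$significant)
})

test_that("reports bind stages into a tidy long table and round-trip via CSV", {
  empty <- build_report(list())
  expect_equal(nrow(empty$table), 0)

  meas <- list(
    counts = data.frame(animal_id = c("m1", "m2"), metric_name = "cells",
                        value = c(12, 15)),
    spacing = data.frame(animal_id = c("m1", "m2"), metric_name = "nnd",
                         value = c(30.5, 22.1)))
  rep <- build_report(meas)
  expect_equal(nrow(rep$table), 4)
  expect_true(grepl("spacing / nnd", rep$summary))

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- utils::read.csv(file.path(dir, "report.csv"))
  expect_equal(nrow(back), nrow(rep$table))
  expect_equal(back$value, rep$table$value)
})
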