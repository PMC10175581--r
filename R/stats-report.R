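#' Aggregate image-level measurements to animal level
#'
#' The unit of analysis is the animal, never the image: per-image values are
#' averaged within each (animal, region, metric) cell before any group
#' comparison, mirroring the averaging of three brain slices per animal.
#'
#' @param table Long-format data frame with columns `animal_id`,
#'   `metric_name`, `value`, plus any of `genotype`, `sex`, `age_months`,
#'   `region` (carried through as grouping keys).
#' @return Tibble with one row per (animal, region, metric): the grouping
#'   keys, `value` (mean over images), and `n_images`.
#' @examples
#' tbl <- data.frame(animal_id = "m1", metric_name = "nnd",
#'                   value = c(1, 2, 3))
#' aggregate_to_animal(tbl)
#' @export
aggregate_to_animal <- function(table) {
  if (!all(c("animal_id", "metric_name", "value") %in% names(table))) {
    abort("`table` needs columns animal_id, metric_name, value")
  }
  if (any(!is.finite(table$value))) abort("non-finite measurement values")
  keys <- intersect(c("animal_id", "genotype", "sex", "age_months",
                      "region", "metric_name"), names(table))
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_images = dplyr::n(), value = mean(.data$value),
                     .groups = "drop")
}

#' Run the group comparison scheme on an animal-level table
#'
#' Dispatches the comparison appropriate to the design, reports the per-group
#' normality check (by the sample-size rule of [choose_normality_test()]),
#' and flags significance at `alpha`. When normality fails the parametric
#' test is still run and the failure is recorded as a caveat rather than
#' silently switching tests.
#'
#' Designs: `two_group_t` (unpaired two-tailed t, equal variances, `value ~
#' group`), `paired_t` (pairs keyed by `animal_id` across the two levels of
#' `group`, e.g. inside/outside clusters in the same animals),
#' `one_way_anova_tukey` (one-way ANOVA with Tukey HSD pairwise contrasts),
#' `two_way_anova_sidak` (two-way ANOVA `value ~ group * region` with
#' Sidak-adjusted pairwise group contrasts within each region level).
#'
#' @param table Animal-level data frame with `value`, `group`, and
#'   (`two_way_anova_sidak`, `paired_t`) `region` / `animal_id` columns.
#' @param design One of `"two_group_t"`, `"paired_t"`,
#'   `"one_way_anova_tukey"`, `"two_way_anova_sidak"`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `comparison_result`: `test_name`, `term`,
#'   `contrast`, `statistic`, `df`, `df2` (ANOVA denominator), `p_value`,
#'   `significant`, with the per-group normality table in attribute
#'   `normality`.
#' @export
run_comparison <- function(table,
                           design = c("two_group_t", "paired_t",
                                      "one_way_anova_tukey",
                                      "two_way_anova_sidak"),
                           alpha = 0.05) {
  design <- match.arg(design)
  if (!all(c("value", "group") %in% names(table))) {
    abort("`table` needs columns value and group")
  }
  tbl <- as_tibble(table)
  tbl$group <- factor(tbl$group)
  groups <- levels(tbl$group)
  if (length(groups) < 2) abort("fewer than 2 groups")

  norm <- tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ tryCatch(normality_test(.x$value),
                                   error = function(e)
                                     tibble(test = NA_character_,
                                            statistic = NA_real_,
                                            p_value = NA_real_,
                                            n = nrow(.x), normal = NA))) |>
    dplyr::ungroup()

  res <- switch(design,
    two_group_t = {
      if (length(groups) != 2) abort("two_group_t needs exactly 2 groups")
      tt <- t.test(value ~ group, data = tbl, var.equal = TRUE)
      tibble(test_name = "unpaired t-test (two-tailed)",
             term = "group",
             contrast = paste(groups, collapse = " vs "),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             df2 = NA_real_, p_value = tt$p.value)
    },
    paired_t = {
      if (length(groups) != 2) abort("paired_t needs exactly 2 groups")
      if (!"animal_id" %in% names(tbl)) abort("paired_t needs animal_id")
      wide <- tidyr::pivot_wider(tbl[c("animal_id", "group", "value")],
                                 names_from = "group",
                                 values_from = "value")
      if (!all(complete.cases(wide))) abort("unbalanced paired design")
      tt <- t.test(wide[[groups[1]]], wide[[groups[2]]], paired = TRUE)
      tibble(test_name = "paired t-test (two-tailed)",
             term = "group",
             contrast = paste(groups, collapse = " vs "),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             df2 = NA_real_, p_value = tt$p.value)
    },
    one_way_anova_tukey = {
      fit <- aov(value ~ group, data = tbl)
      s <- summary(fit)[[1]]
      omni <- tibble(test_name = "one-way ANOVA",
                     term = "group", contrast = "omnibus",
                     statistic = s$`F value`[1], df = s$Df[1],
                     df2 = s$Df[2], p_value = s$`Pr(>F)`[1])
      tk <- TukeyHSD(fit)$group
      pair <- tibble(test_name = "Tukey HSD",
                     term = "group", contrast = rownames(tk),
                     statistic = tk[, "diff"], df = NA_real_,
                     df2 = NA_real_, p_value = tk[, "p adj"])
      dplyr::bind_rows(omni, pair)
    },
    two_way_anova_sidak = {
      if (!"region" %in% names(tbl)) abort("two_way_anova_sidak needs region")
      tbl$region <- factor(tbl$region)
      fit <- aov(value ~ group * region, data = tbl)
      s <- summary(fit)[[1]]
      terms <- trimws(rownames(s))
      omni <- tibble(test_name = "two-way ANOVA",
                     term = terms[-length(terms)], contrast = "omnibus",
                     statistic = s$`F value`[-length(terms)],
                     df = s$Df[-length(terms)],
                     df2 = s$Df[length(terms)],
                     p_value = s$`Pr(>F)`[-length(terms)])
      emm <- emmeans::emmeans(fit, ~ group | region)
      ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                            adjust = "sidak"))
      pair <- tibble(test_name = "Sidak pairwise",
                     term = "group within region",
                     contrast = paste(ct$contrast, "|", ct$region),
                     statistic = ct$t.ratio, df = ct$df,
                     df2 = NA_real_, p_value = ct$p.value)
      dplyr::bind_rows(omni, pair)
    })

  res$significant <- !is.na(res$p_value) & res$p_value <= alpha
  attr(res, "normality") <- norm
  attr(res, "alpha") <- alpha
  class(res) <- c("comparison_result", class(res))
  res
}

#' @method glance comparison_result
#' @export
glance.comparison_result <- function(x, ...) {
  norm <- attr(x, "normality")
  tibble(n_tests = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         all_groups_normal = all(norm$normal %in% TRUE))
}

#' Assemble a tidy long-format report across pipeline stages
#'
#' Binds named measurement tables into one long table and renders a short
#' human-readable summary of the headline quantities (counts, NND, spacing
#' index, cluster areas, puncta densities, fascicle classes).
#'
#' @param measurements Named list of data frames, each with at least
#'   `metric_name` and `value` (extra key columns such as `animal_id`,
#'   `genotype`, `region` are kept); names become the `stage` column.
#' @param comparisons Optional named list of [run_comparison()] results.
#' @return A list of class `analysis_report`: `table` (long tibble),
#'   `comparisons`, `summary` (character, markdown-ish).
#' @export
build_report <- function(measurements, comparisons = NULL) {
  stopifnot(is.list(measurements))
  tab <- purrr::imap(measurements, function(df, nm) {
    df <- as_tibble(df)
    if (!all(c("metric_name", "value") %in% names(df))) {
      abort(sprintf("measurement table '%s' needs metric_name and value", nm))
    }
    dplyr::mutate(df, stage = nm, .before = 1)
  }) |> purrr::list_rbind()
  lines <- c("# Analysis report", "")
  if (nrow(tab) > 0) {
    summ <- tab |>
      dplyr::group_by(.data$stage, .data$metric_name) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                       sd = sd(.data$value), .groups = "drop")
    lines <- c(lines, sprintf("- %s / %s: mean %.4g (sd %.3g, n %d)",
                              summ$stage, summ$metric_name, summ$mean,
                              ifelse(is.na(summ$sd), 0, summ$sd), summ$n))
  }
  for (nm in names(comparisons)) {
    cr <- comparisons[[nm]]
    sig <- cr[cr$significant, ]
    lines <- c(lines, "",
               sprintf("## %s (%s)", nm, cr$test_name[1]),
               if (nrow(sig)) sprintf("- %s: p = %.4g *", sig$contrast,
                                      sig$p_value)
               else "- no significant contrasts")
  }
  structure(list(table = tab, comparisons = comparisons,
                 summary = paste(lines, collapse = "\n")),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(x$summary, "\n")
  invisible(x)
}

#' @rdname build_report
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly; writes `report.csv` and `summary.md`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$table, file.path(dir, "report.csv"), row.names = FALSE)
  writeLines(report$summary, file.path(dir, "summary.md"))
  invisible(dir)
}
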