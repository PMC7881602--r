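#' Run the full GRS association study
#'
#' Orchestrates scoring and the complete statistical battery on one cohort:
#' per-subject GRS with risk categories; a baseline-characteristics table of
#' univariable associations (t-test means and per-unit logistic OR for age,
#' BMI and GRS; 2x2 cross-product OR for male sex and family history) plus
#' a multivariable logistic model `outcome ~ age + male + family_history +
#' bmi + grs` with GRS entered continuously; detection rates by GRS
#' category with a Cochran-Armitage trend test; Kaplan-Meier
#' diagnosis-free curves by category with a log-rank comparison and a
#' mean-age-at-colonoscopy check; and the polyp-subtype association table.
#'
#' @param panel Validated SNP panel tibble.
#' @param genotypes Genotype dosage tibble.
#' @param phenotypes Phenotype tibble.
#' @param low_cut,high_cut GRS category boundaries (defaults 0.5, 1.5).
#' @return An object of class `grs_study` with elements `scores`,
#'   `table1`, `multivariable` (a `polygrs_fit`), `grs_means`
#'   (`polygrs_ttest`), `trend` (`polygrs_trend`), `km` (`polygrs_km`),
#'   `logrank`, `age_by_group` (`polygrs_anova`), `table2`, `n`.
#' @export
run_study <- function(panel, genotypes, phenotypes,
                      low_cut = 0.5, high_cut = 1.5) {
  panel <- validate_panel(panel)
  scores <- compute_grs(genotypes, panel, low_cut, high_cut)
  df <- dplyr::inner_join(scores, phenotypes, by = "subject_id")
  if (nrow(df) == 0) stop("no subjects shared between scores and phenotypes",
                          call. = FALSE)
  df$positive <- as.integer(df$outcome == "positive")
  df$male <- as.integer(df$sex == "male")
  df$fh <- as.integer(df$family_history == "positive")

  # univariable association rows
  uni_cont <- function(var) {
    fit <- fit_logistic(df, "positive", var)
    est <- generics::tidy(fit)
    est[est$term == var, ]
  }
  two_by_two <- function(flag) {
    odds_ratio_2x2(
      a = sum(df[[flag]] == 1 & df$positive == 1),
      b = sum(df[[flag]] == 0 & df$positive == 1),
      c = sum(df[[flag]] == 1 & df$positive == 0),
      d = sum(df[[flag]] == 0 & df$positive == 0)
    )
  }
  df$age <- df$age_at_colonoscopy
  df$grs_score <- df$grs
  rows <- list()
  for (v in c("age", "bmi", "grs_score")) {
    est <- uni_cont(v)
    rows[[v]] <- tibble::tibble(
      variable = sub("_score$", "", v), type = "continuous",
      odds.ratio = est$odds.ratio, conf.low = est$conf.low,
      conf.high = est$conf.high, p.value = est$p.value
    )
  }
  for (v in c("male", "fh")) {
    est <- two_by_two(v)
    rows[[v]] <- tibble::tibble(
      variable = ifelse(v == "fh", "family_history", v),
      type = "binary",
      odds.ratio = est$estimate, conf.low = est$conf.low,
      conf.high = est$conf.high, p.value = est$p.value
    )
  }
  table1 <- dplyr::bind_rows(rows)

  mv_terms <- c("age", "male", "fh", "grs_score")
  if (!all(is.na(df$bmi))) mv_terms <- c("age", "male", "fh", "bmi",
                                         "grs_score")
  multi <- fit_logistic(df, "positive", mv_terms)

  grs_means <- compare_group_means(df, "grs", "outcome")

  by_cat <- df |>
    dplyr::summarise(positives = sum(.data$positive), total = dplyr::n(),
                     .by = "category") |>
    dplyr::arrange(.data$category)
  trend <- trend_across_categories(by_cat$positives, by_cat$total,
                                   as.character(by_cat$category))

  rec <- survival_records(scores, phenotypes)
  km <- km_curves(rec)
  lr <- logrank_test(rec)
  age_grp <- mean_age_by_group(rec)

  table2 <- subgroup_associations(scores, phenotypes)

  structure(list(
    scores = scores, table1 = table1, multivariable = multi,
    grs_means = grs_means, trend = trend, km = km, logrank = lr,
    age_by_group = age_grp, table2 = table2, n = nrow(df),
    cutpoints = c(low = low_cut, high = high_cut)
  ), class = "grs_study")
}

#' @export
print.grs_study <- function(x, ...) {
  overall <- detection_rate(sum(x$trend$table$positives),
                            sum(x$trend$table$total))
  cat("GRS association study —", x$n, "subjects\n")
  cat("Overall adenoma detection rate:", overall$percent, "\n\n")
  cat("Detection rate by GRS category:\n")
  print(x$trend)
  cat("\nMultivariable model:\n")
  print(generics::tidy(x$multivariable))
  cat(sprintf("\nLog-rank across GRS groups: chi-square = %.2f (df = %d), p = %.4g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p.value))
  invisible(x)
}

#' Tidy a study into the baseline association table
#'
#' @param x A `grs_study` object.
#' @param ... Unused.
#' @return Tibble of univariable and multivariable odds ratios per variable.
#' @export
tidy.grs_study <- function(x, ...) {
  mv <- generics::tidy(x$multivariable)
  mv$variable <- dplyr::recode(mv$term, grs_score = "grs",
                               fh = "family_history")
  dplyr::left_join(
    x$table1,
    dplyr::select(mv, "variable", mv.odds.ratio = "odds.ratio",
                  mv.conf.low = "conf.low", mv.conf.high = "conf.high",
                  mv.p.value = "p.value"),
    by = "variable"
  )
}

#' One-row study summary
#'
#' @param x A `grs_study` object.
#' @param ... Unused.
#' @return Tibble: `n`, `detection.rate`, `mean.grs.positive`,
#'   `mean.grs.negative`, `grs.or.adjusted`, `p.trend`, `logrank.p`.
#' @export
glance.grs_study <- function(x, ...) {
  mv <- generics::tidy(x$multivariable)
  g <- x$grs_means$groups
  tibble::tibble(
    n = x$n,
    detection.rate = sum(x$trend$table$positives) /
      sum(x$trend$table$total),
    mean.grs.positive = g$mean[g$group == "positive"],
    mean.grs.negative = g$mean[g$group == "negative"],
    grs.or.adjusted = mv$odds.ratio[mv$term == "grs_score"],
    p.trend = x$trend$p.value,
    logrank.p = x$logrank$p.value
  )
}

#' Write a study report bundle to disk
#'
#' Emits machine-readable TSV/JSON artifacts plus a markdown summary at the
#' display precision used in clinical tables (ORs to 2 decimals, rates to
#' 1 decimal percent; full precision is retained in the TSV/JSON files),
#' and detection-rate / Kaplan-Meier figures.
#'
#' @param study A `grs_study` object.
#' @param out_dir Output directory (created if needed).
#' @param figures Write PNG figures (default `TRUE`).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(study, out_dir, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$scores, file.path(out_dir, "scores.tsv"))
  readr::write_tsv(generics::tidy(study), file.path(out_dir, "table1.tsv"))
  readr::write_tsv(study$trend$table, file.path(out_dir, "trend.tsv"))
  readr::write_tsv(study$table2, file.path(out_dir, "table2.tsv"))
  readr::write_tsv(generics::tidy(study$km),
                   file.path(out_dir, "km_curves.tsv"))
  jsonlite::write_json(
    list(summary = as.list(generics::glance(study)),
         trend = as.list(generics::glance(study$trend)),
         logrank = as.list(study$logrank),
         age_by_group = generics::tidy(study$age_by_group)),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  overall <- detection_rate(sum(study$trend$table$positives),
                            sum(study$trend$table$total))
  t1 <- generics::tidy(study)
  fmt_or <- function(or, lo, hi) {
    ifelse(is.na(or), "—",
           sprintf("%.2f (%.2f–%.2f)", or, lo, hi))
  }
  lines <- c(
    "# GRS association study report", "",
    sprintf("Subjects analysed: %d", study$n),
    sprintf("Overall adenoma detection rate: %s (%d/%d)",
            overall$percent, overall$positives, overall$total), "",
    "## Association with screening colonoscopy outcome", "",
    "| Variable | Univariable OR (95% CI) | p | Multivariable OR (95% CI) | p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %.3g | %s | %.3g |",
            t1$variable,
            fmt_or(t1$odds.ratio, t1$conf.low, t1$conf.high), t1$p.value,
            fmt_or(t1$mv.odds.ratio, t1$mv.conf.low, t1$mv.conf.high),
            t1$mv.p.value),
    "",
    "## Detection rate by GRS category", "",
    "| Category | Positives | Total | Rate |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %d | %.1f%% |",
            study$trend$table$category, study$trend$table$positives,
            study$trend$table$total, 100 * study$trend$table$rate),
    "",
    sprintf("Cochran–Armitage p-trend = %.3g", study$trend$p.value),
    sprintf("Log-rank across GRS groups: p = %.3g", study$logrank$p.value),
    sprintf("Mean age at colonoscopy by group: %s (ANOVA p = %.2f)",
            paste(sprintf("%s %.1f", study$age_by_group$groups$group,
                          study$age_by_group$groups$mean.age),
                  collapse = ", "),
            study$age_by_group$p.value)
  )
  writeLines(lines, file.path(out_dir, "report.md"))

  if (figures) {
    ggplot2::ggsave(file.path(out_dir, "detection_rates.png"),
                    plot_detection_rates(study$trend),
                    width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "km_curves.png"),
                    ggplot2::autoplot(study$km),
                    width = 6, height = 4, dpi = 150)
  }
  invisible(out_dir)
}
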