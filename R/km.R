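#' Kaplan-Meier adenoma-diagnosis-free curves by GRS group
#'
#' Product-limit estimate of the probability of remaining free of an
#' adenomatous polyp diagnosis as a function of age, per GRS risk group.
#' Time zero is birth; subjects with a positive colonoscopy have an event at
#' their age at first screening colonoscopy, event-free subjects are
#' right-censored at that age. Ties are handled by counting events before
#' censorings at equal times, the standard product-limit convention.
#'
#' @param data Data frame with columns `time` (age in years, > 0), `event`
#'   (logical or 0/1) and `group` (GRS category or any grouping label).
#'   Empty groups are dropped with a warning.
#' @return An object of class `polygrs_km` wrapping the
#'   [survival::survfit()] fit; `tidy()` returns the per-group step table,
#'   `autoplot()` draws the curves.
#' @export
km_curves <- function(data) {
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  if (any(data$time <= 0)) stop("`time` must be positive", call. = FALSE)
  data$event <- as.integer(as.logical(data$event))
  if (sum(data$event) == 0) {
    warning("no events in data; all curves are flat at 1", call. = FALSE)
  }
  data$group <- factor(data$group)
  empty <- setdiff(levels(data$group), as.character(unique(data$group)))
  if (length(empty) > 0) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  data$group <- droplevels(data$group)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group,
    data = data, conf.type = "log"
  )
  structure(list(fit = fit, data = tibble::as_tibble(data)),
            class = "polygrs_km")
}

#' @export
print.polygrs_km <- function(x, ...) {
  print(x$fit, ...)
  invisible(x)
}

#' Tidy a Kaplan-Meier fit into a step table
#'
#' @param x A `polygrs_km` object.
#' @param ... Unused.
#' @return Tibble with one row per event/censoring time per group: `group`,
#'   `time` (age, years), `n.risk`, `n.event`, `n.censor`, `survival`
#'   (diagnosis-free probability), `conf.low`, `conf.high`.
#' @export
tidy.polygrs_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) {
    factor(rep(levels(x$data$group)[1], length(s$time)))
  } else {
    factor(sub("^group=", "", as.character(s$strata)))
  }
  tibble::tibble(
    group = grp,
    time = s$time,
    n.risk = s$n.risk,
    n.event = s$n.event,
    n.censor = s$n.censor,
    survival = s$surv,
    conf.low = s$lower,
    conf.high = s$upper
  )
}

#' K-sample log-rank test over GRS groups
#'
#' Standard (unweighted) log-rank comparison of event-time distributions
#' across k groups, chi-square distributed with k - 1 degrees of freedom
#' under the null. Fleming-Harrington G-rho weighting is available through
#' `rho` (`rho = 0` is the unweighted test, `rho = 1` the Peto-Peto
#' modification).
#'
#' @param data Data frame with `time`, `event`, `group` columns (as in
#'   [km_curves()]).
#' @param rho Fleming-Harrington weight exponent (default 0, unweighted).
#' @return One-row tibble: `statistic`, `df`, `p.value`, plus a
#'   `per_group` attribute with observed and expected events.
#' @export
logrank_test <- function(data, rho = 0) {
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  data$event <- as.integer(as.logical(data$event))
  data$group <- droplevels(factor(data$group))
  if (nlevels(data$group) < 2) {
    stop("log-rank test requires >= 2 non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data, rho = rho)
  out <- tibble::tibble(
    statistic = sd$chisq,
    df = length(sd$n) - 1L,
    p.value = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE)
  )
  attr(out, "per_group") <- tibble::tibble(
    group = sub("^group=", "", names(sd$n)),
    n = as.integer(sd$n),
    observed = sd$obs,
    expected = sd$exp
  )
  out
}

#' Mean age at colonoscopy by GRS group
#'
#' Per-group mean age with a one-way ANOVA F-test for any difference in
#' means, used to check that differences in diagnosis-free curves are not
#' driven by a shifted age at first colonoscopy.
#'
#' @param data Data frame with `time` (age at colonoscopy) and `group`
#'   columns.
#' @return An object of class `polygrs_anova` with `groups` (tibble: group,
#'   n, mean.age) and `p.value` (`NA` with a message when the ages carry no
#'   variance).
#' @export
mean_age_by_group <- function(data) {
  stopifnot(all(c("time", "group") %in% names(data)))
  df <- data[!is.na(data$time) & !is.na(data$group), ]
  df$group <- droplevels(factor(df$group))
  if (nlevels(df$group) < 1 || nrow(df) == 0) {
    stop("no records", call. = FALSE)
  }
  groups <- df |>
    dplyr::summarise(n = dplyr::n(), mean.age = mean(.data$time),
                     .by = "group") |>
    dplyr::arrange(.data$group)
  p <- NA_real_
  if (nlevels(df$group) >= 2) {
    if (stats::sd(df$time) == 0) {
      message("zero variance in age; ANOVA p undefined")
    } else {
      p <- summary(stats::aov(time ~ group, data = df))[[1]][
        "group", "Pr(>F)"]
    }
  }
  structure(list(groups = groups, p.value = p), class = "polygrs_anova")
}

#' @export
print.polygrs_anova <- function(x, ...) {
  print(x$groups, ...)
  cat(sprintf("One-way ANOVA p = %.4g\n", x$p.value))
  invisible(x)
}

#' @export
tidy.polygrs_anova <- function(x, ...) x$groups

#' @export
glance.polygrs_anova <- function(x, ...) {
  tibble::tibble(p.value = x$p.value)
}

#' Build survival records from scores and phenotypes
#'
#' Joins per-subject GRS categories to phenotypes and lays out the
#' time-to-event frame for [km_curves()] and [logrank_test()]: `time` is age
#' at first screening colonoscopy, `event` marks a positive colonoscopy,
#' `group` is the GRS risk category.
#'
#' @param scores Score tibble from [compute_grs()].
#' @param phenotypes Phenotype tibble.
#' @return Tibble with `subject_id`, `time`, `event`, `group`.
#' @export
survival_records <- function(scores, phenotypes) {
  df <- dplyr::inner_join(scores, phenotypes, by = "subject_id")
  tibble::tibble(
    subject_id = df$subject_id,
    time = df$age_at_colonoscopy,
    event = df$outcome == "positive",
    group = df$category
  )
}
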