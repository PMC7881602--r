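#' Odds ratio for a 2x2 table
#'
#' Cross-product odds ratio with a Woolf (log-scale Wald) 95% confidence
#' interval and a Wald z p-value:
#' \deqn{OR = \frac{ad}{bc}, \quad
#'   CI = \exp\left(\ln OR \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d}\right)}
#' The table is laid out as exposed/unexposed by positive/negative:
#' `a` exposed-positive, `b` unexposed-positive, `c` exposed-negative,
#' `d` unexposed-negative.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param correction Apply the Haldane-Anscombe 0.5 continuity correction
#'   when any cell is zero (default `FALSE`: a zero cell is an error).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `corrected`.
#' @examples
#' odds_ratio_2x2(247, 273, 411, 838) # male gender vs adenoma, OR ~ 1.84
#' @export
odds_ratio_2x2 <- function(a, b, c, d, correction = FALSE,
                           conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      stop("zero cell in 2x2 table; odds ratio undefined ",
           "(set correction = TRUE for Haldane-Anscombe 0.5)", call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells["a"]) + log(cells["d"]) -
    log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    estimate = exp(unname(log_or)),
    conf.low = exp(unname(log_or) - z * se),
    conf.high = exp(unname(log_or) + z * se),
    p.value = 2 * stats::pnorm(-abs(unname(log_or)) / se),
    corrected = corrected
  )
}

#' Adenoma detection rate
#'
#' Exact proportion of screened subjects with a positive finding, with the
#' percent string at the one-decimal display precision used in reports.
#'
#' @param positives Number of positive subjects.
#' @param total Number screened (> 0).
#' @return One-row tibble: `positives`, `total`, `rate`, `percent`.
#' @examples
#' detection_rate(520, 1769) # 29.4%
#' @export
detection_rate <- function(positives, total) {
  if (length(total) != length(positives)) {
    stop("`positives` and `total` must have equal length", call. = FALSE)
  }
  if (any(total <= 0)) stop("`total` must be positive", call. = FALSE)
  if (any(positives < 0 | positives > total)) {
    stop("need 0 <= positives <= total", call. = FALSE)
  }
  rate <- positives / total
  tibble::tibble(
    positives = positives, total = total, rate = rate,
    percent = sprintf("%.1f%%", 100 * rate)
  )
}

#' Fit a logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' outcome on the given model terms, with an intercept always included.
#' Wald 95% confidence intervals and p-values are reported on the odds-ratio
#' scale. Perfect or quasi-separation is detected from fitted probabilities
#' pinned at 0/1 and reported as an error naming the largest coefficient's
#' term.
#'
#' @param data Data frame holding the outcome and term columns.
#' @param outcome Name of the binary outcome column (logical, 0/1, or a
#'   factor whose *first* level is taken as negative).
#' @param terms Character vector of covariate column names.
#' @return An object of class `polygrs_fit`; see [tidy.polygrs_fit()] and
#'   [glance.polygrs_fit()].
#' @export
fit_logistic <- function(data, outcome, terms) {
  stopifnot(outcome %in% names(data), all(terms %in% names(data)))
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.character(y)) stop("outcome must be logical, 0/1 or factor",
                            call. = FALSE)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  df <- data[, terms, drop = FALSE]
  df$.outcome <- y
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= 10 * (length(terms) + 1)) {
    warning("fewer than 10 observations per model term; estimates may be ",
            "unstable", call. = FALSE)
  }
  form <- stats::reformulate(terms, response = ".outcome")
  fit <- stats::glm(form, data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    worst <- names(which.max(abs(stats::coef(fit))[-1]))
    stop("logistic fit did not converge cleanly (possible separation); ",
         "largest coefficient: ", worst, call. = FALSE)
  }
  structure(list(fit = fit, outcome = outcome, terms = terms,
                 n_obs = nrow(df)),
            class = "polygrs_fit")
}

#' @export
print.polygrs_fit <- function(x, ...) {
  cat("Logistic model:", x$outcome, "~",
      paste(x$terms, collapse = " + "), "\n")
  cat("n =", x$n_obs, "\n\n")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `polygrs_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`
#'   (log-odds), `std.error`, `odds.ratio`, `conf.low`, `conf.high` (Wald
#'   95% CI on the OR scale), `p.value`.
#' @export
tidy.polygrs_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  z <- stats::qnorm(0.975)
  beta <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  tibble::tibble(
    term = rownames(sm),
    estimate = beta,
    std.error = se,
    odds.ratio = exp(beta),
    conf.low = exp(beta - z * se),
    conf.high = exp(beta + z * se),
    p.value = unname(sm[, "Pr(>|z|)"])
  )
}

#' One-row model summary for a logistic fit
#'
#' @param x A `polygrs_fit` object.
#' @param ... Unused.
#' @return Tibble: `n_obs`, `converged`, `deviance`, `null.deviance`, `AIC`.
#' @export
glance.polygrs_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    converged = x$fit$converged,
    deviance = x$fit$deviance,
    null.deviance = x$fit$null.deviance,
    AIC = stats::AIC(x$fit)
  )
}

#' Cochran-Armitage trend test across ordered categories
#'
#' Tests for a linear trend in the proportion of positives across ordered
#' groups (low, average, elevated GRS), using equally spaced integer scores
#' 0, 1, 2, ... via [stats::prop.trend.test()]. Per-category detection rates
#' are reported alongside the chi-square statistic and two-sided p-value.
#'
#' @param positives Integer vector of positive counts per category, ordered
#'   low to high.
#' @param totals Integer vector of totals per category (> 0).
#' @param categories Category labels (default `low`, `average`, `elevated`
#'   when length 3, else `cat1..k`).
#' @return An object of class `polygrs_trend` with elements `table` (rates
#'   per category), `statistic`, `df`, `p.value`.
#' @examples
#' trend_across_categories(c(10, 100, 40), c(120, 500, 110))
#' @export
trend_across_categories <- function(positives, totals, categories = NULL) {
  k <- length(positives)
  if (k < 2) stop("trend requires at least 2 ordered categories",
                  call. = FALSE)
  if (length(totals) != k) stop("`positives` and `totals` lengths differ",
                                call. = FALSE)
  if (any(totals <= 0)) stop("all totals must be positive", call. = FALSE)
  if (any(positives < 0 | positives > totals)) {
    stop("need 0 <= positives <= totals", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- if (k == 3) c("low", "average", "elevated")
                  else paste0("cat", seq_len(k))
  }
  # prop.trend.test warns through its internal lm() on near-perfect trends;
  # only its chi-square statistic is used, so silence that machinery
  tt <- suppressWarnings(
    stats::prop.trend.test(positives, totals, score = seq_len(k) - 1)
  )
  structure(list(
    table = tibble::tibble(
      category = factor(categories, levels = categories, ordered = TRUE),
      positives = as.integer(positives),
      total = as.integer(totals),
      rate = positives / totals
    ),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value
  ), class = "polygrs_trend")
}

#' @export
print.polygrs_trend <- function(x, ...) {
  print(x$table, ...)
  cat(sprintf("Cochran-Armitage chi-square = %.3f (df = %d), p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
tidy.polygrs_trend <- function(x, ...) x$table

#' @export
glance.polygrs_trend <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' Compare mean GRS between outcome groups
#'
#' Per-group mean with a normal-theory 95% confidence interval
#' (mean +/- 1.96 SE), and a Welch two-sample t-test when exactly two groups
#' are present.
#'
#' @param data Data frame with the value and group columns.
#' @param value Name of the numeric column (e.g. `"grs"`).
#' @param group Name of the grouping column (e.g. `"outcome"`).
#' @return An object of class `polygrs_ttest` with elements `groups`
#'   (tibble: group, n, mean, conf.low, conf.high), `p.value` and
#'   `mean.difference` (first minus second group; `NA` unless two groups).
#' @export
compare_group_means <- function(data, value, group) {
  stopifnot(value %in% names(data), group %in% names(data))
  df <- data[!is.na(data[[value]]) & !is.na(data[[group]]), ]
  g <- droplevels(factor(df[[group]]))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("need >= 2 observations per group",
                              call. = FALSE)
  z <- stats::qnorm(0.975)
  groups <- df |>
    dplyr::mutate(.g = g, .v = .data[[value]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.v),
      se = stats::sd(.data$.v) / sqrt(dplyr::n()),
      .by = ".g"
    ) |>
    dplyr::transmute(group = .data$.g, n = .data$n, mean = .data$mean,
                     conf.low = .data$mean - z * .data$se,
                     conf.high = .data$mean + z * .data$se)
  p <- NA_real_; diff <- NA_real_
  if (nlevels(g) == 2) {
    v1 <- df[[value]][g == levels(g)[1]]
    v2 <- df[[value]][g == levels(g)[2]]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      stop("zero variance in both groups; t-test degenerate", call. = FALSE)
    }
    tt <- stats::t.test(v1, v2)
    p <- tt$p.value
    diff <- mean(v1) - mean(v2)
  }
  structure(list(groups = groups, p.value = p, mean.difference = diff),
            class = "polygrs_ttest")
}

#' @export
print.polygrs_ttest <- function(x, ...) {
  print(x$groups, ...)
  if (!is.na(x$p.value)) {
    cat(sprintf("Welch t-test p = %.4g (difference %.4f)\n",
                x$p.value, x$mean.difference))
  }
  invisible(x)
}

#' @export
tidy.polygrs_ttest <- function(x, ...) x$groups

#' @export
glance.polygrs_ttest <- function(x, ...) {
  tibble::tibble(p.value = x$p.value, mean.difference = x$mean.difference)
}

#' Association of GRS with detailed colonoscopy outcomes
#'
#' For each polyp subtype — size (< 0.5 cm / >= 0.5 cm), advanced adenoma,
#' polyp count (one / multiple) and location (cecum-ascending,
#' transverse-descending, rectosigmoid) — fits a logistic regression of
#' subtype membership versus the no-polyp (or hyperplastic-only) reference
#' on continuous GRS. Subtypes with fewer than 10 members are reported with
#' a wide-CI warning; empty subtypes are omitted with a message.
#'
#' @param scores Score tibble from [compute_grs()].
#' @param phenotypes Phenotype tibble (see [read_phenotypes()]).
#' @return Tibble with one row per subtype: `variable`, `level`, `n`,
#'   `grs.mean`, `grs.conf.low`, `grs.conf.high`, `odds.ratio`, `conf.low`,
#'   `conf.high`, `p.value`. The first rows cover the reference group and
#'   all adenomatous polyps.
#' @export
subgroup_associations <- function(scores, phenotypes) {
  df <- dplyr::inner_join(scores, phenotypes, by = "subject_id")
  ref <- df[df$outcome == "negative", ]
  pos <- df[df$outcome == "positive", ]
  z <- stats::qnorm(0.975)
  mean_ci <- function(v) {
    se <- stats::sd(v) / sqrt(length(v))
    c(mean(v), mean(v) - z * se, mean(v) + z * se)
  }
  subsets <- list(
    list("all", "adenomatous polyps", pos),
    list("polyp_size_class", "lt_0.5cm",
         pos[!is.na(pos$polyp_size_class) &
               pos$polyp_size_class == "lt_0.5cm", ]),
    list("polyp_size_class", "ge_0.5cm",
         pos[!is.na(pos$polyp_size_class) &
               pos$polyp_size_class == "ge_0.5cm", ]),
    list("advanced_adenoma", "advanced",
         pos[!is.na(pos$advanced_adenoma) & pos$advanced_adenoma, ]),
    list("polyp_count_class", "one",
         pos[!is.na(pos$polyp_count_class) &
               pos$polyp_count_class == "one", ]),
    list("polyp_count_class", "multiple",
         pos[!is.na(pos$polyp_count_class) &
               pos$polyp_count_class == "multiple", ]),
    list("polyp_location", "CA",
         pos[!is.na(pos$polyp_location) & pos$polyp_location == "CA", ]),
    list("polyp_location", "TD",
         pos[!is.na(pos$polyp_location) & pos$polyp_location == "TD", ]),
    list("polyp_location", "RS",
         pos[!is.na(pos$polyp_location) & pos$polyp_location == "RS", ])
  )
  ref_ci <- mean_ci(ref$grs)
  rows <- list(tibble::tibble(
    variable = "reference", level = "no polyps or HP", n = nrow(ref),
    grs.mean = ref_ci[1], grs.conf.low = ref_ci[2], grs.conf.high = ref_ci[3],
    odds.ratio = 1, conf.low = NA_real_, conf.high = NA_real_,
    p.value = NA_real_
  ))
  for (s in subsets) {
    sub <- s[[3]]
    if (nrow(sub) == 0) {
      message("subtype ", s[[1]], "=", s[[2]], " empty; row omitted")
      next
    }
    if (nrow(sub) < 10) {
      warning("subtype ", s[[1]], "=", s[[2]], " has < 10 members; ",
              "confidence interval will be wide", call. = FALSE)
    }
    mdl <- dplyr::bind_rows(
      dplyr::mutate(ref[, "grs"], member = 0L),
      dplyr::mutate(sub[, "grs"], member = 1L)
    )
    fit <- fit_logistic(mdl, "member", "grs")
    est <- generics::tidy(fit)
    est <- est[est$term == "grs", ]
    ci <- mean_ci(sub$grs)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = s[[1]], level = s[[2]], n = nrow(sub),
      grs.mean = ci[1], grs.conf.low = ci[2], grs.conf.high = ci[3],
      odds.ratio = est$odds.ratio, conf.low = est$conf.low,
      conf.high = est$conf.high, p.value = est$p.value
    )
  }
  dplyr::bind_rows(rows)
}
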