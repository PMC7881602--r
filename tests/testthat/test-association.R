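test_that("2x2 odds ratio reproduces the worked clinical examples", {
  # male sex vs adenoma: 247/411 exposed, 273/838 unexposed
  male <- odds_ratio_2x2(247, 273, 411, 838)
  expect_equal(round(male$estimate, 2), 1.84)
  # positive family history: a weak, non-significant association
  fh <- odds_ratio_2x2(40, 480, 87, 1162)
  expect_equal(round(fh$estimate, 2), 1.11)
  expect_gt(fh$p.value, 0.05)
  # symmetry: identical margins give OR exactly 1
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$estimate, 1)
})

test_that("2x2 odds ratio transforms correctly under label swaps", {
  base <- odds_ratio_2x2(12, 7, 5, 21)
  swapped <- odds_ratio_2x2(7, 12, 21, 5) # swap exposure labels
  expect_equal(swapped$estimate, 1 / base$estimate, tolerance = 1e-12)
  expect_equal(swapped$p.value, base$p.value, tolerance = 1e-12)
  double <- odds_ratio_2x2(21, 5, 7, 12) # swap both -> OR unchanged
  expect_equal(double$estimate, base$estimate, tolerance = 1e-12)
})

test_that("zero cells error unless the continuity correction is requested", {
  expect_error(odds_ratio_2x2(0, 5, 3, 7), "zero cell")
  got <- odds_ratio_2x2(0, 5, 3, 7, correction = TRUE)
  expect_true(got$corrected)
  expect_equal(got$estimate, (0.5 * 7.5) / (5.5 * 3.5), tolerance = 1e-12)
})

test_that("detection rate is the exact quotient at display precision", {
  expect_equal(detection_rate(520, 1769)$percent, "29.4%")
  expect_equal(detection_rate(247, 658)$percent, "37.5%")
  expect_equal(detection_rate(273, 1111)$percent, "24.6%")
  expect_equal(detection_rate(0, 100)$rate, 0)
  expect_error(detection_rate(1, 0), "positive")
  expect_error(detection_rate(5, 3), "positives")
})

test_that("saturated logistic fit equals the closed-form 2x2 odds ratio", {
  df <- expand_2x2(247, 273, 411, 838)
  fit <- fit_logistic(df, "positive", "exposed")
  est <- tidy(fit)
  or_glm <- est$odds.ratio[est$term == "exposed"]
  or_cf <- odds_ratio_2x2(247, 273, 411, 838)$estimate
  expect_equal(or_glm, or_cf, tolerance = 1e-6)
})

test_that("a permuted covariate shows a null odds ratio", {
  set.seed(21)
  df <- expand_2x2(150, 150, 350, 350)
  df$exposed <- sample(df$exposed) # sever any association
  est <- tidy(fit_logistic(df, "positive", "exposed"))
  est <- est[est$term == "exposed", ]
  expect_true(est$conf.low < 1 && est$conf.high > 1)
})

test_that("logistic fit recovers generator truth within 2 SE", {
  cfg <- sim_config(n_subjects = 5000, seed = 31)
  st <- simulate_study(cfg)
  scores <- compute_grs(st$genotypes, st$panel)
  df <- dplyr::inner_join(scores, st$phenotypes, by = "subject_id")
  df$positive <- as.integer(df$outcome == "positive")
  df$log_grs <- log(df$grs)
  df$male <- as.integer(df$sex == "male")
  df$fh <- as.integer(df$family_history == "positive")
  est <- tidy(fit_logistic(df, "positive",
                           c("log_grs", "age_at_colonoscopy", "male",
                             "fh", "bmi")))
  est <- est[est$term == "log_grs", ]
  # the generator applies the panel log-ORs at scale 1, so the true
  # coefficient on log(GRS) is 1
  expect_lt(abs(est$estimate - 1), 2 * est$std.error)
})

test_that("separation is reported rather than silently fit", {
  df <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                       y = c(rep(0, 20), rep(1, 20)))
  expect_error(suppressWarnings(fit_logistic(df, "y", "x")), "separation")
})

test_that("trend test matches direction, null and a permutation oracle", {
  # strictly increasing rates at large n: overwhelming evidence
  inc <- trend_across_categories(c(50, 300, 200), c(500, 1000, 400))
  expect_lt(inc$p.value, 1e-6)
  expect_equal(as.character(inc$table$category),
               c("low", "average", "elevated"))
  # equal rates: statistic at zero
  flat <- trend_across_categories(c(30, 30, 30), c(100, 100, 100))
  expect_lt(flat$statistic, 1e-10)
  # toy table vs 100k-permutation oracle, within 3 Monte-Carlo SEs
  pos <- c(1, 5, 9); tot <- c(10, 10, 10)
  tt <- trend_across_categories(pos, tot)
  p_perm <- oracle_trend_perm_p(pos, tot, n_perm = 1e5)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 1e5)
  expect_lt(abs(tt$p.value - p_perm), 3 * mc_se + 1e-4)
  expect_error(trend_across_categories(5, 10), "at least 2")
})

test_that("rates recompose to the overall rate weighted by totals", {
  tt <- trend_across_categories(c(51, 335, 127), c(310, 1179, 280))
  with(tt$table, {
    expect_true(all(rate >= 0 & rate <= 1))
    expect_equal(sum(rate * total) / sum(total),
                 sum(positives) / sum(total), tolerance = 1e-12)
  })
})

test_that("group-mean comparison detects shifts at nominal power", {
  # identical groups: zero difference, p = 1
  df0 <- tibble::tibble(grs = rep(rnorm(50, 1, 0.3), 2),
                        outcome = rep(c("positive", "negative"), each = 50))
  got0 <- compare_group_means(df0, "grs", "outcome")
  expect_equal(got0$mean.difference, 0, tolerance = 1e-12)
  expect_equal(got0$p.value, 1, tolerance = 1e-8)

  # delta = 0.05, sigma = 0.3, n = 500/1200: analytic power ~ 0.87,
  # so the rejection fraction over 200 replicates stays well above 0.7
  set.seed(77)
  rej <- vapply(1:200, function(i) {
    df <- tibble::tibble(
      grs = c(rnorm(500, 1.02, 0.3), rnorm(1200, 0.97, 0.3)),
      outcome = rep(c("positive", "negative"), c(500, 1200))
    )
    compare_group_means(df, "grs", "outcome")$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.7)

  expect_error(
    compare_group_means(tibble::tibble(grs = rnorm(5), outcome = "a"),
                        "grs", "outcome"),
    "at least 2 groups"
  )
  expect_error(
    compare_group_means(
      tibble::tibble(grs = rep(1, 10),
                     outcome = rep(c("a", "b"), each = 5)),
      "grs", "outcome"),
    "zero variance"
  )
})

test_that("subgroup table mirrors reference vs subtype structure", {
  set.seed(55)
  n <- 600
  ids <- sprintf("s%03d", 1:n)
  ph <- blank_phenotypes(ids)
  ph$outcome[1:200] <- "positive"
  ph$polyp_size_class[1:120] <- "lt_0.5cm"
  ph$polyp_size_class[121:200] <- "ge_0.5cm"
  ph$polyp_count_class[1:200] <- sample(c("one", "multiple"), 200, TRUE)
  ph$polyp_location[1:200] <- sample(c("CA", "TD", "RS"), 200, TRUE)
  ph$advanced_adenoma[121:160] <- TRUE

  # null scores: same GRS distribution in every subtype
  scores <- tibble::tibble(
    subject_id = ids,
    grs = rlnorm(n, 0, 0.25),
    category = categorize_grs(rlnorm(n, 0, 0.25)),
    n_snps_used = 22L, flagged = FALSE
  )
  tab <- subgroup_associations(scores, ph)
  expect_equal(tab$variable[1], "reference")
  expect_equal(tab$odds.ratio[1], 1)
  sub <- tab[tab$variable != "reference", ]
  # every null subtype CI covers OR = 1
  expect_true(all(sub$conf.low < 1 & sub$conf.high > 1))

  # injected effect: shift GRS up in positives only
  scores2 <- scores
  shift <- ph$outcome == "positive"
  scores2$grs[shift] <- scores2$grs[shift] * exp(0.4)
  tab2 <- subgroup_associations(scores2, ph)
  all_row <- tab2[tab2$variable == "all", ]
  expect_gt(all_row$odds.ratio, 1)
  expect_gt(all_row$conf.low, 1)

  # empty subtype is omitted with a message
  ph3 <- ph
  ph3$advanced_adenoma[] <- FALSE
  expect_message(tab3 <- subgroup_associations(scores, ph3),
                 "advanced.*omitted")
  expect_false("advanced" %in% tab3$level)
})
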