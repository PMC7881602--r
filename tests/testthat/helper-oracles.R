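# Independent oracles and tiny fixture builders, kept free of the package's
# own computational paths.

# brute-force E[OR^g] with g ~ Binomial(2, f): the definition of the
# normalization constant, summed term by term
oracle_w <- function(f, or) {
  sum(stats::dbinom(0:2, 2, f) * or^(0:2))
}

# one-row-per-subject expansion of a 2x2 count table
expand_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    exposed = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    positive = c(rep(1, a + b), rep(0, c + d))
  )
}

# permutation p-value for trend in proportions across ordered categories,
# using the score-outcome cross-product as the permutation statistic
oracle_trend_perm_p <- function(positives, totals, n_perm = 1e5,
                                seed = 404) {
  set.seed(seed)
  score <- rep(seq_along(totals) - 1, totals)
  y <- unlist(mapply(function(p, t) c(rep(1, p), rep(0, t - p)),
                     positives, totals, SIMPLIFY = FALSE))
  obs <- abs(sum(score * y) - sum(score) * mean(y))
  stat <- replicate(n_perm, {
    ys <- sample(y)
    abs(sum(score * ys) - sum(score) * mean(ys))
  })
  mean(stat >= obs - 1e-12)
}

# direct O-E/V log-rank for two groups, computed from first principles
oracle_logrank_2group <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L # 0/1
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# minimal valid single-SNP panel
one_snp_panel <- function(f = 0.3, or = 1.2, id = "rs1") {
  tibble::tibble(
    snp_id = id, chrom = "1", pos = 1000L, risk_allele = "A",
    other_allele = "G", odds_ratio = or, risk_allele_freq = f
  )
}

# small multi-SNP panel with fixed, hand-set parameters
toy_panel <- function() {
  tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "2", "3"),
    pos = c(100L, 200L, 300L),
    risk_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    odds_ratio = c(1.2, 1.1, 1.3),
    risk_allele_freq = c(0.3, 0.4, 0.2)
  )
}

# phenotype tibble with every required column, n subjects, all negative
blank_phenotypes <- function(ids, age = 60) {
  n <- length(ids)
  tibble::tibble(
    subject_id = ids,
    age_at_colonoscopy = rep(age, n),
    sex = factor(rep("female", n), levels = c("male", "female")),
    bmi = rep(28, n),
    family_history = factor(rep("negative", n),
                            levels = c("positive", "negative")),
    outcome = factor(rep("negative", n),
                     levels = c("positive", "negative")),
    polyp_size_class = factor(rep("none", n),
                              levels = c("none", "lt_0.5cm", "ge_0.5cm")),
    polyp_count_class = factor(rep("none", n),
                               levels = c("none", "one", "multiple")),
    polyp_location = factor(rep("none", n),
                            levels = c("none", "CA", "TD", "RS")),
    advanced_adenoma = rep(FALSE, n)
  )
}
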