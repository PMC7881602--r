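test_that("normalization constant matches brute-force E[OR^g] under HWE", {
  # frozen worked example: f = 0.3, OR = 1.2 with HWE weights .49/.42/.09
  expect_equal(grs_normalization(0.3, 1.2), 1.1236, tolerance = 1e-12)
  # a null SNP or an absent risk allele never rescales the score
  expect_identical(grs_normalization(0.5, 1.0), 1)
  expect_identical(grs_normalization(0.0, 2.0), 1)

  set.seed(11)
  for (i in 1:50) {
    f <- runif(1)
    or <- runif(1, 0.5, 3)
    expect_equal(grs_normalization(f, or), oracle_w(f, or),
                 tolerance = 1e-12)
  }
})

test_that("normalization constant rejects invalid parameters", {
  expect_error(grs_normalization(-0.1, 1.2), "frequency")
  expect_error(grs_normalization(1.1, 1.2), "frequency")
  expect_error(grs_normalization(0.3, 0), "positive")
  expect_error(grs_normalization(NA_real_, 1.2), "finite")
  expect_error(grs_normalization(0.3, Inf), "finite")
})

test_that("per-SNP risk factor evaluates OR^g / W with neutral missing", {
  expect_equal(snp_risk_factor(0, 1.5, 1.1), 1 / 1.1)
  expect_equal(snp_risk_factor(2, 1.2, 1.1236), 1.44 / 1.1236)
  expect_identical(snp_risk_factor(NA, 2.0, 1.3), 1)
  expect_error(snp_risk_factor(3, 1.2, 1.1), "dosage")
  expect_error(snp_risk_factor(1, 1.2, 0), "positive")
})

test_that("GRS is the product of per-SNP factors, standardized", {
  # single-SNP hand product against the brute-force normalizer
  panel <- one_snp_panel(f = 0.3, or = 1.2)
  geno <- tibble::tibble(subject_id = c("s1", "s2", "s3"),
                         rs1 = c(0, 1, 2))
  res <- compute_grs(geno, panel)
  w <- oracle_w(0.3, 1.2)
  expect_equal(res$grs, c(1 / w, 1.2 / w, 1.44 / w), tolerance = 1e-12)
  expect_equal(res$n_snps_used, c(1L, 1L, 1L))
  expect_equal(res$subject_id, geno$subject_id)

  # all ORs 1: every subject scores exactly 1 whatever the dosages
  null_panel <- toy_panel()
  null_panel$odds_ratio <- 1
  geno3 <- tibble::tibble(subject_id = c("a", "b"),
                          rs1 = c(0, 2), rs2 = c(1, 1), rs3 = c(2, 0))
  expect_equal(compute_grs(geno3, null_panel)$grs, c(1, 1),
               tolerance = 1e-12)
})

test_that("GRS is invariant to panel order and to appended null SNPs", {
  panel <- toy_panel()
  set.seed(3)
  geno <- tibble::tibble(
    subject_id = sprintf("s%d", 1:20),
    rs1 = sample(0:2, 20, TRUE), rs2 = sample(0:2, 20, TRUE),
    rs3 = sample(0:2, 20, TRUE)
  )
  base <- compute_grs(geno, panel)
  shuffled <- compute_grs(geno, panel[c(3, 1, 2), ])
  expect_equal(base$grs, shuffled$grs, tolerance = 1e-12)

  with_null <- dplyr::bind_rows(panel, tibble::tibble(
    snp_id = "rs_null", chrom = "4", pos = 400L, risk_allele = "T",
    other_allele = "C", odds_ratio = 1, risk_allele_freq = 0.25
  ))
  geno$rs_null <- sample(0:2, 20, TRUE)
  expect_equal(compute_grs(geno, with_null)$grs, base$grs,
               tolerance = 1e-12)
})

test_that("GRS increases strictly in a dosage when that SNP's OR > 1", {
  panel <- toy_panel()
  geno <- tibble::tibble(subject_id = c("d0", "d1", "d2"),
                         rs1 = c(0, 1, 2), rs2 = 1, rs3 = 1)
  g <- compute_grs(geno, panel)$grs
  expect_true(all(diff(g) > 0))
})

test_that("log-domain score equals the explicit log-sum identity", {
  panel <- toy_panel()
  set.seed(5)
  geno <- tibble::tibble(
    subject_id = sprintf("s%d", 1:30),
    rs1 = sample(0:2, 30, TRUE), rs2 = sample(0:2, 30, TRUE),
    rs3 = sample(0:2, 30, TRUE)
  )
  res <- compute_grs(geno, panel)
  w <- vapply(seq_len(3), function(j)
    oracle_w(panel$risk_allele_freq[j], panel$odds_ratio[j]), 0)
  expected <- as.matrix(geno[, panel$snp_id]) %*% log(panel$odds_ratio) -
    sum(log(w))
  expect_equal(log(res$grs), drop(expected), tolerance = 1e-10)
})

test_that("missing dosages are neutral, counted and flagged", {
  panel <- toy_panel()
  geno <- tibble::tibble(
    subject_id = c("full", "partial", "empty"),
    rs1 = c(1, 1, NA), rs2 = c(1, NA, NA), rs3 = c(1, NA, NA)
  )
  expect_warning(res <- compute_grs(geno, panel), "all dosages missing")
  expect_equal(nrow(res), 2) # the all-missing subject is excluded
  expect_equal(res$n_snps_used, c(3L, 1L))
  # partial subject misses 2/3 > 20% of the panel
  expect_equal(res$flagged, c(FALSE, TRUE))
  # the missing SNPs contribute exactly factor 1
  w1 <- oracle_w(0.3, 1.2)
  expect_equal(res$grs[2], 1.2 / w1, tolerance = 1e-12)
})

test_that("risk categories honor the closed middle band", {
  got <- categorize_grs(c(0.49, 0.5, 1.0, 1.5, 1.51, 0.3))
  expect_equal(as.character(got),
               c("low", "average", "average", "average", "elevated", "low"))
  expect_true(is.ordered(got))
  expect_error(categorize_grs(-1), "positive")
  expect_error(categorize_grs(1, low_cut = 2, high_cut = 1), "low_cut")
  # custom cutpoints shift the bands coherently
  expect_equal(as.character(categorize_grs(c(0.7, 0.8, 2.1),
                                           low_cut = 0.8, high_cut = 2)),
               c("low", "average", "elevated"))
})

test_that("scoring rejects genotype columns unknown to the panel", {
  geno <- tibble::tibble(subject_id = "s1", rs1 = 1, rs_other = 2)
  expect_error(compute_grs(geno, one_snp_panel()), "not in the panel")
})
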