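#' Population normalization constant for one SNP
#'
#' Computes the expected per-SNP risk factor in a reference population in
#' Hardy-Weinberg equilibrium at risk-allele frequency `f`:
#' \deqn{W = f^2 OR^2 + 2 f (1 - f) OR + (1 - f)^2}
#' which equals \eqn{E[OR^g]} for genotype dosage \eqn{g \sim Binomial(2, f)}.
#' Dividing each subject's per-SNP factor \eqn{OR^g} by `W` makes the
#' population-mean score equal 1, so the resulting GRS reads as relative risk
#' versus the general population.
#'
#' @param f Risk-allele frequency in the reference population, in \[0, 1\].
#'   Vectorized.
#' @param odds_ratio Per-allele odds ratio (> 0). Vectorized, recycled
#'   against `f`.
#' @return Numeric vector of normalization constants (all > 0).
#' @examples
#' grs_normalization(0.3, 1.2) # 1.1236
#' grs_normalization(0.5, 1.0) # 1: a null SNP never moves the score
#' @export
grs_normalization <- function(f, odds_ratio) {
  if (!is.numeric(f) || !is.numeric(odds_ratio)) {
    stop("`f` and `odds_ratio` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(!is.finite(odds_ratio))) {
    stop("`f` and `odds_ratio` must be finite", call. = FALSE)
  }
  if (any(f < 0 | f > 1)) {
    stop("risk-allele frequency must lie in [0, 1]", call. = FALSE)
  }
  if (any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be positive", call. = FALSE)
  }
  f^2 * odds_ratio^2 + 2 * f * (1 - f) * odds_ratio + (1 - f)^2
}

#' Per-SNP risk factor for a subject
#'
#' The multiplicative contribution of one SNP to a subject's GRS:
#' `odds_ratio^dosage / w`. A missing dosage contributes the neutral factor 1
#' (population-average risk), so missingness pulls a score toward 1 rather
#' than biasing it directionally.
#'
#' @param dosage Risk-allele count: 0, 1, 2 or `NA` (missing). Vectorized.
#' @param odds_ratio Per-allele odds ratio (> 0).
#' @param w Normalization constant from [grs_normalization()] (> 0).
#' @return Numeric vector of positive factors.
#' @export
snp_risk_factor <- function(dosage, odds_ratio, w) {
  if (any(odds_ratio <= 0) || any(w <= 0)) {
    stop("`odds_ratio` and `w` must be positive", call. = FALSE)
  }
  bad <- !is.na(dosage) & !dosage %in% c(0, 1, 2)
  if (any(bad)) {
    stop("dosage must be 0, 1, 2 or NA; got ",
         paste(unique(dosage[bad]), collapse = ", "), call. = FALSE)
  }
  out <- odds_ratio^dosage / w
  out[is.na(dosage)] <- 1
  out
}

#' Assign GRS risk categories
#'
#' Stratifies scores into `low` (GRS < `low_cut`), `average`
#' (`low_cut` <= GRS <= `high_cut`) and `elevated` (GRS > `high_cut`).
#' The middle band is closed on both ends, matching the strict inequalities
#' on the outer bands.
#'
#' @param grs Numeric vector of positive scores.
#' @param low_cut,high_cut Category boundaries, `0 < low_cut < high_cut`.
#'   Defaults 0.5 and 1.5.
#' @return Ordered factor with levels `low < average < elevated`.
#' @examples
#' categorize_grs(c(0.49, 0.5, 1.5, 1.51))
#' @export
categorize_grs <- function(grs, low_cut = 0.5, high_cut = 1.5) {
  if (!(low_cut > 0 && low_cut < high_cut)) {
    stop("need 0 < low_cut < high_cut", call. = FALSE)
  }
  if (any(!is.na(grs) & grs <= 0)) {
    stop("GRS values must be positive", call. = FALSE)
  }
  raw <- cut(grs,
             breaks = c(0, low_cut, high_cut, Inf),
             labels = c("low", "average", "elevated"),
             right = FALSE, include.lowest = TRUE)
  # cut() with right = FALSE puts high_cut itself in the upper bin; the
  # middle band is closed at both ends, so pull exact boundary hits back.
  raw[!is.na(grs) & grs == high_cut] <- "average"
  factor(raw, levels = c("low", "average", "elevated"), ordered = TRUE)
}

#' Compute population-standardized genetic risk scores
#'
#' For each subject, multiplies the per-SNP factors \eqn{OR_i^{g_i} / W_i}
#' over the panel, where \eqn{g_i} is the risk-allele dosage and \eqn{W_i}
#' the population normalization constant. The product is accumulated in the
#' log domain and exponentiated at the end. Missing dosages contribute a
#' neutral factor of 1; subjects missing more than `max_missing` of the panel
#' are flagged, and subjects with no non-missing dosage at all are dropped
#' with a warning rather than silently scored.
#'
#' @param genotypes Tibble of risk-allele dosages: a `subject_id` column plus
#'   one column per SNP (values 0, 1, 2 or `NA`), as returned by
#'   [read_genotypes_tsv()] or [read_genotypes_vcf()]. Panel SNPs absent from
#'   the matrix are treated as missing for every subject.
#' @param panel SNP panel tibble (see [read_panel()]).
#' @param low_cut,high_cut Risk-category boundaries passed to
#'   [categorize_grs()].
#' @param max_missing Fraction of panel SNPs a subject may miss before being
#'   flagged (default 0.2).
#' @return Tibble with one row per scored subject: `subject_id`, `grs`,
#'   `category`, `n_snps_used`, `flagged`. Subject order is preserved.
#' @examples
#' panel <- tibble::tibble(
#'   snp_id = "rs1", chrom = "1", pos = 100L, risk_allele = "A",
#'   other_allele = "G", odds_ratio = 1.2, risk_allele_freq = 0.3
#' )
#' geno <- tibble::tibble(subject_id = c("s1", "s2"), rs1 = c(1, 2))
#' compute_grs(geno, panel)
#' @export
compute_grs <- function(genotypes, panel, low_cut = 0.5, high_cut = 1.5,
                        max_missing = 0.2) {
  panel <- validate_panel(panel)
  stopifnot("subject_id" %in% names(genotypes))
  snp_cols <- setdiff(names(genotypes), "subject_id")
  unknown <- setdiff(snp_cols, panel$snp_id)
  if (length(unknown) > 0) {
    stop("genotype matrix has SNPs not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(panel$snp_id, snp_cols)
  if (length(absent) > 0) {
    warning(length(absent), " panel SNP(s) absent from genotypes, ",
            "treated as missing: ", paste(absent, collapse = ", "),
            call. = FALSE)
  }

  n <- nrow(genotypes)
  dosage <- matrix(NA_real_, nrow = n, ncol = nrow(panel),
                   dimnames = list(NULL, panel$snp_id))
  for (s in snp_cols) dosage[, s] <- as.numeric(genotypes[[s]])
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }

  log_or <- log(panel$odds_ratio)
  log_w <- log(grs_normalization(panel$risk_allele_freq, panel$odds_ratio))
  # per-subject log score: sum over non-missing SNPs of g*log(OR) - log(W)
  obs <- !is.na(dosage)
  d0 <- dosage
  d0[!obs] <- 0
  log_grs <- d0 %*% log_or - obs %*% log_w
  n_used <- rowSums(obs)

  all_missing <- n_used == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " subject(s) with all dosages missing ",
            "excluded from scoring: ",
            paste(genotypes$subject_id[all_missing], collapse = ", "),
            call. = FALSE)
  }

  out <- tibble::tibble(
    subject_id = genotypes$subject_id,
    grs = exp(drop(log_grs)),
    n_snps_used = as.integer(n_used),
    flagged = (nrow(panel) - n_used) / nrow(panel) > max_missing
  )
  out <- out[!all_missing, , drop = FALSE]
  out$category <- categorize_grs(out$grs, low_cut, high_cut)
  out[, c("subject_id", "grs", "category", "n_snps_used", "flagged")]
}
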