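#' Simulation configuration for a synthetic screening cohort
#'
#' Bundles every knob of the generator with defaults that echo the marginal
#' structure of a community-based screening-colonoscopy cohort: 1769
#' subjects, adenoma prevalence 0.29, 37% male, 7% positive family history,
#' age at first colonoscopy ~ Normal(60, 8) truncated above 45 years, BMI ~
#' Normal(28.5, 5), and a 22-SNP panel with risk-allele frequencies uniform
#' in \[0.1, 0.5\] and per-allele odds ratios uniform in \[1.05, 1.3\]
#' (GWAS-scale effects for colorectal cancer). Covariate effects enter the
#' outcome model as log odds ratios per unit: 0.01 per year of age, log(1.8)
#' for male sex, log(1.14) for positive family history, log(1.04) per BMI
#' unit.
#'
#' @param n_subjects Cohort size.
#' @param n_snps Panel size.
#' @param or_range,freq_range Ranges for per-allele OR and risk-allele
#'   frequency draws (degenerate ranges such as `c(1, 1)` are allowed and
#'   give a null panel).
#' @param baseline_prevalence Target positive fraction; the model intercept
#'   is calibrated by bisection to hit it in expectation.
#' @param genotype_effect_scale Multiplier on the per-SNP log-ORs in the
#'   outcome model: 1 means genotypes act with exactly the panel's published
#'   effects, 0 severs the genotype-outcome link (a null cohort).
#' @param covariate_effects Named numeric vector of log-ORs:
#'   `age` (per year), `male`, `family_history`, `bmi` (per unit).
#' @param age_mean,age_sd,age_min Age distribution (truncated normal,
#'   `age > age_min`).
#' @param bmi_mean,bmi_sd BMI distribution.
#' @param male_prob,family_history_prob Bernoulli probabilities.
#' @param missing_rate Per-genotype missing probability.
#' @param subtype_probs List with multinomial probabilities among positives:
#'   `size` (lt_0.5cm, ge_0.5cm), `count` (one, multiple), `location`
#'   (CA, TD, RS), and `advanced_given_large`, the probability of an
#'   advanced adenoma given size >= 0.5 cm.
#' @param seed Integer seed; every generator call is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 1769,
                       n_snps = 22,
                       or_range = c(1.05, 1.3),
                       freq_range = c(0.1, 0.5),
                       baseline_prevalence = 0.29,
                       genotype_effect_scale = 1,
                       covariate_effects = c(age = 0.01,
                                             male = log(1.8),
                                             family_history = log(1.14),
                                             bmi = log(1.04)),
                       age_mean = 60, age_sd = 8, age_min = 45,
                       bmi_mean = 28.5, bmi_sd = 5,
                       male_prob = 0.37,
                       family_history_prob = 0.07,
                       missing_rate = 0,
                       subtype_probs = list(
                         size = c(lt_0.5cm = 0.39, ge_0.5cm = 0.61),
                         count = c(one = 0.585, multiple = 0.415),
                         location = c(CA = 0.454, TD = 0.302, RS = 0.244),
                         advanced_given_large = 0.4
                       ),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_snps >= 1,
            baseline_prevalence > 0, baseline_prevalence < 1,
            missing_rate >= 0, missing_rate < 1)
  if (or_range[1] > or_range[2] || or_range[1] <= 0) {
    stop("invalid or_range", call. = FALSE)
  }
  if (freq_range[1] > freq_range[2] ||
      freq_range[1] <= 0 || freq_range[2] >= 1) {
    stop("invalid freq_range", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic SNP panel
#'
#' Draws per-allele odds ratios and risk-allele frequencies uniformly from
#' the configured ranges, with alleles and coordinates invented. The panel
#' stands in for a curated list of risk-associated SNPs and is labeled
#' synthetic; it is not any published panel.
#'
#' @param config A [sim_config()] object (only the panel fields are used).
#' @return Panel tibble with `n_snps` rows.
#' @export
simulate_panel <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_snps
  bases <- c("A", "C", "G", "T")
  risk <- sample(bases, n, replace = TRUE)
  other <- vapply(risk, function(b) sample(setdiff(bases, b), 1), "")
  validate_panel(tibble::tibble(
    snp_id = sprintf("sim_rs%03d", seq_len(n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = as.integer(sort(sample.int(5e7, n))),
    risk_allele = risk,
    other_allele = unname(other),
    odds_ratio = stats::runif(n, config$or_range[1], config$or_range[2]),
    risk_allele_freq = stats::runif(n, config$freq_range[1],
                                    config$freq_range[2])
  ))
}

#' Generate risk-allele dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn independently per SNP as Binomial(2, f_i) — genotype
#' frequencies f^2 / 2f(1-f) / (1-f)^2 — with no linkage disequilibrium
#' between SNPs, matching the independence assumption of the multiplicative
#' GRS. Missing values are injected completely at random at `missing_rate`.
#'
#' @param panel Panel tibble.
#' @param n_subjects Number of subjects.
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param seed Integer seed.
#' @return Genotype tibble (`subject_id` = `S00001`, ... plus one dosage
#'   column per panel SNP).
#' @export
simulate_genotypes <- function(panel, n_subjects, missing_rate = 0,
                               seed = 1L) {
  panel <- validate_panel(panel)
  set.seed(seed)
  n_snp <- nrow(panel)
  dosage <- vapply(seq_len(n_snp), function(j) {
    stats::rbinom(n_subjects, 2, panel$risk_allele_freq[j])
  }, numeric(n_subjects))
  dosage <- matrix(dosage, nrow = n_subjects)
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_subjects * n_snp) < missing_rate,
                   nrow = n_subjects)
    dosage[drop] <- NA_real_
  }
  colnames(dosage) <- panel$snp_id
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%05d", seq_len(n_subjects))),
    tibble::as_tibble(dosage)
  )
}

# expit prevalence of eta + b0, bisection on b0
calibrate_intercept <- function(eta, target, max_iter = 100) {
  lo <- -20; hi <- 20
  prev <- function(b0) mean(stats::plogis(b0 + eta))
  if (prev(lo) > target || prev(hi) < target) {
    stop("prevalence calibration failed: target outside achievable range",
         call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (prev(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) return(mid)
  }
  stop("prevalence calibration did not converge after ", max_iter,
       " bisection steps", call. = FALSE)
}

#' Generate phenotypes from genotypes under a logistic disease model
#'
#' Covariates are drawn from the configured marginals, then the outcome is
#' Bernoulli with
#' \deqn{logit(p) = \beta_0 + s \sum_i g_i \ln OR_i + \beta_{age}(age -
#'   \bar{age}) + \beta_{male} male + \beta_{fh} fh + \beta_{bmi}(BMI -
#'   \bar{BMI})}
#' where `s` is `genotype_effect_scale` and the intercept is calibrated by
#' bisection so the expected prevalence over the drawn cohort equals
#' `baseline_prevalence`. Missing dosages contribute their
#' population-expected log-factor, keeping the calibration unbiased.
#' Among positives, polyp size, count and location classes are assigned
#' multinomially and the advanced-adenoma flag is drawn for polyps
#' >= 0.5 cm.
#'
#' @param genotypes Genotype tibble.
#' @param panel Panel tibble aligned to `genotypes`.
#' @param config A [sim_config()] object.
#' @return Phenotype tibble with the schema of [read_phenotypes()].
#' @export
simulate_phenotypes <- function(genotypes, panel, config = sim_config()) {
  panel <- validate_panel(panel)
  set.seed(config$seed + 1L)
  n <- nrow(genotypes)

  # truncated normal above age_min
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(age <= config$age_min)) {
    idx <- age <= config$age_min
    age[idx] <- stats::rnorm(sum(idx), config$age_mean, config$age_sd)
  }
  male <- stats::rbinom(n, 1, config$male_prob)
  fh <- stats::rbinom(n, 1, config$family_history_prob)
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)

  log_or <- log(panel$odds_ratio)
  dosage <- as.matrix(genotypes[, panel$snp_id, drop = FALSE])
  exp_dose <- 2 * panel$risk_allele_freq  # E[g] used for missing cells
  for (j in seq_len(ncol(dosage))) {
    dosage[is.na(dosage[, j]), j] <- exp_dose[j]
  }
  ce <- config$covariate_effects
  eta <- config$genotype_effect_scale * drop(dosage %*% log_or) +
    ce[["age"]] * (age - config$age_mean) +
    ce[["male"]] * male +
    ce[["family_history"]] * fh +
    ce[["bmi"]] * (bmi - config$bmi_mean)
  b0 <- calibrate_intercept(eta, config$baseline_prevalence)
  outcome <- stats::rbinom(n, 1, stats::plogis(b0 + eta))

  sp <- config$subtype_probs
  size <- count <- location <- rep("none", n)
  advanced <- rep(FALSE, n)
  pos <- which(outcome == 1)
  if (length(pos) > 0) {
    size[pos] <- sample(names(sp$size), length(pos), replace = TRUE,
                        prob = sp$size)
    count[pos] <- sample(names(sp$count), length(pos), replace = TRUE,
                         prob = sp$count)
    location[pos] <- sample(names(sp$location), length(pos), replace = TRUE,
                            prob = sp$location)
    large <- pos[size[pos] == "ge_0.5cm"]
    advanced[large] <- stats::runif(length(large)) < sp$advanced_given_large
  }

  tibble::tibble(
    subject_id = genotypes$subject_id,
    age_at_colonoscopy = round(age, 1),
    sex = factor(ifelse(male == 1, "male", "female"),
                 levels = c("male", "female")),
    bmi = round(bmi, 1),
    family_history = factor(ifelse(fh == 1, "positive", "negative"),
                            levels = c("positive", "negative")),
    outcome = factor(ifelse(outcome == 1, "positive", "negative"),
                     levels = c("positive", "negative")),
    polyp_size_class = factor(size,
                              levels = c("none", "lt_0.5cm", "ge_0.5cm")),
    polyp_count_class = factor(count, levels = c("none", "one", "multiple")),
    polyp_location = factor(location, levels = c("none", "CA", "TD", "RS")),
    advanced_adenoma = advanced
  )
}

#' Generate a complete synthetic study
#'
#' Composes [simulate_panel()], [simulate_genotypes()] and
#' [simulate_phenotypes()] into one reproducible bundle. When `out_dir` is
#' given, writes `panel.tsv`, `genotypes.tsv`, `genotypes.vcf`,
#' `phenotypes.csv` and a `manifest.json` recording the configuration and
#' seed for exact re-generation.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional output directory.
#' @return List with `panel`, `genotypes`, `phenotypes`, `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  panel <- simulate_panel(config)
  genotypes <- simulate_genotypes(panel, config$n_subjects,
                                  config$missing_rate, seed = config$seed)
  phenotypes <- simulate_phenotypes(genotypes, panel, config)
  bundle <- list(panel = panel, genotypes = genotypes,
                 phenotypes = phenotypes, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    write_genotypes_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_genotypes_vcf(genotypes, panel,
                        file.path(out_dir, "genotypes.vcf"))
    write_phenotypes(phenotypes, file.path(out_dir, "phenotypes.csv"))
    manifest <- unclass(config)
    manifest$generated_at <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
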