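#' @importFrom rlang .data
NULL

panel_cols <- c("snp_id", "chrom", "pos", "risk_allele", "other_allele",
                "odds_ratio", "risk_allele_freq")

#' Validate a SNP panel
#'
#' Checks the panel schema used throughout the package: unique `snp_id`,
#' positive odds ratios, frequencies strictly inside (0, 1), and distinct
#' risk/other alleles. Offending rows are named in the error.
#'
#' @param panel A data frame with columns `snp_id`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, `odds_ratio`, `risk_allele_freq`.
#' @return The panel as a tibble, invisibly validated.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  missing_cols <- setdiff(panel_cols, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  problems <- character()
  dup <- panel$snp_id[duplicated(panel$snp_id)]
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicate snp_id: ",
                                   paste(unique(dup), collapse = ", ")))
  }
  bad_or <- which(!is.finite(panel$odds_ratio) | panel$odds_ratio <= 0)
  if (length(bad_or) > 0) {
    problems <- c(problems, paste0("odds_ratio must be > 0 (rows ",
                                   paste(bad_or, collapse = ", "), ")"))
  }
  bad_f <- which(!is.finite(panel$risk_allele_freq) |
                   panel$risk_allele_freq <= 0 | panel$risk_allele_freq >= 1)
  if (length(bad_f) > 0) {
    problems <- c(problems, paste0("risk_allele_freq must be in (0,1) (rows ",
                                   paste(bad_f, collapse = ", "), ")"))
  }
  same <- which(panel$risk_allele == panel$other_allele)
  if (length(same) > 0) {
    problems <- c(problems, paste0("risk_allele equals other_allele (rows ",
                                   paste(same, collapse = ", "), ")"))
  }
  if (length(problems) > 0) {
    stop("invalid SNP panel: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  panel
}

#' Read a SNP panel from TSV
#'
#' Expects a tab-separated file with header columns `snp_id`, `chrom`, `pos`,
#' `risk_allele`, `other_allele`, `odds_ratio`, `risk_allele_freq`. Odds
#' ratios are per-allele; frequencies refer to the external reference
#' population used for standardization (e.g. gnomAD NFE) and are never
#' recomputed from the cohort being scored.
#'
#' @param path Path to the panel TSV.
#' @return Validated panel tibble.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  panel <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             snp_id = readr::col_character(),
                             chrom = readr::col_character(),
                             pos = readr::col_integer(),
                             risk_allele = readr::col_character(),
                             other_allele = readr::col_character(),
                             odds_ratio = readr::col_double(),
                             risk_allele_freq = readr::col_double()
                           ))
  if (nrow(panel) == 0) stop("panel file is empty: ", path, call. = FALSE)
  validate_panel(panel)
}

#' Read risk-allele dosages from a wide TSV
#'
#' The file holds one row per subject (`subject_id` column) and one column
#' per SNP, with cells 0, 1, 2 or `NA`. Column names must all appear in the
#' panel.
#'
#' @param path Path to the dosage TSV.
#' @param panel Validated SNP panel the columns are checked against.
#' @return Genotype tibble (`subject_id` plus one dosage column per SNP).
#' @export
read_genotypes_tsv <- function(path, panel) {
  panel <- validate_panel(panel)
  geno <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(geno)) {
    stop("genotype TSV must have a subject_id column", call. = FALSE)
  }
  geno$subject_id <- as.character(geno$subject_id)
  snp_cols <- setdiff(names(geno), "subject_id")
  unknown <- setdiff(snp_cols, panel$snp_id)
  if (length(unknown) > 0) {
    stop("genotype TSV columns not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (s in snp_cols) {
    v <- geno[[s]]
    bad <- which(!is.na(v) & !v %in% c(0, 1, 2))
    if (length(bad) > 0) {
      stop("invalid dosage in column ", s, ", row(s) ",
           paste(bad, collapse = ", "), ": values must be 0/1/2/NA",
           call. = FALSE)
    }
    geno[[s]] <- as.numeric(v)
  }
  tibble::as_tibble(geno)
}

#' Read risk-allele dosages from a VCF
#'
#' Extracts GT fields and converts them to risk-allele dosages aligned to a
#' panel. Sites are matched by chromosome + position, and the VCF REF/ALT
#' pair must equal the panel's risk/other allele pair in one of the two
#' orientations: when the risk allele is ALT the dosage is the ALT-allele
#' count, when it is REF the count is flipped (`2 - alt count`). Sites whose
#' alleles match in neither orientation (including strand mismatches) are
#' excluded with a warning, never silently flipped. Panel SNPs with no
#' matching VCF record yield missing dosages for all subjects.
#'
#' @param path Path to a VCF 4.x file (uncompressed or bgzipped).
#' @param panel Validated SNP panel.
#' @param match_by `"position"` (default; chrom + pos + allele pair) or
#'   `"id"` (match on the VCF ID column; for files with unreliable
#'   coordinates).
#' @return Genotype tibble (`subject_id` plus one dosage column per panel
#'   SNP present in the VCF).
#' @export
read_genotypes_vcf <- function(path, panel, match_by = c("position", "id")) {
  panel <- validate_panel(panel)
  match_by <- match.arg(match_by)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF drops dims
  fix <- tibble::as_tibble(fix)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  subjects <- colnames(gt)

  geno <- tibble::tibble(subject_id = as.character(subjects))
  dropped <- character()
  for (i in seq_len(nrow(panel))) {
    p <- panel[i, ]
    if (match_by == "position") {
      hit <- which(fix$CHROM == p$chrom & as.integer(fix$POS) == p$pos)
    } else {
      hit <- which(!is.na(fix$ID) & fix$ID == p$snp_id)
    }
    if (length(hit) == 0) next
    if (length(hit) > 1) {
      warning("multiple VCF records match panel SNP ", p$snp_id,
              "; using none", call. = FALSE)
      next
    }
    ref <- fix$REF[hit]; alt <- fix$ALT[hit]
    if (ref == p$risk_allele && alt == p$other_allele) {
      flip <- TRUE
    } else if (ref == p$other_allele && alt == p$risk_allele) {
      flip <- FALSE
    } else {
      dropped <- c(dropped, p$snp_id)
      next
    }
    alt_count <- gt_to_alt_count(gt[hit, ])
    geno[[p$snp_id]] <- if (flip) 2 - alt_count else alt_count
  }
  if (length(dropped) > 0) {
    warning("allele mismatch (possible strand issue); site(s) excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  unmatched <- setdiff(panel$snp_id, c(names(geno), dropped))
  if (length(unmatched) > 0) {
    warning(length(unmatched), " panel SNP(s) not found in VCF: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  geno
}

# "0/1", "1|1", "./." -> count of ALT alleles (NA for missing)
gt_to_alt_count <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }, numeric(1), USE.NAMES = FALSE)
}

pheno_levels <- list(
  sex = c("male", "female"),
  family_history = c("positive", "negative"),
  outcome = c("positive", "negative"),
  polyp_size_class = c("none", "lt_0.5cm", "ge_0.5cm"),
  polyp_count_class = c("none", "one", "multiple"),
  polyp_location = c("none", "CA", "TD", "RS")
)

#' Read a phenotype table from CSV
#'
#' Columns: `subject_id`, `age_at_colonoscopy` (years), `sex`
#' (`male`/`female`), `bmi` (kg/m^2, may be `NA`), `family_history`
#' (`positive`/`negative`), `outcome` (`positive` = any adenomatous polyp,
#' `negative` = no polyps or hyperplastic only), and optionally
#' `polyp_size_class` (`none`/`lt_0.5cm`/`ge_0.5cm`), `polyp_count_class`
#' (`none`/`one`/`multiple`), `polyp_location` (`none`/`CA`/`TD`/`RS`:
#' cecum-ascending, transverse-descending, rectosigmoid) and
#' `advanced_adenoma` (logical). Subjects at or below `min_age` at first
#' screening colonoscopy fail the inclusion criterion and are excluded with
#' a message; records with a missing outcome are rejected. Negative subjects
#' carrying non-`none` polyp subtype fields draw a consistency warning.
#'
#' @param path Path to the phenotype CSV.
#' @param min_age Inclusion threshold in years; kept are ages strictly
#'   greater (default 45).
#' @return Phenotype tibble with validated factor columns.
#' @export
read_phenotypes <- function(path, min_age = 45) {
  ph <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "age_at_colonoscopy", "sex", "family_history",
                "outcome")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols) > 0) {
    stop("phenotype CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ph$subject_id <- as.character(ph$subject_id)
  if (any(is.na(ph$outcome))) {
    stop(sum(is.na(ph$outcome)), " record(s) with missing outcome rejected",
         call. = FALSE)
  }
  for (col in intersect(names(pheno_levels), names(ph))) {
    vals <- as.character(ph[[col]])
    bad <- unique(vals[!is.na(vals) & !vals %in% pheno_levels[[col]]])
    if (length(bad) > 0) {
      stop("invalid value(s) in ", col, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    ph[[col]] <- factor(vals, levels = pheno_levels[[col]])
  }
  n_excluded <- sum(ph$age_at_colonoscopy <= min_age)
  if (n_excluded > 0) {
    message(n_excluded, " subject(s) excluded: age at first screening ",
            "colonoscopy <= ", min_age)
    ph <- ph[ph$age_at_colonoscopy > min_age, , drop = FALSE]
  }
  neg <- !is.na(ph$outcome) & ph$outcome == "negative"
  for (col in c("polyp_size_class", "polyp_count_class", "polyp_location")) {
    if (col %in% names(ph) &&
        any(neg & !is.na(ph[[col]]) & ph[[col]] != "none")) {
      warning("negative outcome with non-none ", col,
              " — check record consistency", call. = FALSE)
    }
  }
  tibble::as_tibble(ph)
}

#' Write per-subject scores to TSV
#'
#' @param scores Tibble from [compute_grs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' Write a genotype dosage matrix to TSV
#'
#' @param genotypes Genotype tibble (`subject_id` plus dosage columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  readr::write_tsv(genotypes, path)
  invisible(path)
}

#' Write a SNP panel to TSV
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(validate_panel(panel), path)
  invisible(path)
}

#' Write a phenotype table to CSV
#'
#' @param phenotypes Phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotype fields, one biallelic record
#' per panel SNP (REF = other allele, ALT = risk allele), suitable for
#' round-tripping through [read_genotypes_vcf()].
#'
#' @param genotypes Genotype tibble of risk-allele dosages.
#' @param panel Validated SNP panel supplying coordinates and alleles.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, panel, path) {
  panel <- validate_panel(panel)
  snp_cols <- intersect(panel$snp_id, setdiff(names(genotypes), "subject_id"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$subject_id), collapse = "\t")
  ), con)
  gt_string <- c("0/0", "0/1", "1/1")
  for (s in snp_cols) {
    p <- panel[panel$snp_id == s, ]
    d <- genotypes[[s]]
    gt <- ifelse(is.na(d), "./.", gt_string[d + 1])
    writeLines(paste(c(p$chrom, p$pos, p$snp_id, p$other_allele,
                       p$risk_allele, ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
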