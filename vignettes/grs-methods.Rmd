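---
title: "Methods: population-standardized genetic risk scores for screening colonoscopy outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-standardized genetic risk scores for screening colonoscopy outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygrs)
```

## The score

`polygrs` computes a multiplicative, odds-ratio-weighted polygenic risk
score from risk-allele dosages at a panel of independent biallelic SNPs.
For subject $j$ with dosage $g_{ij} \in \{0, 1, 2\}$ at SNP $i$, per-allele
odds ratio $OR_i$ and reference-population risk-allele frequency $f_i$,

$$\mathrm{GRS}_j = \prod_{i=1}^{n} \frac{OR_i^{\,g_{ij}}}{W_i},
\qquad
W_i = f_i^2\,OR_i^2 + 2 f_i (1 - f_i)\,OR_i + (1 - f_i)^2 .$$

$W_i$ is the expectation of $OR_i^{g}$ when $g \sim \mathrm{Binomial}(2,
f_i)$, i.e. under Hardy–Weinberg genotype proportions at the reference
frequency. Dividing by it standardizes each SNP's factor so that the
population-mean score is 1, which lets a subject's GRS be read as relative
risk versus the general population. Subjects are stratified as **low**
(GRS $< 0.5$), **average** ($0.5 \le$ GRS $\le 1.5$) and **elevated**
(GRS $> 1.5$); the cutpoints are arguments everywhere they are used.

Assumptions inherited from this construction:

* SNPs combine multiplicatively (no interactions, no dominance terms);
* panel SNPs are in linkage equilibrium — correlated SNPs would be
  double-counted;
* the $f_i$ describe the population the subject should be compared to.
  They are taken from the panel file (an external reference such as gnomAD
  NFE) and never recomputed from the cohort being scored, since the cohort
  is usually enriched or depleted for the outcome.

### Numerical and edge-case choices

* The product is accumulated in the log domain,
  $\log \mathrm{GRS} = \sum_i (g_i \log OR_i - \log W_i)$, and
  exponentiated once. At 22 SNPs both routes agree to machine precision;
  the log route stays robust for much larger panels.
* **Missing dosages** contribute the neutral factor 1: the subject is
  assigned the population-average risk at that SNP, preserving the
  "relative to the population" reading without an imputation model. The
  number of non-missing SNPs is reported per subject (`n_snps_used`), and
  subjects missing more than 20% of the panel are flagged. A subject with
  no usable dosage at all is excluded with a warning — never silently
  scored as 1.
* **Category boundaries**: the middle band is read as the closed interval
  $[0.5, 1.5]$, since the outer bands are defined by strict inequalities.
  Scores landing exactly on a cutpoint are therefore "average".
* Allele harmonization in the VCF reader matches sites by chromosome +
  position and requires the REF/ALT pair to equal the panel's allele pair
  in one of the two orientations (flipping the dosage when the risk allele
  is REF). Sites whose alleles match in neither orientation — including
  strand flips — are excluded with a warning rather than guessed at,
  because a silent strand error corrupts the score directionally.
  Matching by rsID is opt-in (`match_by = "id"`) for files whose
  coordinates drift across builds.

## The association battery

Downstream of scoring, the package reproduces the standard analysis suite
for a screening cohort, all through base-R/`survival` machinery:

* **2×2 odds ratios** by the cross-product, with Woolf (log-scale Wald)
  confidence intervals and Wald p-values. Zero cells error unless the
  Haldane–Anscombe 0.5 correction is explicitly requested, and corrected
  results are flagged. The Woolf CI was chosen as the standard
  closed-form method; published tables sometimes print CIs from other
  machinery, so point estimates, not interval bounds, are the quantities
  to compare.
* **Logistic regression** via `stats::glm` (IRLS). The multivariable
  model is `outcome ~ age + male + family_history + bmi + grs` with GRS
  entered continuously, so its adjusted odds ratio is per unit of GRS
  (one population-average risk). Separation is detected from fitted
  probabilities pinned at 0/1 and reported as an error naming the worst
  term.
* **Trend across GRS categories**: Cochran–Armitage with equally spaced
  integer scores (0, 1, 2), via `stats::prop.trend.test`. Equal spacing
  is the default choice when no alternative scoring is stated; the test
  is validated against a permutation oracle in the suite.
* **Group means**: normal-theory 95% CIs and a Welch two-sample t-test.
* **Kaplan–Meier / log-rank** (`survival::survfit`, `survival::survdiff`):
  time zero is birth, the event is the first colonoscopy finding an
  adenomatous polyp at the subject's age, and event-free subjects are
  right-censored at their age at first screening colonoscopy — the only
  consistent reading of "diagnosis-free since birth" with single-timepoint
  screening data. Left-truncation is deliberately **not** applied; this
  mirrors the germline-predictor framing (a genotype is observable from
  age zero) but means the curves describe this screening design rather
  than general population incidence — a statistical caveat, not a bug.
  The log-rank test is unweighted by default; `rho` exposes
  Fleming–Harrington weighting.
* **Subgroup associations**: each polyp subtype (size < 0.5 / ≥ 0.5 cm,
  advanced adenoma, single/multiple, location CA/TD/RS) is contrasted
  against the no-polyp (or hyperplastic-only) reference by a logistic fit
  of subtype membership on continuous GRS. Subtypes under 10 members are
  reported with a wide-CI warning; empty subtypes are omitted with a
  message.

## The synthetic-cohort generator

The generator exists so every pipeline stage can be exercised against
known ground truth. It emulates the statistical structure the analysis
assumes:

* genotypes drawn independently per SNP as $\mathrm{Binomial}(2, f_i)$ —
  Hardy–Weinberg proportions with zero linkage disequilibrium, the
  idealization of a panel curated for pairwise $r^2 < 0.2$;
* outcome from a logistic model whose genetic term is exactly the panel's
  log odds ratios, $\mathrm{logit}(p) = \beta_0 + s \sum_i g_i \log OR_i +
  \text{covariates}$, so the true coefficient on $\log \mathrm{GRS}$ is
  the effect scale $s$ (1 by default, 0 for null cohorts);
* covariates with clinically familiar marginals: age at first screening
  colonoscopy $\sim N(60, 8^2)$ truncated above 45 years (the inclusion
  age), BMI $\sim N(28.5, 5^2)$ kg/m², 37% male, 7% positive family
  history, with covariate log-odds effects of 0.01/year, $\log 1.8$
  (male), $\log 1.14$ (family history) and $\log 1.04$ per BMI unit —
  the magnitudes a multivariable model on a screening cohort of this kind
  reports. The default cohort size is 1769 and the default target
  prevalence 0.29. These defaults describe realistic study conditions;
  they are not tuned to reproduce any particular dataset's outputs.
* $\beta_0$ is calibrated by bisection so that the *expected* prevalence
  over the drawn covariates equals the target — the covariate mixture has
  no closed-form prevalence. Missing dosages enter the linear predictor
  at their population expectation $2 f_i$, keeping calibration unbiased
  under missingness. Calibration failure (target unreachable, or no
  convergence in 100 steps) is an error, not a silent fallback.
* among positives, polyp size, count and location classes are assigned
  multinomially (defaults echoing the subtype mix of a screening cohort:
  39/61 small/large, 58/42 single/multiple, 45/30/24 CA/TD/RS) and the
  advanced-adenoma flag is drawn only for polyps ≥ 0.5 cm, keeping the
  records internally consistent.

What the generator does **not** emulate: linkage disequilibrium,
population structure and admixture, genotyping error, informative
missingness, correlation between covariates and genotype, and
non-multiplicative genetic architectures. Tests passing on synthetic
cohorts therefore validate the pipeline's statistics under its own
assumptions; they cannot certify behavior on real data that violates
them.

The shipped `inst/extdata/demo_panel_synthetic.tsv` is a generated,
clearly synthetic 22-SNP panel with GWAS-scale effects (OR $\in [1.05,
1.3]$, $f \in [0.1, 0.5]$); it is illustrative only and is not any
published SNP list.

## Validation strategy and problem sizes

The test suite checks each statistic against an independent route:
brute-force $E[OR^g]$ for $W$; hand-computed product-limit tables and a
first-principles $O\!-\!E/V$ implementation for KM/log-rank; a 100,000-draw
permutation oracle for the trend test; closed-form 2×2 odds ratios against
the saturated logistic fit; and parameter recovery on simulated cohorts
(50 replicates of $n = 5000$, requiring the true log-GRS coefficient
inside $\pm 2\,\mathrm{SE}$ in at least 90% of fits). The
population-standardization property is verified on a 50,000-subject null
cohort, where the sample-mean GRS must land in $[0.98, 1.02]$. These
problem sizes keep the full suite under a minute on a single core while
leaving Monte-Carlo error well below the asserted tolerances.

## Known limitations

* Frequencies and odds ratios are taken on trust from the panel file;
  the package does not audit them against an external reference.
* Only biallelic sites are matched; multi-allelic records and PLINK
  formats are out of scope.
* The KM analysis ignores left truncation (see above) and competing
  risks, and no proportional-hazards model is fit.
* Family history is a binary flag; richer pedigree definitions collapse
  to it.
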