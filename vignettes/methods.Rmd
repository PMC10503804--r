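---
title: "Methods: predicted-expression modifier scans for CHIP-associated cardiovascular risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicted-expression modifier scans for CHIP-associated cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmod)
```

## The scientific problem

Clonal hematopoiesis of indeterminate potential (CHIP) — the age-related
expansion of blood-cell clones carrying somatic driver mutations in genes
such as *DNMT3A*, *TET2*, *ASXL1* and *JAK2* — raises cardiovascular
disease (CVD) risk, plausibly through inflammasome signalling.  If that is
so, genetically determined differences in inflammatory gene expression
should *modify* the CHIP–CVD association: a person's inherited tendency to
express, say, *AIM2* more highly should matter mostly (or only) when a
mutant clone is present.

`chipmod` implements that modifier scan as a reusable pipeline:

1. **Predicted expression scores.**  For each gene, a per-individual score
   $PES_i = \sum_{j \in S_{\text{clump}}(r_c^2, w_c)} \hat\beta_j \, G_{ij}
   \, I(p_j < p_r)$ is built from external cis-eQTL summary statistics
   ($\hat\beta_j$, $p_j$), the individual's allele dosages $G_{ij}$, greedy
   LD clumping at squared-correlation threshold $r_c^2$ within a physical
   window $w_c$, and a P-value threshold $p_r$ — pruning and thresholding
   (P+T).
2. **Tuning.**  Thirty candidate configurations
   ($r_c^2 \in \{0.1, 0.01, 0.001\}$, $p_r \in \{5\times10^{-8},
   10^{-5}, 10^{-3}, 10^{-2}, 0.1\}$, $w_c \in \{250\text{ kb},
   5\text{ Mb}\}$) are evaluated against measured expression in
   independent cohorts; the configuration explaining the largest fraction
   of covariate-adjusted expression variance wins, and genes whose best
   $r^2$ does not exceed 1% are dropped.
3. **CHIP annotation.**  Somatic calls are filtered to a whitelist of
   driver genes at variant allele fraction (VAF) strictly above 2%;
   per-sample indicators are derived for composite CHIP, individual driver
   genes, and large clones (VAF > 10%).
4. **The scan.**  For every (CHIP variable, gene score) pair, Cox
   proportional-hazards models of incident CVD are fitted separately among
   carriers and non-carriers (per 1-SD score).  Pairs significant *only*
   among carriers (P < 0.05 present, P ≥ 0.05 absent) are carried forward
   to a hierarchical interaction model (score + CHIP + score×CHIP), whose
   product-term Wald statistics are corrected by Benjamini–Hochberg FDR.
   An exploratory arm tests carried-forward scores against 31 hematologic
   and 5 cardiometabolic quantitative traits among carriers, with FDR
   applied within each trait family.

All models adjust for age at enrollment, sex, an ancestry indicator, BMI,
type-2-diabetes status, ever-smoking and ten genetic principal components;
rows with any missing adjusted covariate are removed (complete-case) and
the removed fraction is reported.

## The synthetic cohort: what it emulates

The real datasets behind such a scan (biobank-scale exomes, genotype
arrays and registry follow-up; external eQTL consortia; RNA-Seq tuning
panels) are access-restricted, so the package ships a generative twin of
the data *structure*:

- **LD-structured genotypes.**  Haplotypes arise from a Gaussian copula:
  within a block, latent normals share an exchangeable correlation and are
  thresholded at the block's allele frequency.  The latent correlation is
  calibrated numerically (1-D Gaussian quadrature plus root-finding) so
  that the *binary allele* correlation — not the latent one — matches the
  requested `within_block_corr`; one minor-allele frequency is drawn per
  block because a shared frequency is what makes a high allele correlation
  attainable after thresholding (and tightly linked variants do have
  near-identical frequencies).  Blocks are independent, so clumping is
  non-trivial but between-block r² is near zero.  Variant ref/alt labels
  avoid complementary (A/T, C/G) pairs, as in a QC'd imputation panel;
  strand-ambiguous handling in `harmonize_alleles()` is exercised on
  constructed fixtures instead.
- **Sparse cis-eQTL architecture.**  Expression is
  $\sqrt{h^2}\,g + \sqrt{1-h^2}\,\varepsilon$ with $g$ the standardized
  weighted dosage of the causal variants, so the cis-heritability $h^2$ is
  exact by construction.  External summary statistics come from marginal
  regressions in an *independently simulated* panel (default
  $n = 31{,}684$, a consortium-scale size), one record per cis variant
  with explicit effect alleles.
- **CHIP carriers.**  Carrier status is drawn so the composite prevalence
  is 6.2%; carriers receive one driver (92.6%) or two (7.4%) with gene
  shares DNMT3A 55.4%, TET2 19.9%, ASXL1 9.1%, JAK2 1.0%, the remainder
  split across SRSF2/SF3B1/TP53/PPM1D.  VAFs follow Beta distributions
  truncated to (0.02, 1]: Beta(1, 6) by default (~60% large clones), and
  Beta(3, 6.65) for JAK2, solved so that 97.2% of JAK2 carriers exceed the
  10% large-clone threshold — reflecting the clonal dominance typical of
  JAK2-mutant hematopoiesis.  JAK2 calls are labelled p.V617F with
  probability 89.5%.
- **Covariates and outcomes.**  Age ~ N(56.3, 8.1), 44.4% male, BMI ~
  N(27.4, 4.8), and binary smoking/diabetes/ancestry with standard-normal
  PCs.  Event times are exponential with rate
  $\lambda_0 \exp(\text{lp})$; the linear predictor sums covariate,
  CHIP, score and CHIP×score log-hazards (continuous covariates centered).
  The default baseline rate (0.005 per person-year over a 12-year
  horizon) was chosen so that, averaging over the default covariate
  effects, the cohort cumulative event fraction is ≈ 10.6%; independent
  exponential censoring (rate 0.004/year) loses ≈ 5% to follow-up.
  Default planted effects are a composite-CHIP log-hazard of log(1.18) and
  a carrier-only interaction of log(1.85) between composite CHIP and the
  first simulated gene's score.

Every generator draws from a stream derived from one master seed
(`fan_seed`), so a cohort is byte-reproducible from a single integer.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: realistic recombination maps or admixture
(LD is blockwise-exchangeable, not decaying); age-dependent CHIP
acquisition (an age term is deliberately absent by default); clonal
dynamics over time; confounding between covariates and CHIP beyond what
the user plants; sequencing error in VAFs; and non-proportional hazards.

## Numerical choices

- **P-value underflow.**  At consortium-scale $n$, association P values
  underflow double precision to exactly 0, which would make the clumping
  order (smallest P first) degenerate among a causal variant and its
  proxies.  Summary statistics therefore carry a natural-log P column
  (`log_pvalue`) computed on the log scale; `clump()` ranks on it when
  present, and the linear P is floored at the smallest positive double so
  it stays within its contractual (0, 1] range.  The positional tie-break
  (lower chrom:pos) applies only to genuine ties.
- **Tie-breaks.**  Clumping orders by (P, chromosome, position);
  tuning ties on equal r² resolve to the earlier configuration in grid
  enumeration order.  Both make results independent of input row order.
- **Strictness.**  The score's threshold indicator is strict
  ($p_j < p_r$), as are the 1% retention rule, the 2% VAF rule and the
  10% large-clone rule.
- **Standardization.**  Scores, residualized expression and transformed
  traits use the population (divide-by-n) standard deviation; with the
  cohort sizes involved the distinction from the sample SD is
  inconsequential, but one convention must be fixed for exact
  reproducibility.  Scores can be standardized per stratum by passing the
  stratum ids as the `population`.
- **Clumping precedes thresholding.**  The indicator is applied inside
  the clumped set; the reverse order would change which proxies survive.
- **Degenerate cases.**  A score with no passing variants is an all-zero
  vector flagged degenerate; degenerate scores evaluate to r² = 0 and are
  never selected; constant traits are skipped with a note; monomorphic
  variants have undefined r² and are treated as r² = 0 by clumping (they
  can tag nothing).
- **Missing dosages** are mean-imputed per variant from the cohort.
- **Cox fitting** uses the Efron approximation for ties; non-convergence
  and separation (runaway coefficients) are flagged and the affected pair
  is excluded downstream with its reason recorded.

## Open design points and how they were resolved

- **"Adjusted variance" in tuning.**  The adjustment behind the tuning
  r² is implemented as linear residualization of expression on supplied
  covariates (re-standardized), with the covariate set configurable —
  the exact covariates used on the real tuning cohorts are not
  recoverable, so the default is the structure (age, sex) the validation
  sets carry.
- **Carry-forward reading.**  "Associated only in the presence of CHIP"
  is read as the two-clause rule (significant among carriers AND
  non-significant among non-carriers), with `rule = "one_clause"`
  available for the weaker reading.
- **Trait associations.**  Quantitative traits are analyzed with linear
  models on the log2-standardized trait (CRP offset +1 before the log);
  a rank-based "all-events proportional-hazards" reading is selectable
  (`method = "cox"`) but is not the default, since a hazard model has no
  natural meaning for a cross-sectional trait.
- **FDR family.**  The primary interaction FDR is computed within the
  carried-forward pairs (configurable to all tested pairs).
- **PRS-CS-style scores** are not reimplemented; tuning accepts any named
  list of candidate score vectors, so externally computed posterior-weight
  scores (e.g. from a continuous-shrinkage method with global shrinkage
  grid $10^{-6}, 10^{-4}, 10^{-2}, 1$) can compete in selection as
  plug-ins.
- **Ancestry.**  One LD reference per run; scores can be standardized per
  ancestry stratum via `standardize_score(population = ...)`.

## Problem sizes used by the test suite

The suite favors the smallest sizes at which each property is decidable:
definition oracles run on ≤ 12-variant instances (1,000 each for clumping
and scoring; 10,000 for the FDR step-up); calibration uses 1,000 null
replicates at n = 20,000 with 5% carriers and ~10% events for the
interaction test's type-I error, and 200 replicates for CI coverage of
planted log-hazards; tuning recovery uses an external panel of 30,000 and
a validation cohort of 5,000 for an $h^2 = 0.35$ gene; and the end-to-end
pipeline is exercised on 50 seeded cohorts of 10,000.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(n = 10000, seed = 7)
res <- run_pipeline(cohort)
res$tuning
subset(res$scan, carried_forward,
       select = c(chip_variable, gene, hr_present, p_present, p_absent,
                  interaction_z, interaction_q))
```

The planted pair (composite CHIP × the first gene) should be carried
forward with a strongly positive interaction z; null genes should show
stratified P values consistent with no effect.

## Limitations

Hazard ratios estimated on synthetic cohorts characterize the *procedure*
(calibration, power, coverage), not any real population.  The pipeline
performs no proportional-hazards diagnostics beyond convergence flags, no
competing-risks modelling, and no germline/artifact filtering of somatic
calls — inputs are assumed to be post-QC.  Sensitivity analyses with an
alternative endpoint are supported only by passing a different outcome
column.
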