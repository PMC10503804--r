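#' Simulate a complete synthetic biobank cohort
#'
#' Generates every input the modifier-scan pipeline consumes, under one
#' master seed: per-gene LD regions with an LD reference panel, external
#' cis-eQTL summary statistics from an independently simulated consortium
#' panel, two independent expression-tuning cohorts (a whole-blood-like and
#' a PBMC-like set with their own genotypes, expression and nuisance
#' covariates), CHIP driver calls with realistic clone sizes, baseline
#' covariates, and survival outcomes with planted CHIP and CHIP-by-score
#' interaction log-hazards acting on the true (generative) standardized
#' genetic score of each gene.
#'
#' @param n target-cohort size.
#' @param genes named numeric vector of cis heritabilities, one per gene;
#'   each gene gets its own chromosome-like LD region.
#' @param seed master seed; all generators draw from streams derived
#'   from it.
#' @param n_reference LD reference panel individuals (1000-Genomes-like).
#' @param n_external external eQTL panel size (consortium-like).
#' @param n_validation named sizes of the two expression-tuning cohorts.
#' @param n_causal causal cis variants per gene.
#' @param ld ld-region shape parameters passed to [ld_block_spec()]
#'   (`n_blocks`, `block_size`, `within_block_corr`, `maf_range`).
#' @param prevalences,vaf_shapes CHIP generator settings
#'   (see [simulate_chip_status()]).
#' @param model a [survival_model_spec()]; the default plants a composite
#'   CHIP log-hazard of log(1.18) and a carrier-only interaction of
#'   log(1.85) between the composite CHIP indicator and the first gene's
#'   score.
#' @param include_traits also simulate null quantitative traits (31
#'   hematologic + 5 cardiometabolic) for the exploratory trait scan.
#' @return a list of class `synthetic_cohort`; see Details.
#' @details The returned list holds `per_gene` (for each gene: `ld_spec`,
#'   `arch`, `reference`, `sumstats`, `genotypes`), `validation` (per
#'   cohort: `genotypes` per gene, `expression` per gene, `covariates`),
#'   `chip_calls`, `pheno` (covariates + `follow_time` + `event`),
#'   optional `traits`, and `truth` (generative genetic scores, carrier
#'   table, the survival model, and the master seed).
#' @export
simulate_cohort <- function(n = 10000,
                            genes = c(AIM2 = 0.35, IL6R = 0.15,
                                      IL1RAP = 0.10),
                            seed = 1,
                            n_reference = 500,
                            n_external = 31684,
                            n_validation = c(whole_blood = 800, pbmc = 400),
                            n_causal = 1,
                            ld = list(n_blocks = 5, block_size = 10,
                                      within_block_corr = 0.9,
                                      maf_range = c(0.1, 0.5)),
                            prevalences = chip_default_prevalences(),
                            vaf_shapes = chip_default_vaf_shapes(),
                            model = NULL,
                            include_traits = FALSE) {
  assert_that(!is.null(names(genes)) && all(nzchar(names(genes))),
              "genes must be a named h2 vector")
  if (is.null(model)) {
    model <- survival_model_spec(
      chip_log_hazards = c(has_chip = log(1.18)),
      interaction_log_hazards = stats::setNames(
        log(1.85), paste0("has_chip:", names(genes)[1])))
  }
  gene_names <- names(genes)
  per_gene <- list()
  truth_scores <- data.frame(sample_id = paste0("S", seq_len(n)),
                             stringsAsFactors = FALSE)
  validation <- lapply(names(n_validation), function(v)
    list(genotypes = list(), expression = list()))
  names(validation) <- names(n_validation)

  for (gi in seq_along(gene_names)) {
    g <- gene_names[gi]
    gseed <- fan_seed(seed, 100L + gi)
    spec <- ld_block_spec(n_blocks = ld$n_blocks, block_size = ld$block_size,
                          within_block_corr = ld$within_block_corr,
                          maf_range = ld$maf_range,
                          chrom = as.character(gi))
    names(spec$tss) <- g
    # causal variants: the mid-block variants nearest the TSS
    m <- length(spec$positions)
    ref <- simulate_ld_panel(spec, 2L * n_reference, seed = fan_seed(gseed, 1L))
    near <- order(abs(spec$positions - spec$tss))[seq_len(n_causal)]
    causal_ids <- ref$variants$variant_id[near]
    effects <- rep(1, n_causal)
    if (n_causal > 1) {
      set.seed(fan_seed(gseed, 2L))
      effects <- stats::rnorm(n_causal)
    }
    arch <- eqtl_architecture(g, causal_ids, effects, h2 = unname(genes[gi]),
                              tss = spec$tss)
    sumstats <- simulate_external_sumstats(spec, arch, n_external,
                                           seed = fan_seed(gseed, 3L))
    geno <- simulate_ld_panel(spec, 2L * n, seed = fan_seed(gseed, 4L))
    geno$sample_ids <- rownames(geno$dosages) <- truth_scores$sample_id
    truth_scores[[g]] <- genetic_value(geno, arch)
    per_gene[[g]] <- list(ld_spec = spec, arch = arch, reference = ref,
                          sumstats = sumstats, genotypes = geno)
    for (vi in seq_along(n_validation)) {
      v <- names(n_validation)[vi]
      vg <- simulate_ld_panel(spec, 2L * n_validation[[vi]],
                              seed = fan_seed(gseed, 10L + vi))
      vids <- paste0(toupper(substr(v, 1, 2)), seq_len(n_validation[[vi]]))
      vg$sample_ids <- rownames(vg$dosages) <- vids
      validation[[v]]$genotypes[[g]] <- vg
      validation[[v]]$expression[[g]] <-
        simulate_expression(vg, arch, seed = fan_seed(gseed, 20L + vi))
    }
  }
  for (v in names(validation)) {
    ids <- validation[[v]]$genotypes[[1]]$sample_ids
    set.seed(fan_seed(seed, 500L + match(v, names(validation))))
    validation[[v]]$covariates <- data.frame(
      sample_id = ids,
      age = stats::rnorm(length(ids), 60, 9),
      sex = stats::rbinom(length(ids), 1, 0.5),
      stringsAsFactors = FALSE)
  }

  covariates <- simulate_covariates(n, seed = fan_seed(seed, 7L))
  chip_calls <- simulate_chip_status(n, prevalences = prevalences,
                                     vaf_shapes = vaf_shapes,
                                     seed = fan_seed(seed, 8L),
                                     sample_ids = covariates$sample_id)
  chip_truth <- derive_chip_variables(chip_calls, covariates$sample_id)
  outcomes <- simulate_survival(covariates, chip_truth, truth_scores,
                                model = model, seed = fan_seed(seed, 9L))
  pheno <- merge(covariates, outcomes, by = "sample_id", sort = FALSE)

  traits <- NULL
  if (include_traits) {
    traits <- simulate_null_traits(covariates$sample_id,
                                   seed = fan_seed(seed, 13L))
  }
  structure(list(per_gene = per_gene, validation = validation,
                 chip_calls = chip_calls, pheno = pheno, traits = traits,
                 truth = list(scores = truth_scores,
                              chip_vars = chip_truth,
                              model = model, seed = seed)),
            class = "synthetic_cohort")
}

#' Simulate null quantitative traits
#'
#' 31 hematologic indexes and 5 cardiometabolic biomarkers drawn as
#' positive log-normal measurements with no dependence on genotype, CHIP
#' or outcome -- a pure-noise bed for calibrating the exploratory trait
#' scan.  CRP-like traits may contain exact zeros, which is why the scan
#' applies a +1 offset before the log transform.
#'
#' @param sample_ids cohort sample ids.
#' @param seed integer seed.
#' @return list with `traits` (data.frame `sample_id` + 36 columns),
#'   `families` (named list: `hematologic` 31 names, `cardiometabolic` 5),
#'   and `offsets` (named offsets, `crp = 1`).
#' @export
simulate_null_traits <- function(sample_ids, seed = 1) {
  set.seed(fan_seed(seed, 71L))
  n <- length(sample_ids)
  hem <- paste0("hem_", sprintf("%02d", 1:31))
  card <- c("crp", "total_chol", "hdl", "ldl", "triglycerides")
  traits <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (h in hem) traits[[h]] <- stats::rlnorm(n, meanlog = 1, sdlog = 0.4)
  traits$crp <- round(stats::rlnorm(n, meanlog = 0.3, sdlog = 1) - 0.3, 1)
  traits$crp[traits$crp < 0] <- 0
  for (b in card[-1]) traits[[b]] <- stats::rlnorm(n, 1.4, 0.25)
  list(traits = traits,
       families = list(hematologic = hem, cardiometabolic = card),
       offsets = c(crp = 1))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> n = %d, genes: %s, CHIP carriers: %d, events: %d\n",
    nrow(x$pheno), paste(names(x$per_gene), collapse = ", "),
    sum(x$truth$chip_vars$has_chip), sum(x$pheno$event)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- do.call(rbind, lapply(cohort$per_gene, `[[`, "sumstats"))
  write_sumstats(ss, file.path(dir, "sumstats.tsv"))
  for (g in names(cohort$per_gene)) {
    write_dosage_tsv(cohort$per_gene[[g]]$reference,
                     file.path(dir, paste0("reference_", g, ".tsv")))
    write_dosage_tsv(cohort$per_gene[[g]]$genotypes,
                     file.path(dir, paste0("genotypes_", g, ".tsv")))
  }
  for (v in names(cohort$validation)) {
    for (g in names(cohort$validation[[v]]$expression)) {
      write_expression(cohort$validation[[v]]$expression[[g]],
                       file.path(dir, paste0("expression_", v, "_", g, ".tsv")))
      write_dosage_tsv(cohort$validation[[v]]$genotypes[[g]],
                       file.path(dir, paste0("genotypes_", v, "_", g, ".tsv")))
    }
    write_table_tsv(cohort$validation[[v]]$covariates,
                    file.path(dir, paste0("covariates_", v, ".tsv")))
  }
  write_table_tsv(cohort$chip_calls, file.path(dir, "chip_calls.tsv"))
  write_table_tsv(cohort$pheno, file.path(dir, "phenotypes.tsv"))
  invisible(dir)
}
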