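#' Default configuration for the synthetic end-to-end pipeline
#'
#' Problem sizes are chosen so the whole chain (probe-level simulation,
#' chip-definition build, quantification, phenotyping, association,
#' meta-analysis, intervention layer) runs in minutes on one CPU while
#' keeping enough power for the planted signal to be recoverable.
#'
#' @param n_genes Genes on the synthetic chip (default 400).
#' @param n_cohorts Baseline cohorts (default 6).
#' @param n_subjects Per-cohort size range (default 60--90).
#' @param frac_is_genes,effect_r Planted IS-gene fraction and correlation
#'   (defaults 0.10 and 0.4).
#' @param fdr_threshold CORE-IS FDR cutoff (default 0.10).
#' @param n_intervention_subjects,n_intervention_studies Intervention design
#'   (defaults 40 and 4).
#' @param delta_rho Planted delta coupling (default 0.5).
#' @param probe_level Simulate at probe level and run the chip-definition /
#'   quantification stages (default TRUE); FALSE skips to expression level.
#' @param ... Overrides passed to [chip_design()], [cohort_params()] or
#'   [intervention_params()] via the returned list.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(n_genes = 400L, n_cohorts = 6L,
                            n_subjects = c(60L, 90L), frac_is_genes = 0.10,
                            effect_r = 0.4, fdr_threshold = 0.10,
                            n_intervention_subjects = 40L,
                            n_intervention_studies = 4L, delta_rho = 0.5,
                            probe_level = TRUE, ...) {
  c(list(n_genes = n_genes, n_cohorts = n_cohorts, n_subjects = n_subjects,
         frac_is_genes = frac_is_genes, effect_r = effect_r,
         fdr_threshold = fdr_threshold,
         n_intervention_subjects = n_intervention_subjects,
         n_intervention_studies = n_intervention_studies,
         delta_rho = delta_rho, probe_level = probe_level),
    list(...))
}

#' Run the full synthetic discovery-and-validation pipeline
#'
#' Chains every stage: simulate baseline cohorts (planted truth), optionally
#' re-express each cohort at probe level and recover expression through the
#' probe-filter cascade, chip-definition assembly, quantile normalization,
#' median-polish summarization, NUSE QC and gene collapse; phenotype each
#' cohort (HOMA stand-in, operating-range exclusion); associate expression
#' with IS per cohort (sequential bivariate ANOVA); meta-analyse across
#' cohorts into the CORE-IS table; simulate paired interventions and run the
#' delta layer against the *estimated* CORE-IS genes. A provenance record of
#' every stage's parameters, seeds and counts is returned (and written to
#' `out_dir` along with the main TSV tables when given).
#'
#' @param config List from [pipeline_config()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return List: `core_is` (meta gene table), `delta` (delta-layer results),
#'   `truth` (planted gene truth), `delta_truth`, `cohorts` (per-cohort
#'   expression/phenotype actually analysed), `nuse` (per-cohort QC, when
#'   probe-level), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stage_seed <- function(k) {
    as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647)
  }
  prov <- list(master_seed = seed, config = config,
               package_version = as.character(utils::packageVersion("coreis")),
               stages = list())

  cp <- cohort_params(n_cohorts = config$n_cohorts,
                      n_subjects = config$n_subjects,
                      n_genes = config$n_genes,
                      frac_is_genes = config$frac_is_genes,
                      effect_r = config$effect_r,
                      seed = stage_seed(1L))
  sim <- simulate_cohorts(cp)
  prov$stages$simulate <- list(seed = cp$seed, n_genes = cp$n_genes,
                               n_cohorts = cp$n_cohorts,
                               n_planted = sum(sim$truth$is_planted))

  nuse_reports <- list()
  cohorts <- vector("list", length(sim$cohorts))
  for (k in seq_along(sim$cohorts)) {
    co <- sim$cohorts[[k]]
    if (isTRUE(config$probe_level)) {
      design <- chip_design(n_genes = config$n_genes)
      chip <- simulate_chip(design, 2^co$expression, seed = stage_seed(100L + k))
      cdf <- build_chip_definition(chip$intensities, chip$annotation)
      quant <- quantify_chip(chip$intensities, cdf)
      qc <- nuse_qc(quant$residuals)
      nuse_reports[[co$study_id]] <- qc
      expr <- quant$expression[, !qc$outlier, drop = FALSE]
      expr <- collapse_by_gene(expr, chip$gene_map)
      prov$stages[[paste0("quantify_", co$study_id)]] <- list(
        seed = stage_seed(100L + k),
        n_probes = nrow(chip$intensities),
        n_probesets = length(cdf$probesets),
        n_outlier_arrays = sum(qc$outlier))
    } else {
      expr <- co$expression
    }
    pheno <- add_insulin_sensitivity(co$phenotype)
    cohorts[[k]] <- list(study_id = co$study_id, expression = expr,
                         phenotype = pheno)
  }
  names(cohorts) <- vapply(cohorts, `[[`, "", "study_id")

  assoc <- lapply(cohorts, function(co) {
    associate_study(co$expression, co$phenotype)
  })
  core <- assemble_core_is(assoc, fdr_threshold = config$fdr_threshold)
  prov$stages$meta <- list(
    fdr_threshold = config$fdr_threshold,
    required_studies = attr(core, "required_studies"),
    n_genes_meta = nrow(core), n_core_is = sum(core$core_is))

  ip <- intervention_params(n_subjects = config$n_intervention_subjects,
                            n_studies = config$n_intervention_studies,
                            delta_rho = config$delta_rho,
                            seed = stage_seed(2L))
  intv <- simulate_intervention(ip, sim$truth, baseline = sim$baseline)
  core_genes <- core[core$core_is, c("gene_id", "direction")]
  delta <- NULL
  if (nrow(core_genes) > 0L) {
    delta <- delta_analysis(intv$studies, core_genes)
    prov$stages$delta <- list(seed = ip$seed, n_core_tested = nrow(core_genes),
                              n_selected = length(delta$selected),
                              p_tail = delta$binomial$p_tail)
  } else {
    prov$stages$delta <- list(seed = ip$seed, n_core_tested = 0L,
                              note = "no CORE-IS genes; delta layer skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(core, file.path(out_dir, "core_is.tsv"))
    write_table_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
    if (!is.null(delta)) {
      dd <- data.frame(gene_id = rownames(delta$rho), delta$rho,
                       selected = rownames(delta$rho) %in% delta$selected,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_table_tsv(dd, file.path(out_dir, "delta.tsv"))
      jsonlite::write_json(as.list(delta$binomial),
                           file.path(out_dir, "delta_binomial.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(core_is = core, delta = delta, truth = sim$truth,
       delta_truth = intv$truth, cohorts = cohorts,
       nuse = if (length(nuse_reports)) nuse_reports else NULL,
       provenance = prov)
}
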