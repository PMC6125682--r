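#!/usr/bin/env Rscript
# Stage 3: how covariate ordering changes the IS gene list.
#
# In a sequential (Type I) ANOVA the variance shared between IS and a
# coupled covariate is credited to whichever variable enters the model
# first. With BMI coupled to IS (r = -0.4) and a continuum of weak planted
# effects, putting BMI first systematically costs significant genes.

suppressMessages(library(coreis))

seed <- 20260920L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

n_reps <- 12L
counts <- t(vapply(seq_len(n_reps), function(i) {
  params <- cohort_params(n_genes = 1000L, n_cohorts = 6L,
                          n_subjects = c(80L, 190L), frac_is_genes = 0.15,
                          effect_r = c(0.05, 0.25), bmi_is_coupling = -0.4,
                          seed = seed + i)
  sim <- simulate_cohorts(params)
  assoc <- lapply(sim$cohorts, function(co) {
    ph <- suppressMessages(add_insulin_sensitivity(co$phenotype))
    associate_study(co$expression, ph)
  })
  names(assoc) <- vapply(sim$cohorts, `[[`, "", "study_id")
  is_first <- assemble_core_is(assoc, fdr_threshold = 0.10)
  cov_first <- assemble_core_is(assoc, fdr_threshold = 0.10, order = "cov_first")
  c(is_first = sum(is_first$q_bmi < 0.10),
    cov_first = sum(cov_first$q_bmi < 0.10))
}, c(is_first = 0, cov_first = 0)))

df <- data.frame(replicate = seq_len(n_reps), counts)
print(df, row.names = FALSE)
cat(sprintf("\ngenes at FDR < 10%%: mean %.1f (IS first) vs %.1f (BMI first); BMI-first lower in %d/%d replicates\n",
            mean(df$is_first), mean(df$cov_first),
            sum(df$cov_first < df$is_first), n_reps))
write_table_tsv(df, file.path(out_dir, "order_effect.tsv"))
cat("wrote results/order_effect.tsv\n")
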