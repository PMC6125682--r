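# Shared driver: simulate baseline cohorts at expression level, associate
# each cohort, and assemble the meta-analytic gene table. Used by the
# calibration, recovery and order-effect tests and mirrored by
# scripts/acceptance.R.
run_discovery <- function(params, fdr_threshold = 0.10,
                          order = "is_first") {
  sim <- simulate_cohorts(params)
  assoc <- lapply(sim$cohorts, function(co) {
    ph <- suppressMessages(add_insulin_sensitivity(co$phenotype))
    associate_study(co$expression, ph)
  })
  names(assoc) <- vapply(sim$cohorts, `[[`, "", "study_id")
  core <- assemble_core_is(assoc, fdr_threshold = fdr_threshold, order = order)
  list(sim = sim, assoc = assoc, core = core)
}
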