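test_that("chip simulation is deterministic and respects a clean design", {
  set.seed(1)
  ab <- matrix(2^runif(50 * 10, 6, 10), 50, 10)
  clean <- chip_design(50, frac_dead_probes = 0, frac_multimap_probes = 0,
                       frac_gc_extreme = 0)
  chip <- simulate_chip(clean, ab, seed = 9)
  expect_true(all(chip$annotation$map_count == 1L))
  expect_true(all(chip$annotation$gc_fraction >= 0.20 &
                    chip$annotation$gc_fraction <= 0.80))
  expect_false(any(chip$probe_truth$dead))
  # identical (design, abundance, seed) => identical output
  chip2 <- simulate_chip(clean, ab, seed = 9)
  expect_identical(chip, chip2)
  expect_false(identical(chip$intensities,
                         simulate_chip(clean, ab, seed = 10)$intensities))
  expect_error(simulate_chip(clean, -ab, seed = 1), "positive")
})

test_that("planted dead probes sit below the signal floor", {
  set.seed(2)
  ab <- matrix(2^runif(100 * 50, 6, 12), 100, 50)
  design <- chip_design(100, frac_dead_probes = 0.2)
  below <- replicate(20, {
    chip <- simulate_chip(design, ab, seed = sample.int(1e6, 1))
    dead <- chip$probe_truth$dead
    mean(rowMeans(chip$intensities[dead, , drop = FALSE]) < 10)
  })
  # the generator is calibrated so dead-probe means fall under the 10-unit
  # floor essentially always at 50 samples
  expect_gte(mean(below), 0.99)
})

test_that("cohort generator is reproducible and honours stated ranges", {
  p <- cohort_params(n_cohorts = 3, n_subjects = c(50, 80), n_genes = 60,
                     seed = 33)
  s1 <- simulate_cohorts(p)
  s2 <- simulate_cohorts(p)
  expect_identical(s1, s2)
  for (co in s1$cohorts) {
    ph <- co$phenotype
    expect_true(all(ph$fasting_insulin >= 20 & ph$fasting_insulin <= 400))
    expect_true(all(ph$fasting_glucose >= 4.0 & ph$fasting_glucose <= 6.5))
    expect_true(all(ph$bmi >= 19 & ph$bmi <= 45))
    # the phenotype module reproduces the planted IS values inside range
    expect_true(all(suppressMessages(
      add_insulin_sensitivity(ph))$valid))
  }
  # truth covers every gene with directions in {-1, 0, +1}
  expect_identical(s1$truth$gene_id, rownames(s1$cohorts[[1]]$expression))
  expect_true(all(s1$truth$true_direction %in% c(-1L, 0L, 1L)))
})

test_that("planted correlations hit the target effect size", {
  hits <- vapply(1:100, function(i) {
    p <- cohort_params(n_cohorts = 1, n_subjects = 200L, n_genes = 12,
                       frac_is_genes = 0.5, effect_r = 0.5, sign_mix = 0,
                       seed = 1000 + i)
    sim <- simulate_cohorts(p)
    co <- sim$cohorts[[1]]
    is_log <- suppressMessages(add_insulin_sensitivity(co$phenotype))$is_log
    g <- sim$truth$gene_id[sim$truth$is_planted][1]
    r <- cor(co$expression[g, ], is_log)
    abs(r - 0.5) <= 0.15
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("sign_mix = 1 plants only negative directions", {
  p <- cohort_params(n_cohorts = 1, n_subjects = 50L, n_genes = 40,
                     frac_is_genes = 0.25, sign_mix = 1, seed = 5)
  sim <- simulate_cohorts(p)
  expect_true(all(sim$truth$true_direction[sim$truth$is_planted] == -1L))
  # BMI couples negatively with IS by default
  co <- sim$cohorts[[1]]
  is_log <- suppressMessages(add_insulin_sensitivity(co$phenotype))$is_log
  expect_lt(cor(co$phenotype$bmi, is_log), 0)
})

test_that("with no planted genes the IS term p-values are uniform", {
  p <- cohort_params(n_cohorts = 1, n_subjects = 150L, n_genes = 2000,
                     frac_is_genes = 0, seed = 77)
  sim <- simulate_cohorts(p)
  co <- sim$cohorts[[1]]
  ph <- suppressMessages(add_insulin_sensitivity(co$phenotype))
  scan <- fit_bivariate_scan(co$expression, ph$is_log, ph$age, "is_first")
  ks <- suppressWarnings(stats::ks.test(scan$p_is, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("intervention studies share truth but not noise, and recover the planted rho", {
  truth <- data.frame(gene_id = sprintf("G%03d", 1:50),
                      true_direction = rep(c(-1L, 1L, 0L), c(15, 15, 20)))
  p <- intervention_params(n_subjects = 50L, n_studies = 4L,
                           frac_delta_genes = 0.4, delta_rho = 0.9, seed = 8)
  iv <- simulate_intervention(p, truth)
  expect_length(iv$studies, 4L)
  expect_identical(simulate_intervention(p, truth)$truth, iv$truth)
  fc1 <- iv$studies[[1]]$post - iv$studies[[1]]$pre
  fc2 <- iv$studies[[2]]$post - iv$studies[[2]]$pre
  expect_false(identical(unname(fc1), unname(fc2)))
  # planted genes track delta IS strongly at rho = 0.9, n = 50
  hits <- vapply(1:40, function(i) {
    pp <- intervention_params(n_subjects = 50L, n_studies = 1L,
                              frac_delta_genes = 0.4, delta_rho = 0.9,
                              seed = 100 + i)
    ivi <- simulate_intervention(pp, truth)
    st <- ivi$studies[[1]]
    g <- which(ivi$truth$is_delta_planted)[1]
    fc <- (st$post - st$pre)[g, ]
    dirg <- ivi$truth$expected_direction[g]
    cor(fc, st$delta_is, method = "spearman") * dirg > 0.6
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("planted directions are recoverable from sample correlations", {
  p <- cohort_params(n_cohorts = 1, n_subjects = 160L, n_genes = 400,
                     frac_is_genes = 0.25, effect_r = 0.3, seed = 91)
  sim <- simulate_cohorts(p)
  co <- sim$cohorts[[1]]
  is_log <- suppressMessages(add_insulin_sensitivity(co$phenotype))$is_log
  r <- univariate_r(co$expression, is_log)
  planted <- sim$truth$is_planted
  agree <- sign(r[planted]) == sim$truth$true_direction[planted]
  expect_gte(mean(agree), 0.90)
})
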