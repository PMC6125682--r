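paired_fixture <- function(d_rows) {
  n <- ncol(d_rows)
  pre <- matrix(8, nrow(d_rows), n,
                dimnames = list(rownames(d_rows), sprintf("s%02d", 1:n)))
  list(pre = pre, post = pre + d_rows)
}

test_that("paired differential expression matches the t-test and flags degeneracy", {
  d <- rbind(g1 = c(0.5, 0.7, 0.3, 0.9, 0.6),
             g2 = rep(0, 5),
             g3 = rep(1, 5))
  fx <- paired_fixture(d)
  de <- paired_de(fx$pre, fx$post)
  tt <- t.test(d["g1", ])
  expect_equal(de$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(de$p[1], tt$p.value, tolerance = 1e-12)
  expect_equal(de$log2fc[1], 0.6)
  # no change and uniform change both have zero difference variance
  expect_true(de$degenerate[2])
  expect_true(de$degenerate[3])
  expect_equal(de$p[2:3], c(1, 1))
  expect_equal(de$log2fc[3], 1)
  expect_error(paired_de(fx$pre[, 1:2], fx$post[, 1:2]), "3 pairs")
})

test_that("DE meta-analysis reduces to BH for one study and gains power with more", {
  p1 <- setNames(c(0.01, 0.2, 0.8), paste0("g", 1:3))
  m1 <- de_meta(list(a = p1))
  expect_equal(m1$q_meta, bh_fdr(p1), ignore_attr = TRUE)
  # identical evidence across 4 studies beats any single study (p < 0.5)
  m4 <- de_meta(list(a = p1, b = p1, c = p1, d = p1))
  expect_true(all(m4$p_meta[p1 < 0.5] < p1[p1 < 0.5]))
})

test_that("delta correlation is a rank statistic", {
  d_is <- c(0.1, 0.4, 0.2, 0.3)
  fc <- c(0.01, 0.5, 0.1, 0.2)  # strictly increasing with d_is in rank
  expect_equal(delta_correlation(fc, d_is), 1)
  # invariant to strictly monotone transforms
  expect_equal(delta_correlation(exp(fc), d_is), 1)
  set.seed(12)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(delta_correlation(x, y), spearman_bruteforce(x, y),
               tolerance = 1e-12)
  expect_true(is.na(delta_correlation(rep(1, 6), rnorm(6))))
  expect_error(delta_correlation(1:3, 1:3), "4 subjects")
})

test_that("consistency selection demands concordant strict signs in every study", {
  rho <- rbind(gA = c(0.3, 0.2, 0.4, 0.1),
               gB = c(0.3, 0.2, 0.4, -0.1),
               gC = c(0.3, 0.2, 0.4, 0),
               gD = c(-0.2, -0.4, -0.1, -0.3))
  dirs <- c(gA = 1, gB = 1, gC = 1, gD = -1)
  expect_setequal(select_consistent_genes(rho, dirs), c("gA", "gD"))
  # direction must match: a consistently positive gene expected negative fails
  dirs2 <- c(gA = -1, gB = 1, gC = 1, gD = -1)
  expect_setequal(select_consistent_genes(rho, dirs2), "gD")
  # optional magnitude threshold: both survivors have a weakest study at 0.1
  expect_length(select_consistent_genes(rho, dirs, min_abs_rho = 0.15), 0)
  expect_setequal(select_consistent_genes(rho, dirs, min_abs_rho = 0.1),
                  c("gA", "gD"))
  expect_error(select_consistent_genes(rho, dirs[1:2]), "missing")
})

test_that("binomial consistency tail matches exhaustive enumeration", {
  expect_equal(binomial_consistency_p(0, 10, 4)$p_tail, 1)
  expect_equal(binomial_consistency_p(2, 2, 1)$p_tail, 0.25)
  # brute force across all n <= 20 and several nulls
  for (p0 in c(0.5, 0.25, 0.0625)) {
    for (n in c(1, 5, 12, 20)) {
      for (k in 0:n) {
        expect_equal(binomial_consistency_p(k, n, 4, p0 = p0)$p_tail,
                     binom_tail_bruteforce(k, n, p0), tolerance = 1e-12)
      }
    }
  }
  # monotone: larger counts are more surprising, larger p0 less so
  pt <- vapply(0:20, function(k) binomial_consistency_p(k, 20, 4)$p_tail, 0)
  expect_true(all(diff(pt) < 0))
  p_by_null <- vapply(c(0.05, 0.1, 0.3, 0.6),
                      function(p0) binomial_consistency_p(5, 20, 4, p0)$p_tail, 0)
  expect_true(all(diff(p_by_null) > 0))
  expect_error(binomial_consistency_p(5, 20, 4, p0 = 0), "p0")
})

test_that("the delta layer recovers planted responders end to end", {
  truth <- data.frame(gene_id = sprintf("G%03d", 1:200),
                      true_direction = rep(c(-1L, 1L), 100))
  p <- intervention_params(n_subjects = 40L, n_studies = 4L,
                           frac_delta_genes = 0.25, delta_rho = 0.6, seed = 14)
  iv <- simulate_intervention(p, truth)
  core <- data.frame(gene_id = truth$gene_id, direction = truth$true_direction)
  res <- delta_analysis(iv$studies, core)
  planted <- iv$truth$gene_id[iv$truth$is_delta_planted]
  recall <- mean(planted %in% res$selected)
  precision <- mean(res$selected %in% planted)
  expect_gte(recall, 0.5)
  expect_gte(precision, 0.8)
  expect_lt(res$binomial$p_tail, 1e-6)
  expect_identical(res$binomial$n, length(truth$gene_id))
  # planted responders are also differentially expressed in the meta analysis
  expect_true(all(dim(res$rho) == c(200, 4)))
})
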