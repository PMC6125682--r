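test_that("sequential ANOVA matches the classical single-gene fit and handles degeneracy", {
  set.seed(3)
  n <- 30
  is_log <- rnorm(n, 1.8, 0.25)
  age <- 0.5 * scale(is_log)[, 1] + rnorm(n)
  y <- 1 + 0.8 * is_log + 0.1 * age + rnorm(n, sd = 0.5)
  fit <- fit_bivariate_model(y, is_log, age, "is_first")
  at <- anova(lm(y ~ is_log * age))
  expect_equal(fit$p_is, at[["Pr(>F)"]][1], tolerance = 1e-12)
  expect_equal(fit$p_interaction, at[["Pr(>F)"]][3], tolerance = 1e-12)
  # perfect fit: residual SS 0, degenerate flag, p reported as 0
  y_exact <- 2 * is_log
  fit2 <- fit_bivariate_model(y_exact, is_log, age)
  expect_true(fit2$degenerate)
  expect_equal(fit2$p_is, 0)
  # zero-variance response
  fit3 <- fit_bivariate_model(rep(1, n), is_log, age)
  expect_true(fit3$degenerate)
  expect_equal(fit3$p_is, 1)
  expect_error(fit_bivariate_model(y, is_log, is_log * 2), "collinear")
})

test_that("order does not matter when IS and covariate are orthogonal", {
  # build an exactly orthogonal covariate
  set.seed(4)
  n <- 24
  is_log <- rnorm(n)
  cov_raw <- rnorm(n)
  covar <- residuals(lm(cov_raw ~ is_log))  # sample correlation exactly 0
  y <- 0.5 * is_log + rnorm(n)
  f1 <- fit_bivariate_model(y, is_log, covar, "is_first")
  f2 <- fit_bivariate_model(y, is_log, covar, "cov_first")
  expect_equal(f1$p_is, f2$p_is, tolerance = 1e-10)
})

test_that("the genome-wide scan agrees with per-gene fits and the brute-force oracle", {
  set.seed(6)
  n <- 8
  reps <- 200
  for (i in seq_len(reps)) {
    is_log <- rnorm(n)
    covar <- 0.4 * is_log + rnorm(n)
    y <- rnorm(n)
    oracle <- seq_anova_bruteforce(y, is_log, covar)  # p for x1, x2, x1:x2
    fit <- fit_bivariate_model(y, is_log, covar, "is_first")
    expect_equal(fit$p_is, oracle[1], tolerance = 1e-10)
    expect_equal(fit$p_cov, oracle[2], tolerance = 1e-10)
    expect_equal(fit$p_interaction, oracle[3], tolerance = 1e-10)
  }
  # matrix scan equals the single-gene path on a block of genes
  set.seed(7)
  n <- 40
  is_log <- rnorm(n)
  covar <- -0.4 * scale(is_log)[, 1] + rnorm(n)
  Y <- matrix(rnorm(50 * n), 50, n, dimnames = list(sprintf("g%02d", 1:50), NULL))
  for (ord in c("is_first", "cov_first")) {
    scan <- fit_bivariate_scan(Y, is_log, covar, ord)
    idx <- c(1, 17, 50)
    for (j in idx) {
      f <- fit_bivariate_model(Y[j, ], is_log, covar, ord)
      expect_equal(scan$p_is[j], f$p_is, tolerance = 1e-10)
      expect_equal(scan$p_interaction[j], f$p_interaction, tolerance = 1e-10)
    }
  }
})

test_that("univariate correlation behaves and matches hand computation", {
  x <- c(1, 2, 3)
  expect_equal(univariate_r(x, x), 1)
  expect_equal(univariate_r(-x + 10, x), -1)
  expect_equal(univariate_r(c(1, 2, 4), c(1, 2, 3)), 0.9820, tolerance = 1e-4)
  expect_true(is.na(univariate_r(c(1, 1, 1), x)))
})

test_that("Stouffer combination follows the closed form", {
  # single study is the identity
  expect_equal(stouffer_combine(0.2)$p, 0.2, tolerance = 1e-12)
  # two studies at p = 0.05: Z = sqrt(2) * z_{0.95}
  s <- stouffer_combine(c(0.05, 0.05))
  expect_equal(s$z, sqrt(2) * qnorm(0.95), tolerance = 1e-12)
  expect_equal(s$p, pnorm(sqrt(2) * qnorm(0.95), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(s$p, 4), 0.0100)
  # uninformative studies combine to nothing
  s5 <- stouffer_combine(rep(0.5, 4))
  expect_equal(s5$z, 0)
  expect_equal(s5$p, 0.5)
  # more agreeing studies, stronger meta evidence (for p < 0.5)
  ps <- vapply(1:6, function(k) stouffer_combine(rep(0.2, k))$p, 0)
  expect_true(all(diff(ps) < 0))
  # degenerate p-values are clamped with a warning
  expect_warning(out <- stouffer_combine(c(0, 0.5)), "clamped")
  expect_true(is.finite(out$z))
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-14)
  }
  expect_error(bh_fdr(numeric()), "empty")
})

test_that("directional consistency requires one strict sign in required studies", {
  r <- c(s1 = 0.21, s2 = 0.33, s3 = 0.12, s4 = 0.08)
  out <- directional_consistency(r)
  expect_true(out$consistent)
  expect_equal(out$direction, 1L)
  expect_false(directional_consistency(c(0.2, 0.3, -0.1, 0.2))$consistent)
  # a zero correlation is not a sign
  expect_false(directional_consistency(c(0, 0.3, 0.1, 0.2))$consistent)
  # only the required studies are consulted
  r2 <- c(s1 = -0.2, s2 = -0.3, s3 = 0.5, s4 = -0.1)
  out2 <- directional_consistency(r2, required_studies = c("s1", "s2", "s4"))
  expect_true(out2$consistent)
  expect_equal(out2$direction, -1L)
  expect_error(directional_consistency(r2, required_studies = "s9"), "missing")
})

test_that("CORE-IS assembly enforces FDR in both models plus directional filter", {
  p <- cohort_params(n_cohorts = 4, n_subjects = 120L, n_genes = 300,
                     frac_is_genes = 0.1, effect_r = 0.45, seed = 19)
  d <- run_discovery(p)
  core <- d$core
  expect_true(all(core$core_is == (core$q_age < 0.10 & core$q_bmi < 0.10 &
                                     core$consistent)))
  # a gene flagged CORE-IS must carry a nonzero direction
  expect_true(all(core$direction[core$core_is] != 0))
  # sign-flip in a required study disqualifies even meta-significant genes
  assoc <- d$assoc
  sel <- which(core$core_is)[1]
  gene <- core$gene_id[sel]
  req <- attr(core, "required_studies")[1]
  i <- match(gene, assoc[[req]]$gene_id)
  assoc[[req]]$r_is[i] <- -assoc[[req]]$r_is[i]
  core2 <- assemble_core_is(assoc, fdr_threshold = 0.10)
  expect_false(core2$core_is[core2$gene_id == gene])
  # either-model rule is weaker than the both-model rule
  core_either <- assemble_core_is(d$assoc, fdr_threshold = 0.10,
                                  both_models_required = FALSE)
  expect_gte(sum(core_either$core_is), sum(core$core_is))
})
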