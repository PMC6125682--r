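#' Sequential (Type I) bivariate ANOVA of one gene against IS and a covariate
#'
#' Fits the linear model `y ~ a*b` (main effects plus interaction) and
#' decomposes the variance sequentially via `anova(lm(...))`, exactly the
#' classical R call. With `order = "is_first"` the model is
#' `y ~ is_log * covariate`; with `"cov_first"` it is
#' `y ~ covariate * is_log`. When IS and the covariate are correlated the
#' p-value of the IS term depends on this order -- the shared variance is
#' credited to whichever variable enters first.
#'
#' @param y Numeric expression vector (log2) for one gene.
#' @param is_log Insulin-sensitivity phenotype (log10 S%).
#' @param covariate Covariate vector (age or BMI).
#' @param order `"is_first"` (default) or `"cov_first"`.
#' @return List with `p_is`, `p_cov`, `p_interaction`, `degenerate` (TRUE
#'   when y has zero variance, p's forced to 1, or the fit is numerically
#'   perfect, p_is reported as 0).
#' @export
fit_bivariate_model <- function(y, is_log, covariate,
                                order = c("is_first", "cov_first")) {
  order <- match.arg(order)
  n <- length(y)
  if (n < 5L) stop("need at least 5 observations for the 4-parameter model")
  if (!all(is.finite(y)) || !all(is.finite(is_log)) || !all(is.finite(covariate))) {
    stop("non-finite inputs")
  }
  if (abs(stats::cor(is_log, covariate)) > 0.999) {
    stop("covariate is collinear with IS")
  }
  if (stats::var(y) == 0) {
    return(list(p_is = 1, p_cov = 1, p_interaction = 1, degenerate = TRUE))
  }
  a <- if (order == "is_first") is_log else covariate
  b <- if (order == "is_first") covariate else is_log
  # perfect fits are detected and flagged below; silence the F-test caveat
  at <- suppressWarnings(stats::anova(stats::lm(y ~ a * b)))
  p <- at[["Pr(>F)"]][1:3]
  degenerate <- at["Residuals", "Sum Sq"] < 1e-12 * sum(at[["Sum Sq"]])
  if (degenerate) p[is.na(p)] <- 0
  is_pos <- if (order == "is_first") 1L else 2L
  cov_pos <- if (order == "is_first") 2L else 1L
  list(p_is = p[is_pos], p_cov = p[cov_pos], p_interaction = p[3L],
       degenerate = degenerate)
}

#' Genome-wide sequential-ANOVA scan
#'
#' Vectorised equivalent of [fit_bivariate_model()] for a gene-by-sample
#' matrix: the design matrix `[1, a, b, a:b]` is orthonormalised once (QR in
#' column order, which reproduces the sequential Type-I decomposition) and
#' every gene's term sums of squares are obtained by projection.
#'
#' @param Y Gene-by-sample log2 expression matrix.
#' @param is_log,covariate Phenotype vectors, length `ncol(Y)`.
#' @param order `"is_first"` or `"cov_first"`.
#' @return data.frame: `gene_id`, `p_is`, `p_cov`, `p_interaction`.
#' @export
fit_bivariate_scan <- function(Y, is_log, covariate,
                               order = c("is_first", "cov_first")) {
  order <- match.arg(order)
  stopifnot(is.matrix(Y), ncol(Y) == length(is_log),
            length(is_log) == length(covariate))
  n <- ncol(Y)
  if (n < 5L) stop("need at least 5 samples")
  a <- if (order == "is_first") is_log else covariate
  b <- if (order == "is_first") covariate else is_log
  X <- cbind(1, a, b, a * b)
  qx <- qr(X)
  if (qx$rank < 4L) stop("rank-deficient design (collinear IS/covariate)")
  Q <- qr.Q(qx)
  E <- Y %*% Q                              # genes x 4 sequential projections
  ss_term <- E[, 2:4, drop = FALSE]^2
  rss <- rowSums(Y^2) - rowSums(E^2)
  df_res <- n - 4L
  mse <- rss / df_res
  pvals <- matrix(NA_real_, nrow(Y), 3L)
  ok <- mse > 0
  for (j in 1:3) {
    pvals[ok, j] <- stats::pf(ss_term[ok, j] / mse[ok], 1L, df_res,
                              lower.tail = FALSE)
    pvals[!ok, j] <- 0
  }
  zero_var <- apply(Y, 1L, stats::var) == 0
  pvals[zero_var, ] <- 1
  is_pos <- if (order == "is_first") 1L else 2L
  cov_pos <- if (order == "is_first") 2L else 1L
  data.frame(gene_id = rownames(Y), p_is = pvals[, is_pos],
             p_cov = pvals[, cov_pos], p_interaction = pvals[, 3L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate Pearson correlation of each gene with IS
#'
#' @param Y Gene-by-sample matrix (or a single numeric vector).
#' @param is_log Phenotype vector.
#' @return Named numeric vector of correlations; `NA` for zero-variance
#'   genes.
#' @export
univariate_r <- function(Y, is_log) {
  if (!is.matrix(Y)) {
    if (length(Y) < 3L) stop("need at least 3 observations")
    if (stats::var(Y) == 0 || stats::var(is_log) == 0) return(NA_real_)
    return(stats::cor(Y, is_log))
  }
  sds <- apply(Y, 1L, stats::sd)
  r <- suppressWarnings(as.vector(stats::cor(t(Y), is_log)))
  r[sds == 0] <- NA_real_
  stats::setNames(r, rownames(Y))
}

#' Stouffer combination of per-study p-values
#'
#' Converts each one-sided p-value to a normal quantile
#' \eqn{z_i = \Phi^{-1}(1-p_i)} and combines \eqn{Z = \sum w_i z_i /
#' \sqrt{\sum w_i^2}} (unweighted by default), with
#' \eqn{p_{meta} = 1 - \Phi(Z)}. Degenerate p-values are clamped away from 0
#' and 1 with a warning.
#'
#' @param p Vector of per-study p-values in (0,1).
#' @param weights Optional positive weights (e.g. sqrt of sample sizes);
#'   default unweighted.
#' @return List with `z` and `p`.
#' @export
stouffer_combine <- function(p, weights = NULL) {
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  eps <- 1e-300
  if (any(p <= 0) || any(p >= 1)) {
    warning("p-values at 0 or 1 clamped for the normal-quantile transform")
    p <- pmin(pmax(p, eps), 1 - 1e-16)
  }
  w <- if (is.null(weights)) rep(1, length(p)) else weights
  z <- stats::qnorm(p, lower.tail = FALSE)
  Z <- sum(w * z) / sqrt(sum(w^2))
  list(z = Z, p = stats::pnorm(Z, lower.tail = FALSE))
}

# row-wise Stouffer over a gene x study p-value matrix
stouffer_rows <- function(P, weights = NULL) {
  P <- pmin(pmax(P, 1e-300), 1 - 1e-16)
  Zmat <- stats::qnorm(P, lower.tail = FALSE)
  w <- if (is.null(weights)) rep(1, ncol(P)) else weights
  Z <- as.vector(Zmat %*% w) / sqrt(sum(w^2))
  data.frame(z = Z, p = stats::pnorm(Z, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values, input order preserved.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-study directional consistency of the expression--IS correlation
#'
#' A gene is directionally consistent when its univariate correlation with IS
#' keeps one strict sign across every required study; a zero correlation in
#' any required study breaks consistency.
#'
#' @param r_by_study Numeric vector (one gene) or gene-by-study matrix of
#'   per-study correlations; columns named by study.
#' @param required_studies Character vector of study names that must agree
#'   (the largest cohorts, by design).
#' @return For a vector: list with `consistent`, `direction` (+1/-1, 0 when
#'   inconsistent). For a matrix: data.frame `gene_id`, `consistent`,
#'   `direction`.
#' @export
directional_consistency <- function(r_by_study, required_studies = NULL) {
  if (is.matrix(r_by_study)) {
    cols <- if (is.null(required_studies)) colnames(r_by_study) else required_studies
    if (!all(cols %in% colnames(r_by_study))) {
      stop("missing required study: ",
           paste(setdiff(cols, colnames(r_by_study)), collapse = ", "))
    }
    R <- r_by_study[, cols, drop = FALSE]
    pos <- rowSums(R > 0) == ncol(R)
    neg <- rowSums(R < 0) == ncol(R)
    ok <- !is.na(pos) & !is.na(neg) & (pos | neg)
    data.frame(gene_id = rownames(r_by_study),
               consistent = ok & !is.na(rowSums(R)),
               direction = ifelse(ok & pos, 1L, ifelse(ok & neg, -1L, 0L)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (!is.null(required_studies)) {
      if (!all(required_studies %in% names(r_by_study))) {
        stop("missing required study: ",
             paste(setdiff(required_studies, names(r_by_study)), collapse = ", "))
      }
      r_by_study <- r_by_study[required_studies]
    }
    if (any(is.na(r_by_study))) return(list(consistent = FALSE, direction = 0L))
    if (all(r_by_study > 0)) return(list(consistent = TRUE, direction = 1L))
    if (all(r_by_study < 0)) return(list(consistent = TRUE, direction = -1L))
    list(consistent = FALSE, direction = 0L)
  }
}

#' Per-study association of every gene with IS
#'
#' For one cohort, fits the two bivariate models
#' `expression ~ IS*age` and `expression ~ IS*BMI` (sequential ANOVA,
#' IS first), plus the covariate-first variants for order-sensitivity
#' analysis, and computes each gene's univariate correlation with IS.
#' Subjects flagged invalid (outside the HOMA operating range) are excluded.
#'
#' @param expression Gene-by-sample log2 matrix.
#' @param phenotype Phenotype data.frame carrying `is_log`, `age`, `bmi` and
#'   optionally `valid`; rows aligned to the expression columns via
#'   `subject_id`.
#' @return Object of class `study_association`: data.frame with `gene_id`,
#'   `r_is`, `p_is_age`, `p_is_bmi` (IS-first p-values), `p_is_age_covfirst`,
#'   `p_is_bmi_covfirst`, `p_int_age`, `p_int_bmi`; attribute `n` holds the
#'   sample count used.
#' @export
associate_study <- function(expression, phenotype) {
  stopifnot(all(c("subject_id", "is_log", "age", "bmi") %in% names(phenotype)))
  ph <- phenotype
  if ("valid" %in% names(ph)) ph <- ph[ph$valid & !is.na(ph$is_log), , drop = FALSE]
  common <- intersect(colnames(expression), ph$subject_id)
  if (length(common) < 5L) stop("fewer than 5 usable subjects")
  Y <- expression[, common, drop = FALSE]
  ph <- ph[match(common, ph$subject_id), , drop = FALSE]
  age1 <- fit_bivariate_scan(Y, ph$is_log, ph$age, "is_first")
  age2 <- fit_bivariate_scan(Y, ph$is_log, ph$age, "cov_first")
  bmi1 <- fit_bivariate_scan(Y, ph$is_log, ph$bmi, "is_first")
  bmi2 <- fit_bivariate_scan(Y, ph$is_log, ph$bmi, "cov_first")
  out <- data.frame(gene_id = rownames(Y),
                    r_is = unname(univariate_r(Y, ph$is_log)),
                    p_is_age = age1$p_is, p_is_bmi = bmi1$p_is,
                    p_is_age_covfirst = age2$p_is,
                    p_is_bmi_covfirst = bmi2$p_is,
                    p_int_age = age1$p_interaction,
                    p_int_bmi = bmi1$p_interaction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- length(common)
  class(out) <- c("study_association", "data.frame")
  out
}

#' Meta-analytic assembly of the CORE-IS gene table
#'
#' Combines each gene's per-study IS p-values (IS-first sequential ANOVA)
#' across studies with the Stouffer method, separately for the age model and
#' the BMI model; adjusts each meta p-value column by Benjamini-Hochberg;
#' and flags as CORE-IS the genes that pass the FDR threshold (in both
#' bivariate models by default) *and* keep a directionally consistent
#' univariate correlation across the required (largest) studies. Genes absent
#' from any study are excluded rather than imputed.
#'
#' @param assoc_list Named list of [associate_study()] results (names =
#'   study ids).
#' @param fdr_threshold FDR cutoff (default 0.10).
#' @param both_models_required Require FDR pass in both the age and BMI
#'   models (default TRUE); otherwise either suffices.
#' @param required_studies Studies whose correlation signs must agree;
#'   default: the four largest by sample count (all, if fewer).
#' @param order Which per-study p enters the meta-analysis: `"is_first"`
#'   (default) or `"cov_first"` (for order-sensitivity analyses).
#' @param weights Optional per-study Stouffer weights.
#' @return data.frame (`meta_gene_table`): `gene_id`, `z_age`, `p_meta_age`,
#'   `q_age`, `z_bmi`, `p_meta_bmi`, `q_bmi`, per-study `r_<study>` columns,
#'   `direction`, `consistent`, `core_is`.
#' @export
assemble_core_is <- function(assoc_list, fdr_threshold = 0.10,
                             both_models_required = TRUE,
                             required_studies = NULL,
                             order = c("is_first", "cov_first"),
                             weights = NULL) {
  order <- match.arg(order)
  if (length(assoc_list) < 2L) stop("need at least 2 studies for meta-analysis")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) stop("fdr_threshold in (0,1)")
  if (is.null(names(assoc_list)) || any(names(assoc_list) == "")) {
    stop("assoc_list must be a named list of studies")
  }
  genes <- Reduce(intersect, lapply(assoc_list, function(a) a$gene_id))
  if (length(genes) == 0L) stop("no genes common to all studies")
  pick <- function(a, col) a[[col]][match(genes, a$gene_id)]
  p_age_col <- if (order == "is_first") "p_is_age" else "p_is_age_covfirst"
  p_bmi_col <- if (order == "is_first") "p_is_bmi" else "p_is_bmi_covfirst"
  P_age <- sapply(assoc_list, pick, col = p_age_col)
  P_bmi <- sapply(assoc_list, pick, col = p_bmi_col)
  R <- sapply(assoc_list, pick, col = "r_is")
  rownames(P_age) <- rownames(P_bmi) <- rownames(R) <- genes

  meta_age <- stouffer_rows(P_age, weights)
  meta_bmi <- stouffer_rows(P_bmi, weights)
  q_age <- bh_fdr(meta_age$p)
  q_bmi <- bh_fdr(meta_bmi$p)

  if (is.null(required_studies)) {
    ns <- vapply(assoc_list, function(a) attr(a, "n"), 1L)
    required_studies <- names(sort(ns, decreasing = TRUE))[
      seq_len(min(4L, length(ns)))]
  }
  cons <- directional_consistency(R, required_studies)

  pass_fdr <- if (both_models_required) {
    q_age < fdr_threshold & q_bmi < fdr_threshold
  } else {
    q_age < fdr_threshold | q_bmi < fdr_threshold
  }
  out <- data.frame(gene_id = genes,
                    z_age = meta_age$z, p_meta_age = meta_age$p, q_age = q_age,
                    z_bmi = meta_bmi$z, p_meta_bmi = meta_bmi$p, q_bmi = q_bmi,
                    stringsAsFactors = FALSE, row.names = NULL)
  rcols <- as.data.frame(R, stringsAsFactors = FALSE)
  names(rcols) <- paste0("r_", names(assoc_list))
  out <- cbind(out, rcols)
  out$direction <- cons$direction
  out$consistent <- cons$consistent
  out$core_is <- pass_fdr & cons$consistent
  attr(out, "required_studies") <- required_studies
  attr(out, "fdr_threshold") <- fdr_threshold
  rownames(out) <- NULL
  out
}
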