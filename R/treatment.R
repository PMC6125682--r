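#' Paired differential expression (pre vs post intervention)
#'
#' Per gene: per-subject difference \eqn{d_i = post_i - pre_i} on the log2
#' scale, paired t statistic \eqn{t = \bar d / (s_d/\sqrt n)} and two-sided
#' p-value with \eqn{n-1} degrees of freedom. Genes whose differences have
#' zero variance are flagged degenerate with p = 1.
#'
#' @param pre,post Gene-by-subject log2 matrices with matching dimnames
#'   (columns aligned to the same subjects, in order).
#' @return data.frame: `gene_id`, `log2fc` (mean difference), `t`, `p`,
#'   `degenerate`.
#' @export
paired_de <- function(pre, post) {
  stopifnot(is.matrix(pre), is.matrix(post),
            nrow(pre) == nrow(post), ncol(pre) == ncol(post))
  n <- ncol(pre)
  if (n < 3L) stop("need at least 3 pairs")
  d <- post - pre
  m <- rowMeans(d)
  sdev <- sqrt(rowSums((d - m)^2) / (n - 1L))
  degenerate <- sdev == 0
  tstat <- ifelse(degenerate, NA_real_, m / (sdev / sqrt(n)))
  p <- ifelse(degenerate, 1,
              2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE))
  data.frame(gene_id = rownames(pre), log2fc = m, t = tstat, p = p,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stouffer meta-analysis of per-study differential-expression p-values
#'
#' Combines aligned per-study p-value vectors gene-wise with the Stouffer
#' method and adjusts by Benjamini-Hochberg.
#'
#' @param p_list Named list of per-study p-value vectors, all aligned to the
#'   same genes (names or a shared `genes` attribute define alignment).
#' @param genes Optional gene ids (default: names of the first vector).
#' @param weights Optional per-study Stouffer weights.
#' @return data.frame: `gene_id`, `z`, `p_meta`, `q_meta`.
#' @export
de_meta <- function(p_list, genes = NULL, weights = NULL) {
  stopifnot(is.list(p_list), length(p_list) >= 1L)
  P <- do.call(cbind, p_list)
  if (is.null(genes)) genes <- names(p_list[[1L]])
  if (is.null(genes)) genes <- sprintf("feature%d", seq_len(nrow(P)))
  meta <- stouffer_rows(P, weights)
  data.frame(gene_id = genes, z = meta$z, p_meta = meta$p,
             q_meta = bh_fdr(meta$p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Spearman correlation of per-subject expression change with IS change
#'
#' Rank correlation (average ranks for ties) between each gene's per-subject
#' log2 fold change and the per-subject change in log-IS. Genes with constant
#' fold change get `NA`.
#'
#' @param log2fc Gene-by-subject matrix of per-subject log2 fold changes, or
#'   a single numeric vector.
#' @param delta_is Per-subject change in log-IS, aligned to the columns.
#' @return Named numeric vector of Spearman rho (a scalar for vector input).
#' @export
delta_correlation <- function(log2fc, delta_is) {
  if (!is.matrix(log2fc)) {
    if (length(log2fc) < 4L) stop("need at least 4 subjects")
    if (stats::sd(log2fc) == 0 || stats::sd(delta_is) == 0) return(NA_real_)
    return(stats::cor(log2fc, delta_is, method = "spearman"))
  }
  if (ncol(log2fc) < 4L) stop("need at least 4 subjects")
  sds <- apply(log2fc, 1L, stats::sd)
  rho <- suppressWarnings(
    as.vector(stats::cor(t(log2fc), delta_is, method = "spearman")))
  rho[sds == 0] <- NA_real_
  stats::setNames(rho, rownames(log2fc))
}

#' Select genes tracking IS change consistently across studies
#'
#' A gene is selected when, in every study, the sign of its
#' \eqn{\Delta}expression--\eqn{\Delta}IS Spearman correlation is strictly
#' nonzero and concordant with the gene's expected direction from the
#' baseline analysis: positively IS-associated genes must rise with IS
#' improvement, negatively associated genes must fall. No magnitude
#' threshold is applied (the weakest, sign-only reading); `min_abs_rho`
#' optionally adds one.
#'
#' @param rho_matrix Gene-by-study matrix of Spearman correlations.
#' @param expected_direction Named vector (+1/-1) of expected signs per gene.
#' @param min_abs_rho Optional minimum |rho| required in every study
#'   (default 0 = sign only).
#' @return Character vector of selected gene ids.
#' @export
select_consistent_genes <- function(rho_matrix, expected_direction,
                                    min_abs_rho = 0) {
  stopifnot(is.matrix(rho_matrix))
  genes <- rownames(rho_matrix)
  if (is.null(names(expected_direction))) {
    stopifnot(length(expected_direction) == nrow(rho_matrix))
    names(expected_direction) <- genes
  }
  if (!all(genes %in% names(expected_direction))) {
    stop("expected_direction missing for: ",
         paste(utils::head(setdiff(genes, names(expected_direction)), 5L),
               collapse = ", "))
  }
  dir <- expected_direction[genes]
  signed <- rho_matrix * dir
  ok <- rowSums(signed > 0 & abs(rho_matrix) >= min_abs_rho) == ncol(rho_matrix)
  ok[is.na(ok) | dir == 0] <- FALSE
  genes[ok]
}

#' Upper cumulative binomial probability of the consistency count
#'
#' Probability of observing at least `k` of `n` genes consistently
#' sign-concordant across `s` independent studies under the null that each
#' study contributes an independent fair sign, i.e. per-gene success
#' probability \eqn{p_0 = (1/2)^s} by default. Computed via the (log-space
#' stable) binomial tail.
#'
#' @param k Observed consistent genes.
#' @param n Genes tested.
#' @param s Number of studies.
#' @param p0 Per-gene null probability (default `(1/2)^s`).
#' @return data.frame: `k`, `n`, `s`, `p0`, `p_tail`.
#' @export
binomial_consistency_p <- function(k, n, s, p0 = (1 / 2)^s) {
  if (s < 1L) stop("s >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
  p_tail <- stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
  data.frame(k = k, n = n, s = s, p0 = p0, p_tail = p_tail)
}

#' Intervention-layer analysis of a candidate gene list
#'
#' For each paired intervention study: per-subject log2 fold changes of the
#' candidate genes, paired differential expression, and the per-gene Spearman
#' correlation of fold change with the subject's IS change. Per-study DE
#' p-values are meta-analysed (Stouffer + BH); genes whose correlation sign
#' is concordant with the expected baseline direction in every study are
#' selected, and the cumulative-binomial consistency probability of that
#' count is reported.
#'
#' @param studies List of paired studies, each a list with `pre`, `post`
#'   (gene x sample log2 matrices), `pairing` (data.frame `subject_id`,
#'   `pre_sample`, `post_sample`) and `delta_is` (named per-subject vector);
#'   as produced by [simulate_intervention()].
#' @param core_table data.frame with `gene_id` and `direction` (+1/-1), e.g.
#'   the CORE-IS rows of [assemble_core_is()].
#' @param min_abs_rho Passed to [select_consistent_genes()].
#' @return List: `rho` (gene x study matrix), `de` (per-study paired DE),
#'   `de_meta` (meta table), `selected` (gene ids), `binomial`
#'   (consistency test), `fc` (list of per-study fold-change matrices).
#' @export
delta_analysis <- function(studies, core_table, min_abs_rho = 0) {
  stopifnot(all(c("gene_id", "direction") %in% names(core_table)))
  genes <- core_table$gene_id
  dirs <- stats::setNames(core_table$direction, genes)
  rho <- matrix(NA_real_, length(genes), length(studies),
                dimnames = list(genes, vapply(studies, `[[`, "", "study_id")))
  de <- vector("list", length(studies))
  fc_list <- vector("list", length(studies))
  for (s in seq_along(studies)) {
    st <- studies[[s]]
    pre <- st$pre[genes, st$pairing$pre_sample, drop = FALSE]
    post <- st$post[genes, st$pairing$post_sample, drop = FALSE]
    d_is <- st$delta_is[st$pairing$subject_id]
    fc <- post - pre
    colnames(fc) <- st$pairing$subject_id
    fc_list[[s]] <- fc
    rho[, s] <- delta_correlation(fc, d_is)
    de[[s]] <- paired_de(pre, post)
  }
  names(de) <- names(fc_list) <- colnames(rho)
  p_list <- lapply(de, function(x) stats::setNames(x$p, x$gene_id))
  meta <- de_meta(p_list, genes = genes)
  selected <- select_consistent_genes(rho, dirs, min_abs_rho)
  binom <- binomial_consistency_p(length(selected), length(genes),
                                  length(studies))
  list(rho = rho, de = de, de_meta = meta, selected = selected,
       binomial = binom, fc = fc_list)
}
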