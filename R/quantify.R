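#' Quantile normalization
#'
#' Forces every array (column) to share one reference distribution: the
#' row-wise mean of the sorted columns; ties receive the mean of their
#' reference values. Delegates to \code{limma::normalizeQuantiles}. The
#' operation is idempotent.
#'
#' @param m Numeric intensity matrix (linear or log2), samples in columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (length(m) == 0L) stop("empty matrix")
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Median-polish summarization of one probe-set
#'
#' Fits the additive model \eqn{y_{ij} = \mu + probe_i + sample_j + r_{ij}}
#' to the log2 probe intensities of a probe-set by iterated row/column median
#' sweeps (\code{stats::medpolish}; tolerance 1e-8, at most 20 iterations),
#' the RMA-style robust summarizer. The probe-set expression for sample j is
#' \eqn{\mu + sample_j}; residuals are returned for quality control.
#'
#' @param y Log2 probe-by-sample matrix for one probe-set.
#' @param method `"medianpolish"` (default) or `"mean"` (plain column means).
#' @return List with `expression` (named per-sample vector) and `residuals`
#'   (matrix shaped like `y`).
#' @export
summarize_median_polish <- function(y, method = c("medianpolish", "mean")) {
  method <- match.arg(method)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L, dimnames = list("p1", names(y)))
  if (any(!is.finite(y))) stop("non-finite probe intensities")
  if (method == "mean") {
    expr <- colMeans(y)
    return(list(expression = expr,
                residuals = sweep(sweep(y, 2L, expr), 1L, rowMeans(y) - mean(y))))
  }
  if (nrow(y) == 1L) {
    expr <- y[1L, ]
    return(list(expression = expr, residuals = y * 0))
  }
  # non-convergence at eps within the iteration cap is routine and benign
  fit <- suppressWarnings(
    stats::medpolish(y, eps = 1e-8, maxiter = 20L, trace.iter = FALSE))
  expr <- fit$overall + fit$col
  names(expr) <- colnames(y)
  list(expression = expr, residuals = fit$residuals)
}

#' Quantify a chip: normalize, log2, summarize all probe-sets
#'
#' Applies quantile normalization to the linear probe intensities, log2
#' transforms, and median-polish summarizes each probe-set of the chip
#' definition into one expression value per sample.
#'
#' @param intensities Linear-scale probe-by-sample matrix.
#' @param cdf A `chip_definition` from [build_chip_definition()].
#' @param normalize Apply quantile normalization first (default TRUE).
#' @param method Summarizer, see [summarize_median_polish()].
#' @return List with `expression` (probe-set by sample log2 matrix) and
#'   `residuals` (named list of per-probe-set residual matrices).
#' @export
quantify_chip <- function(intensities, cdf, normalize = TRUE,
                          method = "medianpolish") {
  stopifnot(inherits(cdf, "chip_definition"))
  m <- if (normalize) quantile_normalize(intensities) else intensities
  m <- log2(pmax(m, 1))  # floor at 1 linear unit to keep log2 finite
  sets <- cdf$probesets
  expr <- matrix(NA_real_, length(sets), ncol(m),
                 dimnames = list(names(sets), colnames(m)))
  resid <- vector("list", length(sets))
  names(resid) <- names(sets)
  for (ps in names(sets)) {
    fit <- summarize_median_polish(m[sets[[ps]], , drop = FALSE], method = method)
    expr[ps, ] <- fit$expression
    resid[[ps]] <- fit$residuals
  }
  list(expression = expr, residuals = resid)
}

#' NUSE array quality control
#'
#' Normalized unscaled standard errors: for each probe-set, the per-sample
#' standard error of the summarized expression is estimated from the
#' median-polish residual spread, scaled to a cross-sample median of 1, and
#' each array is scored by its median scaled SE over probe-sets. Arrays whose
#' score exceeds `cutoff` are flagged as outliers. Probe-sets with zero
#' residual spread carry no information and are ignored.
#'
#' @param residuals Named list of per-probe-set residual matrices (probes x
#'   samples), as returned by [quantify_chip()].
#' @param cutoff NUSE outlier threshold (default 1.05, common PLM practice).
#' @return data.frame with `sample_id`, `nuse`, `outlier`.
#' @export
nuse_qc <- function(residuals, cutoff = 1.05) {
  stopifnot(is.list(residuals), length(residuals) > 0L)
  n_samp <- ncol(residuals[[1L]])
  if (n_samp < 3L) warning("NUSE is uninformative with fewer than 3 samples")
  se_rows <- lapply(residuals, function(r) {
    if (nrow(r) < 2L) return(NULL)
    se <- sqrt(colSums(r^2) / (nrow(r) - 1L)) / sqrt(nrow(r))
    med <- stats::median(se)
    if (!is.finite(med) || med <= 0) return(NULL)
    se / med
  })
  se_rows <- se_rows[!vapply(se_rows, is.null, TRUE)]
  if (length(se_rows) == 0L) {
    # degenerate chip (e.g. identical replicate arrays everywhere): all SEs
    # equal, define NUSE = 1
    nuse <- rep(1, n_samp)
  } else {
    nuse_mat <- do.call(rbind, se_rows)
    nuse <- apply(nuse_mat, 2L, stats::median)
  }
  data.frame(sample_id = colnames(residuals[[1L]]), nuse = nuse,
             outlier = nuse > cutoff, row.names = NULL,
             stringsAsFactors = FALSE)
}
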