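#' Validate fasting insulin and glucose against the HOMA operating range
#'
#' Homeostasis-model assessment is only considered reliable inside an
#' operating range of its inputs; records outside it are excluded from
#' association analysis rather than extrapolated. Defaults mirror the ranges
#' accepted by the published HOMA2 calculator: insulin 20--400 pmol/l,
#' glucose 3.0--25.0 mmol/l.
#'
#' @param insulin Fasting insulin, pmol/l (vectorised).
#' @param glucose Fasting glucose, mmol/l (vectorised).
#' @param insulin_range,glucose_range Length-2 numeric inclusive bounds.
#' @return data.frame with columns `valid` (logical) and `reason` (character,
#'   `""` when valid).
#' @export
validate_range <- function(insulin, glucose,
                           insulin_range = c(20, 400),
                           glucose_range = c(3.0, 25.0)) {
  if (!is.numeric(insulin) || !is.numeric(glucose)) {
    stop("insulin and glucose must be numeric")
  }
  if (any(insulin <= 0, na.rm = TRUE) || any(glucose <= 0, na.rm = TRUE)) {
    stop("insulin and glucose must be positive")
  }
  n <- max(length(insulin), length(glucose))
  insulin <- rep_len(insulin, n)
  glucose <- rep_len(glucose, n)
  reason <- character(n)
  flag <- function(reason, cond, msg) ifelse(cond & reason == "", msg, reason)
  reason <- flag(reason, insulin < insulin_range[1], "insulin below operating range")
  reason <- flag(reason, insulin > insulin_range[2], "insulin above operating range")
  reason <- flag(reason, glucose < glucose_range[1], "glucose below operating range")
  reason <- flag(reason, glucose > glucose_range[2], "glucose above operating range")
  data.frame(valid = reason == "", reason = reason, stringsAsFactors = FALSE)
}

#' Insulin sensitivity (log10 S%) from fasting insulin and glucose
#'
#' Computes a closed-form homeostasis-model stand-in for insulin resistance,
#' its reciprocal insulin-sensitivity percentile S%, and the log10-transformed
#' S% used as the IS phenotype throughout the pipeline:
#' \deqn{HOMA = \frac{(insulin/6.945)\times glucose}{22.5},\quad
#'       S\% = 100/HOMA,\quad IS = \log_{10} S\%.}
#' Insulin is converted from pmol/l to \eqn{\mu}U/ml by the factor 6.945.
#' The true HOMA2 model is an iterative computer model with nonlinear
#' corrections and is not reproduced here; precomputed S% values from it can
#' be injected instead via `s_percent`.
#'
#' @param insulin Fasting insulin, pmol/l.
#' @param glucose Fasting glucose, mmol/l.
#' @param s_percent Optional precomputed insulin-sensitivity percentile; when
#'   supplied it overrides the closed-form computation.
#' @return data.frame with columns `homa_ir`, `s_percent`, `is_log`.
#' @examples
#' compute_is(57.5, 4.8)  # Table-1-like medians -> is_log about 1.75
#' @export
compute_is <- function(insulin, glucose, s_percent = NULL) {
  if (is.null(s_percent)) {
    if (any(insulin <= 0) || any(glucose <= 0)) stop("inputs must be positive")
    homa <- (insulin / 6.945) * glucose / 22.5
    s_percent <- 100 / homa
  } else {
    homa <- 100 / s_percent
  }
  data.frame(homa_ir = homa, s_percent = s_percent, is_log = log10(s_percent))
}

#' Augment a phenotype table with insulin-sensitivity columns
#'
#' Applies [validate_range()] and [compute_is()] to a phenotype table holding
#' `subject_id`, `fasting_insulin` (pmol/l), `fasting_glucose` (mmol/l) and
#' covariates. Invalid records keep `is_log = NA` and are expected to be
#' excluded downstream.
#'
#' @param pheno Phenotype data.frame.
#' @param s_percent_column Optional column name holding precomputed S%.
#' @param insulin_range,glucose_range Passed to [validate_range()].
#' @return `pheno` with added columns `homa_ir`, `s_percent`, `is_log`,
#'   `valid`, `exclusion_reason`.
#' @export
add_insulin_sensitivity <- function(pheno, s_percent_column = NULL,
                                    insulin_range = c(20, 400),
                                    glucose_range = c(3.0, 25.0)) {
  stopifnot(all(c("fasting_insulin", "fasting_glucose") %in% names(pheno)))
  v <- validate_range(pheno$fasting_insulin, pheno$fasting_glucose,
                      insulin_range, glucose_range)
  sp <- if (!is.null(s_percent_column)) pheno[[s_percent_column]] else NULL
  is_tab <- compute_is(pheno$fasting_insulin, pheno$fasting_glucose, sp)
  is_tab[!v$valid, c("homa_ir", "s_percent", "is_log")] <- NA_real_
  n_lost <- sum(!v$valid)
  if (n_lost > 0L) {
    message(sprintf("add_insulin_sensitivity: %d/%d record(s) outside HOMA operating range excluded",
                    n_lost, nrow(pheno)))
  }
  cbind(pheno, is_tab, valid = v$valid, exclusion_reason = v$reason)
}
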