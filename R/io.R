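#' Read a feature-by-sample matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers and
#' the feature identifier in the first column. Duplicated feature ids are an
#' error; empty cells and the token \code{"NA"} become missing values and
#' their count is reported via a message.
#'
#' @param path Path to a tab-delimited text file.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames, in file order.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file must have a feature id column and at least one sample")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix body: ", path)
  rownames(m) <- ids
  n_na <- sum(is.na(m))
  if (n_na > 0L) {
    message(sprintf("read_matrix: %d missing value(s) in %s", n_na, path))
    if (any(rowSums(!is.na(m)) == 0L)) stop("all-missing feature row in ", path)
  }
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]: header row of sample ids, first column
#' `feature_id`. Round-trips losslessly up to numeric printing precision
#' (15 significant digits).
#'
#' @param m Numeric matrix with rownames (feature ids) and colnames (samples).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write plain data-frame tables (phenotypes, annotations, pairings)
#'
#' Thin wrappers fixing the tabular dialect used throughout the package:
#' tab-delimited, UTF-8, dot decimal separator, header row.
#'
#' @param path File path.
#' @return `read_table_tsv`: a data.frame. `write_table_tsv`: `path`,
#'   invisibly.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                    stringsAsFactors = FALSE)
}

#' @rdname read_table_tsv
#' @param df Data frame to write.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
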