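#' Probe uniqueness filter
#'
#' Retains only probes whose sequence aligns to exactly one genomic location
#' (`map_count == 1`). Probes that align nowhere (`map_count == 0`) or to
#' several locations are discarded: their signal cannot be attributed to a
#' single transcript.
#'
#' @param annot Probe annotation data.frame with columns `probe_id`,
#'   `target_id`, `map_count`, `gc_fraction`.
#' @return Character vector of retained probe ids.
#' @export
filter_unique_probes <- function(annot) {
  check_annotation(annot)
  if (any(is.na(annot$map_count))) stop("map_count missing for some probes")
  annot$probe_id[annot$map_count == 1L]
}

#' Per-probe signal statistics on the linear intensity scale
#'
#' Mean and coefficient of variation (sd/mean) across samples for each probe.
#' Probes with zero mean get `cv = NA` and `cv_defined = FALSE`.
#'
#' @param intensities Linear-scale probe-by-sample matrix (rownames = probe
#'   ids); at least 2 samples.
#' @return data.frame with `probe_id`, `mean_intensity`, `cv`, `cv_defined`.
#' @export
compute_probe_stats <- function(intensities) {
  stopifnot(is.matrix(intensities))
  if (ncol(intensities) < 2L) stop("need at least 2 samples to estimate probe variability")
  mu <- rowMeans(intensities)
  sdev <- apply(intensities, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdev / mu, NA_real_)
  data.frame(probe_id = rownames(intensities), mean_intensity = mu,
             cv = cv, cv_defined = mu > 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Low-and-variable-signal probe filter
#'
#' Removes probes with weak and unstable hybridisation signal: retained iff
#' mean intensity >= `min_mean` (linear units) and coefficient of variation
#' <= `max_cv`. Defaults (10 units, 25%) are tissue-dependent starting points
#' and are configurable.
#'
#' @param stats Output of [compute_probe_stats()].
#' @param min_mean Minimum mean linear intensity (default 10).
#' @param max_cv Maximum coefficient of variation (default 0.25).
#' @return Character vector of retained probe ids.
#' @export
filter_signal <- function(stats, min_mean = 10, max_cv = 0.25) {
  if (min_mean < 0 || max_cv < 0) stop("thresholds must be non-negative")
  keep <- stats$cv_defined & stats$mean_intensity >= min_mean & stats$cv <= max_cv
  stats$probe_id[keep]
}

#' Extreme-GC-content probe filter
#'
#' Removes probes whose GC fraction lies outside `[gc_low, gc_high]`
#' (boundaries inclusive-retain): signal correction models behave nonlinearly
#' at GC extremes, so such probes are dropped rather than corrected.
#'
#' @param annot Probe annotation data.frame (see [filter_unique_probes()]).
#' @param gc_low,gc_high Inclusive retention bounds (defaults 0.20, 0.80).
#' @return Character vector of retained probe ids.
#' @export
filter_gc <- function(annot, gc_low = 0.20, gc_high = 0.80) {
  check_annotation(annot)
  gc <- annot$gc_fraction
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc_fraction outside [0,1]")
  annot$probe_id[!is.na(gc) & gc >= gc_low & gc <= gc_high]
}

#' Assemble probe-sets from filtered probes (the custom chip definition)
#'
#' Groups retained probes by their target transcript and keeps only targets
#' represented by at least `min_probes` surviving probes. The result is a
#' chip definition: the probe-to-probe-set map used for summarization, with
#' the filter provenance recorded.
#'
#' @param retained Character vector of probe ids that passed all filters
#'   (typically the intersection of the three filter outputs).
#' @param annot Probe annotation data.frame.
#' @param min_probes Minimum probes per probe-set (default 3).
#' @param provenance Optional named list of the thresholds used; stored as-is.
#' @return Object of class `chip_definition`: list with `probesets` (named
#'   list target_id -> character vector of probe ids, probes in annotation
#'   order) and `provenance`.
#' @export
assemble_chipdef <- function(retained, annot, min_probes = 3L,
                             provenance = list()) {
  check_annotation(annot)
  if (length(retained) == 0L) stop("no probes retained; cannot assemble a chip definition")
  ann <- annot[annot$probe_id %in% retained, , drop = FALSE]
  sets <- split(ann$probe_id, ann$target_id)
  sets <- sets[vapply(sets, length, 1L) >= min_probes]
  provenance$min_probes <- min_probes
  provenance$n_probes_retained <- sum(vapply(sets, length, 1L))
  provenance$n_probesets <- length(sets)
  structure(list(probesets = sets, provenance = provenance),
            class = "chip_definition")
}

#' Build a chip definition from raw probe intensities and annotation
#'
#' Runs the full probe filter cascade -- genomic uniqueness, low/variable
#' signal, extreme GC -- then assembles probe-sets. The three filters are
#' pure set intersections, so their order is immaterial. The signal filter is
#' computed from the supplied sample set, making the definition
#' experiment-specific.
#'
#' @param intensities Linear-scale probe-by-sample matrix.
#' @param annot Probe annotation data.frame.
#' @inheritParams filter_signal
#' @inheritParams filter_gc
#' @inheritParams assemble_chipdef
#' @return A `chip_definition` (see [assemble_chipdef()]).
#' @export
build_chip_definition <- function(intensities, annot, min_mean = 10,
                                  max_cv = 0.25, gc_low = 0.20,
                                  gc_high = 0.80, min_probes = 3L) {
  keep_unique <- filter_unique_probes(annot)
  keep_signal <- filter_signal(compute_probe_stats(intensities), min_mean, max_cv)
  keep_gc <- filter_gc(annot, gc_low, gc_high)
  retained <- intersect(intersect(keep_unique, keep_signal), keep_gc)
  message(sprintf(
    "build_chip_definition: %d probes in; unique %d, signal %d, gc %d; retained %d",
    nrow(annot), length(keep_unique), length(keep_signal), length(keep_gc),
    length(retained)))
  assemble_chipdef(retained, annot, min_probes,
                   provenance = list(min_mean = min_mean, max_cv = max_cv,
                                     gc_low = gc_low, gc_high = gc_high,
                                     n_samples_defining = ncol(intensities)))
}

#' Serialize / deserialize a chip definition as TSV
#'
#' Long format: `probe_set_id`, `probe_id`, `rank` (1-based position within
#' the set). Provenance is written as a JSON sidecar `<path>.json`. The
#' round-trip is lossless.
#'
#' @param cdf A `chip_definition`.
#' @param path Output TSV path.
#' @return `write_chipdef`: `path`, invisibly. `read_chipdef`: a
#'   `chip_definition`.
#' @export
write_chipdef <- function(cdf, path) {
  stopifnot(inherits(cdf, "chip_definition"))
  df <- do.call(rbind, lapply(names(cdf$probesets), function(ps) {
    probes <- cdf$probesets[[ps]]
    data.frame(probe_set_id = ps, probe_id = probes,
               rank = seq_along(probes), stringsAsFactors = FALSE)
  }))
  write_table_tsv(df, path)
  jsonlite::write_json(cdf$provenance, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_chipdef
#' @export
read_chipdef <- function(path) {
  df <- read_table_tsv(path)
  df <- df[order(match(df$probe_set_id, unique(df$probe_set_id)), df$rank), ]
  sets <- split(df$probe_id, df$probe_set_id)
  # split() sorts keys; restore file order of probe-sets
  sets <- sets[unique(df$probe_set_id)]
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  structure(list(probesets = sets, provenance = prov), class = "chip_definition")
}

#' Collapse probe-set expression to gene level
#'
#' When a gene is represented by more than one probe-set, the probe-set with
#' the highest mean expression across samples is kept and the others dropped
#' (ties broken by the lexicographically smallest probe-set id). Probe-sets
#' absent from the gene map are dropped with a warning.
#'
#' @param expression Probe-set by sample log2 expression matrix.
#' @param gene_map data.frame with columns `probe_set_id`, `gene_id`.
#' @return Gene-by-sample log2 expression matrix (rownames = gene ids).
#' @export
collapse_by_gene <- function(expression, gene_map) {
  stopifnot(is.matrix(expression),
            all(c("probe_set_id", "gene_id") %in% names(gene_map)))
  ps <- rownames(expression)
  gene <- gene_map$gene_id[match(ps, gene_map$probe_set_id)]
  if (any(is.na(gene))) {
    warning(sum(is.na(gene)), " probe-set(s) missing from gene map; dropped")
    expression <- expression[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  means <- rowMeans(expression)
  ord <- order(gene, -means, rownames(expression), method = "radix")
  keep <- ord[!duplicated(gene[ord])]
  out <- expression[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out
}

check_annotation <- function(annot) {
  req <- c("probe_id", "target_id", "map_count", "gc_fraction")
  if (!all(req %in% names(annot))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(annot$probe_id)) {
    stop("duplicate probe_id in annotation (multi-target probes are an input error)")
  }
  invisible(TRUE)
}
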