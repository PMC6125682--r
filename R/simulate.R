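# Synthetic data with planted truth: probe-level chips, multi-cohort
# baseline phenotypes, and paired interventions. All randomness flows from
# explicit seed arguments; the global RNG state is saved and restored.

#' Evaluate code under a local RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so the
#' generators never leak global RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# lognormal draws with a given linear-scale mean and coefficient of variation
rlnorm_meancv <- function(n, mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# truncated normal via inverse CDF (a, b may be vectors)
rtruncnorm <- function(n, mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

#' Chip design parameters for the probe-level simulator
#'
#' Describes a synthetic high-density expression array: how many probes
#' interrogate each gene and which fractions of probes are planted to violate
#' each probe-level filter -- "dead" probes reporting only optical/chemical
#' background, probes mapping to multiple genomic locations, and probes with
#' extreme GC content.
#'
#' Default planted fractions (0.15 dead, 0.10 multi-mapping, 0.10 GC-extreme,
#' about a third of probes in total) mirror the scale of probe attrition seen
#' on real high-density arrays after such filtering.
#'
#' @param n_genes Number of genes (one transcript target per gene).
#' @param probes_per_gene Nominal probes per gene (default 8).
#' @param frac_dead_probes Fraction of probes that are background-only.
#' @param frac_multimap_probes Fraction with genomic map count >= 2.
#' @param frac_gc_extreme Fraction with GC fraction outside [0.20, 0.80].
#' @param background_mean Mean background intensity, linear units (default 5,
#'   below the 10-unit signal floor by design).
#' @param background_cv Coefficient of variation of background (default 0.2).
#' @param signal_gain Linear intensity per unit true abundance (default 20).
#' @param affinity_sd Log-normal sd of the fixed per-probe binding affinity
#'   (default 0.25; sequence-dependent, constant across samples).
#' @param noise_cv Per-measurement multiplicative noise CV (default 0.10).
#' @return Validated list of class `chip_design`.
#' @export
chip_design <- function(n_genes, probes_per_gene = 8L,
                        frac_dead_probes = 0.15,
                        frac_multimap_probes = 0.10,
                        frac_gc_extreme = 0.10,
                        background_mean = 5, background_cv = 0.2,
                        signal_gain = 20, affinity_sd = 0.25,
                        noise_cv = 0.10) {
  fr <- c(frac_dead_probes, frac_multimap_probes, frac_gc_extreme)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (n_genes < 1L || probes_per_gene < 1L) stop("empty design")
  if (background_mean <= 0) stop("background_mean must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 frac_dead_probes = frac_dead_probes,
                 frac_multimap_probes = frac_multimap_probes,
                 frac_gc_extreme = frac_gc_extreme,
                 background_mean = background_mean,
                 background_cv = background_cv,
                 signal_gain = signal_gain,
                 affinity_sd = affinity_sd,
                 noise_cv = noise_cv),
            class = "chip_design")
}

#' Simulate probe-level intensities and probe annotation
#'
#' Live probes measure \code{gain * abundance * affinity * noise} with a
#' fixed per-probe log-normal affinity and per-measurement log-normal noise.
#' Dead probes are drawn from background only (linear mean
#' `background_mean`), regardless of the target's abundance. Multi-mapping
#' probes (`map_count >= 2`) cross-hybridise: their signal is the sum of the
#' target's abundance and that of the other loci they map to. GC-extreme
#' probes (GC outside [0.20, 0.80]) respond nonlinearly, with a compressed
#' dynamic range. The probe truth (planted flags) is returned so filter
#' recovery can be scored.
#'
#' @param design A [chip_design()].
#' @param true_abundance Gene-by-sample matrix of positive linear abundances;
#'   rownames are gene ids (generated if absent).
#' @param seed Integer seed; identical (design, abundance, seed) give
#'   byte-identical output.
#' @return List with `intensities` (probe x sample matrix), `annotation`
#'   (data.frame: probe_id, target_id, map_count, gc_fraction), `probe_truth`
#'   (data.frame: probe_id, gene_id, dead, multimap, gc_extreme) and
#'   `gene_map` (data.frame: probe_set_id, gene_id).
#' @export
simulate_chip <- function(design, true_abundance, seed) {
  stopifnot(inherits(design, "chip_design"))
  if (!is.matrix(true_abundance)) stop("true_abundance must be a gene x sample matrix")
  if (any(true_abundance <= 0)) stop("abundances must be positive")
  if (nrow(true_abundance) != design$n_genes) {
    stop("true_abundance must have n_genes rows")
  }
  genes <- rownames(true_abundance)
  if (is.null(genes)) {
    genes <- sprintf("G%05d", seq_len(design$n_genes))
    rownames(true_abundance) <- genes
  }
  samples <- colnames(true_abundance)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(true_abundance)))
  with_seed(seed, {
    ppg <- design$probes_per_gene
    n_probes <- design$n_genes * ppg
    gene_of <- rep(genes, each = ppg)
    probe_id <- sprintf("P%07d", seq_len(n_probes))
    target_id <- paste0("ENST_", gene_of)

    dead <- stats::runif(n_probes) < design$frac_dead_probes
    multimap <- stats::runif(n_probes) < design$frac_multimap_probes
    gc_extreme <- stats::runif(n_probes) < design$frac_gc_extreme

    map_count <- rep(1L, n_probes)
    map_count[multimap] <- sample(2:4, sum(multimap), replace = TRUE)
    gc <- stats::runif(n_probes, 0.30, 0.70)
    n_ext <- sum(gc_extreme)
    if (n_ext > 0L) {
      lo <- stats::runif(n_ext) < 0.5
      gc[gc_extreme] <- ifelse(lo, stats::runif(n_ext, 0.02, 0.18),
                               stats::runif(n_ext, 0.82, 0.98))
    }

    affinity <- rlnorm_meancv(n_probes, 1, design$affinity_sd)
    n_samp <- length(samples)
    noise <- matrix(rlnorm_meancv(n_probes * n_samp, 1, design$noise_cv),
                    n_probes, n_samp)
    ab <- true_abundance[gene_of, , drop = FALSE]
    # multi-mapping probes cross-hybridise: they also pick up the abundance
    # of (map_count - 1) other genomic loci, fixed per probe
    for (i in which(multimap)) {
      others <- sample(setdiff(seq_len(design$n_genes),
                               match(gene_of[i], genes)),
                       map_count[i] - 1L)
      ab[i, ] <- ab[i, ] + colSums(true_abundance[others, , drop = FALSE])
    }
    # GC-extreme probes respond nonlinearly: compressed dynamic range around
    # the gene's geometric-mean abundance
    if (n_ext > 0L) {
      gm <- exp(rowMeans(log(ab[gc_extreme, , drop = FALSE])))
      ab[gc_extreme, ] <- sqrt(ab[gc_extreme, , drop = FALSE] * gm)
    }
    signal <- design$signal_gain * ab * affinity * noise
    bg <- matrix(rlnorm_meancv(n_probes * n_samp, design$background_mean,
                               design$background_cv),
                 n_probes, n_samp)
    intens <- ifelse(matrix(dead, n_probes, n_samp), bg, signal)
    dimnames(intens) <- list(probe_id, samples)

    list(intensities = intens,
         annotation = data.frame(probe_id = probe_id, target_id = target_id,
                                 map_count = map_count, gc_fraction = gc,
                                 stringsAsFactors = FALSE),
         probe_truth = data.frame(probe_id = probe_id, gene_id = gene_of,
                                  dead = dead, multimap = multimap,
                                  gc_extreme = gc_extreme,
                                  stringsAsFactors = FALSE),
         gene_map = data.frame(probe_set_id = paste0("ENST_", genes),
                               gene_id = genes, stringsAsFactors = FALSE))
  })
}

#' Cohort simulation parameters
#'
#' Defines the multi-cohort baseline study: cohort sizes, phenotype ranges
#' (units: insulin pmol/l, glucose mmol/l, age years, BMI kg/m2), the planted
#' fraction of insulin-sensitivity (IS) genes and their target correlation
#' with log10 S%, the sign mixture, and the BMI--IS coupling.
#'
#' @param n_cohorts Number of cohorts (default 6).
#' @param n_subjects Integer vector of per-cohort sizes, or a length-2 range
#'   from which sizes are drawn (default `c(80, 190)`).
#' @param n_genes Genes simulated (default 2000).
#' @param frac_is_genes Planted fraction of IS-associated genes (default
#'   0.05).
#' @param effect_r Target population correlation between log2 expression and
#'   log-IS for planted genes (default 0.3; |r| < 1). A length-2 vector is
#'   treated as a range: each planted gene draws its own |r| uniformly from
#'   it, emulating a continuous effect-size distribution.
#' @param sign_mix Fraction of planted genes with negative direction
#'   (default 0.5).
#' @param insulin_range,glucose_range Operating ranges the generated values
#'   must respect (defaults 20--400 pmol/l, 4.0--6.5 mmol/l).
#' @param age_range,bmi_range Covariate ranges (defaults 18--70 y,
#'   19--45 kg/m2).
#' @param bmi_is_coupling Correlation between BMI and log-IS (default -0.4:
#'   heavier subjects tend to be less insulin sensitive).
#' @param is_log_mean,is_log_sd Population location/scale of log10 S%
#'   (defaults 1.8 and 0.25, matching a median S% near 80 with a several-fold
#'   range).
#' @param expr_sd Residual log2-expression sd (default 0.25, typical array-scale
#   biological variation; linear-scale CV about 18 percent).
#' @param seed Integer seed.
#' @return Validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_cohorts = 6L, n_subjects = c(80L, 190L),
                          n_genes = 2000L, frac_is_genes = 0.05,
                          effect_r = 0.3, sign_mix = 0.5,
                          insulin_range = c(20, 400),
                          glucose_range = c(4.0, 6.5),
                          age_range = c(18, 70), bmi_range = c(19, 45),
                          bmi_is_coupling = -0.4,
                          is_log_mean = 1.8, is_log_sd = 0.25,
                          expr_sd = 0.25, seed = 1L) {
  p <- mget(names(formals()))
  if (any(abs(effect_r) >= 1)) stop("|effect_r| must be < 1")
  if (length(effect_r) > 2L) stop("effect_r is a scalar or a length-2 range")
  if (frac_is_genes < 0 || frac_is_genes > 1) stop("frac_is_genes in [0,1]")
  if (sign_mix < 0 || sign_mix > 1) stop("sign_mix in [0,1]")
  for (rg in list(insulin_range, glucose_range, age_range, bmi_range)) {
    if (length(rg) != 2L || diff(rg) <= 0) stop("ranges must be non-degenerate")
  }
  if (abs(bmi_is_coupling) >= 1) stop("|bmi_is_coupling| must be < 1")
  structure(p, class = "cohort_params")
}

# constant of the closed-form HOMA stand-in: is_log = IS_C - log10(ins) - log10(glu)
IS_C <- log10(100 * 22.5 * 6.945)

#' Simulate baseline cohorts with planted IS genes
#'
#' Per cohort: log-IS is drawn from a truncated normal inside the window
#' compatible with the insulin/glucose operating ranges, glucose uniformly
#' inside its range, and insulin back-solved through the closed-form HOMA
#' stand-in so that [compute_is()] reproduces the planted log-IS exactly and
#' both analytes stay inside their stated ranges. BMI is coupled to log-IS by
#' a bivariate Gaussian with the configured correlation; age is independent.
#' Planted genes follow \eqn{y = \alpha_g + d_g\, r\, \sigma z_{IS} +
#' \sigma\sqrt{1-r^2}\,\varepsilon} with \eqn{z_{IS}} the standardized
#' log-IS, giving population correlation `effect_r`; all other genes are
#' independent of IS.
#'
#' @param params A [cohort_params()].
#' @return List with `cohorts` (each: `expression` gene x sample log2 matrix,
#'   `phenotype` data.frame, `study_id`), `truth` (gene_id, is_planted,
#'   true_direction, true_effect), `baseline` (per-gene log2 baseline) and
#'   `params`.
#' @export
simulate_cohorts <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  with_seed(p$seed, {
    sizes <- if (length(p$n_subjects) == 2L && p$n_cohorts != 2L) {
      sample(seq(p$n_subjects[1], p$n_subjects[2]), p$n_cohorts, replace = TRUE)
    } else rep_len(p$n_subjects, p$n_cohorts)
    genes <- sprintf("G%05d", seq_len(p$n_genes))
    n_planted <- round(p$frac_is_genes * p$n_genes)
    planted <- sort(sample.int(p$n_genes, n_planted))
    direction <- integer(p$n_genes)
    if (n_planted > 0L) {
      neg <- stats::runif(n_planted) < p$sign_mix
      direction[planted] <- ifelse(neg, -1L, 1L)
    }
    r_gene <- numeric(p$n_genes)
    r_gene[planted] <- if (length(p$effect_r) == 2L) {
      stats::runif(n_planted, min(abs(p$effect_r)), max(abs(p$effect_r)))
    } else rep(abs(p$effect_r), n_planted)
    alpha <- stats::runif(p$n_genes, 6, 12)  # shared gene baselines, log2

    # feasible log-IS window given the analyte ranges
    lo_is <- IS_C - log10(p$insulin_range[2]) - log10(p$glucose_range[2])
    hi_is <- IS_C - log10(p$insulin_range[1]) - log10(p$glucose_range[1])

    cohorts <- vector("list", p$n_cohorts)
    for (k in seq_len(p$n_cohorts)) {
      n <- sizes[k]
      glucose <- stats::runif(n, p$glucose_range[1], p$glucose_range[2])
      is_lo <- pmax(lo_is, IS_C - log10(p$insulin_range[2]) - log10(glucose))
      is_hi <- pmin(hi_is, IS_C - log10(p$insulin_range[1]) - log10(glucose))
      is_log <- rtruncnorm(n, p$is_log_mean, p$is_log_sd, is_lo, is_hi)
      insulin <- 10^(IS_C - is_log - log10(glucose))
      z <- as.vector(scale(is_log))
      rho <- p$bmi_is_coupling
      bmi_mid <- mean(p$bmi_range)
      bmi_sd <- diff(p$bmi_range) / 8
      bmi <- bmi_mid + bmi_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
      bmi <- pmin(pmax(bmi, p$bmi_range[1]), p$bmi_range[2])
      age <- stats::runif(n, p$age_range[1], p$age_range[2])

      expr <- matrix(stats::rnorm(p$n_genes * n, sd = p$expr_sd),
                     p$n_genes, n) * sqrt(1 - r_gene^2)
      expr <- expr + alpha + outer(direction * r_gene * p$expr_sd, z)
      dimnames(expr) <- list(genes, sprintf("C%d_S%03d", k, seq_len(n)))

      cohorts[[k]] <- list(
        study_id = sprintf("study%d", k),
        expression = expr,
        phenotype = data.frame(
          subject_id = colnames(expr),
          fasting_insulin = insulin, fasting_glucose = glucose,
          age = age, bmi = bmi, assay = "ELISA",
          stringsAsFactors = FALSE))
    }
    truth <- data.frame(gene_id = genes,
                        is_planted = direction != 0L,
                        true_direction = direction,
                        true_effect = direction * r_gene,
                        stringsAsFactors = FALSE)
    list(cohorts = cohorts, truth = truth,
         baseline = stats::setNames(alpha, genes), params = p)
  })
}

#' Intervention simulation parameters
#'
#' Defines paired pre/post intervention studies: per-subject change in log-IS
#' and the planted rank coupling between per-subject expression change and
#' IS change.
#'
#' @param n_subjects Paired subjects per study (default 40).
#' @param n_studies Number of independent intervention studies (default 4).
#' @param frac_delta_genes Fraction of the eligible (directional) genes whose
#'   change tracks the IS change (default 0.25).
#' @param delta_rho Target Spearman correlation between per-subject log2 fold
#'   change and per-subject change in log-IS for planted genes (default 0.5).
#' @param delta_is_mean,delta_is_sd Mean and sd of the per-subject log-IS
#'   response (defaults 0.15 and 0.20: interventions improve IS on average
#'   but individual responses vary, some worsening).
#' @param fc_sd Log2 fold-change scale (default 0.3).
#' @param seed Integer seed.
#' @return Validated list of class `intervention_params`.
#' @export
intervention_params <- function(n_subjects = 40L, n_studies = 4L,
                                frac_delta_genes = 0.25, delta_rho = 0.5,
                                delta_is_mean = 0.15, delta_is_sd = 0.20,
                                fc_sd = 0.3, seed = 1L) {
  p <- mget(names(formals()))
  if (abs(delta_rho) >= 1) stop("|delta_rho| must be < 1")
  if (n_studies < 1L) stop("n_studies >= 1")
  if (n_subjects < 3L) stop("need at least 3 paired subjects")
  structure(p, class = "intervention_params")
}

#' Simulate paired pre/post intervention studies
#'
#' Planted delta genes change in proportion (in rank) to each subject's
#' log-IS change, with the sign matched to the gene's baseline direction: an
#' IS improvement moves expression toward the healthy direction. The Pearson
#' coupling is set to \eqn{2\sin(\pi\rho_S/6)} so the population Spearman
#' correlation equals `delta_rho` under the Gaussian copula. Non-planted
#' genes change independently. The planted gene subset is shared across
#' studies; noise is independent per study.
#'
#' @param params An [intervention_params()].
#' @param truth Gene truth table with `gene_id` and `true_direction`
#'   (e.g. from [simulate_cohorts()]); genes with nonzero direction are the
#'   eligible pool from which delta genes are planted.
#' @param baseline Named per-gene log2 baseline vector (defaults to 8 for
#'   all genes).
#' @return List with `studies` (each: `pre`, `post` gene x sample matrices,
#'   `pairing` data.frame, `delta_is` named per-subject vector, `study_id`),
#'   `truth` (gene_id, is_delta_planted, expected_direction, true_rho) and
#'   `params`.
#' @export
simulate_intervention <- function(params, truth, baseline = NULL) {
  stopifnot(inherits(params, "intervention_params"))
  p <- params
  genes <- truth$gene_id
  if (is.null(baseline)) baseline <- stats::setNames(rep(8, length(genes)), genes)
  eligible <- which(truth$true_direction != 0L)
  if (length(eligible) == 0L) eligible <- seq_along(genes)
  with_seed(p$seed, {
    n_delta <- round(p$frac_delta_genes * length(eligible))
    delta_idx <- sort(sample(eligible, n_delta))
    is_delta <- seq_along(genes) %in% delta_idx
    dir <- truth$true_direction
    dir[dir == 0L & is_delta] <- 1L  # only when no directional pool existed
    # Gaussian-copula coupling targeting the requested Spearman rho
    r_pearson <- 2 * sin(pi * p$delta_rho / 6)
    c_load <- r_pearson / sqrt(1 - r_pearson^2)

    studies <- vector("list", p$n_studies)
    for (s in seq_len(p$n_studies)) {
      n <- p$n_subjects
      subj <- sprintf("T%d_subj%03d", s, seq_len(n))
      d_is <- stats::rnorm(n, p$delta_is_mean, p$delta_is_sd)
      z_dis <- as.vector(scale(d_is))
      fc <- matrix(stats::rnorm(length(genes) * n), length(genes), n)
      if (n_delta > 0L) {
        fc[delta_idx, ] <- sweep(fc[delta_idx, , drop = FALSE] , 2L,
                                 c_load * z_dis, `+`) * dir[delta_idx]
        fc[delta_idx, ] <- fc[delta_idx, , drop = FALSE] / sqrt(1 + c_load^2)
      }
      fc <- fc * p$fc_sd
      pre <- matrix(stats::rnorm(length(genes) * n, sd = 0.4),
                    length(genes), n) + baseline[genes]
      post <- pre + fc
      pre_ids <- paste0(subj, "_pre")
      post_ids <- paste0(subj, "_post")
      dimnames(pre) <- list(genes, pre_ids)
      dimnames(post) <- list(genes, post_ids)
      studies[[s]] <- list(
        study_id = sprintf("intervention%d", s),
        pre = pre, post = post,
        pairing = data.frame(subject_id = subj, pre_sample = pre_ids,
                             post_sample = post_ids,
                             stringsAsFactors = FALSE),
        delta_is = stats::setNames(d_is, subj))
    }
    list(studies = studies,
         truth = data.frame(gene_id = genes,
                            is_delta_planted = is_delta,
                            expected_direction = truth$true_direction,
                            true_rho = ifelse(is_delta, p$delta_rho * dir, 0),
                            stringsAsFactors = FALSE),
         params = p)
  })
}
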