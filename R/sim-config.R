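#' Configuration for the synthetic screen generator
#'
#' Bundles every tunable of the synthetic-data generator: the toy genome and
#' deficiency tiling, the viability model of the balancer crosses, the
#' expression model (negative-binomial counts with an NMD-target fold change
#' and a flagged ribosomal gene set), and the mRNA decay time courses.
#'
#' The defaults describe the screen the generator emulates: a partially viable
#' NMD mutant with 10\% baseline survival, a single true suppressor locus (a
#' Gadd45-like driver gene) whose mRNA rises 16.7-fold in the mutant, and a
#' reference set of 74 ribosomal-protein genes used to rescale mutant
#' libraries.
#'
#' @param genome_length Length of the single toy chromosome, in bases.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_deficiencies Number of deficiencies tiling the genome.
#' @param tiling_overlap_fraction Fraction in `[0, 1)` of each deficiency
#'   shared with its neighbour; 0 gives pairwise-disjoint deficiencies.
#' @param driver_gene_index Index (1-based) of the true suppressor locus among
#'   the genes; defaults to the middle gene.
#' @param baseline_viability Survival probability `v0` of the NMD-mutant class
#'   in an unsuppressed cross; default 0.10.
#' @param suppressed_viability Survival probability `v1 >= v0` of the mutant
#'   class when the deficiency deletes the driver gene; default 0.30.
#' @param progeny_per_cross Number of F1 male zygotes `N` scored per cross.
#' @param nmd_fold_change Fold increase of driver-gene mRNA in the mutant
#'   condition; default 16.7.
#' @param ribosomal_gene_count Number of genes flagged as ribosomal-protein
#'   reference genes; default 74.
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2); must be positive.
#' @param n_replicates Biological replicates per expression condition.
#' @param decay_halflives Half-lives, in hours, of the simulated decay curves.
#' @param decay_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on decay measurements.
#' @param decay_replicates Replicate decay curves per half-life.
#' @param seed Integer seed; identical config + seed reproduce identical data.
#'
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(genome_length = 1e5, n_genes = 50, n_deficiencies = 10)
#' cfg$baseline_viability
#' @export
sim_config <- function(genome_length = 1e6,
                       n_genes = 400,
                       n_deficiencies = 100,
                       tiling_overlap_fraction = 0.15,
                       driver_gene_index = NULL,
                       baseline_viability = 0.10,
                       suppressed_viability = 0.30,
                       progeny_per_cross = 200,
                       nmd_fold_change = 16.7,
                       ribosomal_gene_count = 74,
                       nb_dispersion = 0.1,
                       n_replicates = 2,
                       decay_halflives = c(0.5, 1, 2, 4),
                       decay_noise_cv = 0.05,
                       decay_replicates = 3,
                       seed = 1L) {
  driver_gene_index <- driver_gene_index %||% max(1L, n_genes %/% 2L)
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_genes = as.integer(n_genes),
    n_deficiencies = as.integer(n_deficiencies),
    tiling_overlap_fraction = tiling_overlap_fraction,
    driver_gene_index = as.integer(driver_gene_index),
    baseline_viability = baseline_viability,
    suppressed_viability = suppressed_viability,
    progeny_per_cross = as.integer(progeny_per_cross),
    nmd_fold_change = nmd_fold_change,
    ribosomal_gene_count = as.integer(ribosomal_gene_count),
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    decay_halflives = as.numeric(decay_halflives),
    decay_noise_cv = decay_noise_cv,
    decay_replicates = as.integer(decay_replicates),
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (!(baseline_viability > 0 && baseline_viability <= 1)) {
      abort("`baseline_viability` must lie in (0, 1].", class = "defsup_config_error")
    }
    if (!(suppressed_viability >= baseline_viability && suppressed_viability <= 1)) {
      abort("`suppressed_viability` must lie in [baseline_viability, 1].",
            class = "defsup_config_error")
    }
    if (progeny_per_cross < 0) {
      abort("`progeny_per_cross` must be >= 0.", class = "defsup_config_error")
    }
    if (genome_length < n_genes) {
      abort("`genome_length` must be at least `n_genes`.", class = "defsup_config_error")
    }
    if (ribosomal_gene_count >= n_genes) {
      abort("`ribosomal_gene_count` must be smaller than `n_genes`.",
            class = "defsup_config_error")
    }
    if (tiling_overlap_fraction < 0 || tiling_overlap_fraction >= 1) {
      abort("`tiling_overlap_fraction` must lie in [0, 1).", class = "defsup_config_error")
    }
    if (driver_gene_index < 1 || driver_gene_index > n_genes) {
      abort("`driver_gene_index` out of range.", class = "defsup_config_error")
    }
    if (nb_dispersion <= 0) {
      abort("`nb_dispersion` must be positive.", class = "defsup_config_error")
    }
    if (nmd_fold_change <= 0) {
      abort("`nmd_fold_change` must be positive.", class = "defsup_config_error")
    }
    if (length(decay_halflives) && any(decay_halflives <= 0)) {
      abort("`decay_halflives` must all be positive.", class = "defsup_config_error")
    }
    if (decay_noise_cv < 0) {
      abort("`decay_noise_cv` must be nonnegative.", class = "defsup_config_error")
    }
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %s bases, %d genes (driver #%d), %d deficiencies (overlap %.2f)\n",
              format(x$genome_length, big.mark = ","), x$n_genes,
              x$driver_gene_index, x$n_deficiencies, x$tiling_overlap_fraction))
  cat(sprintf("  crosses: N = %d, v0 = %.3g, v1 = %.3g\n",
              x$progeny_per_cross, x$baseline_viability, x$suppressed_viability))
  cat(sprintf("  expression: fold = %.3g, %d ribosomal genes, dispersion = %.3g, %d reps\n",
              x$nmd_fold_change, x$ribosomal_gene_count, x$nb_dispersion, x$n_replicates))
  cat(sprintf("  decay: t1/2 = {%s} h, noise CV = %.3g, %d reps; seed = %d\n",
              paste(x$decay_halflives, collapse = ", "), x$decay_noise_cv,
              x$decay_replicates, x$seed))
  invisible(x)
}

# Deterministic substream seed so that adding crosses/genes/curves never
# perturbs draws made for earlier units (31-bit multiplicative hash).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}
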