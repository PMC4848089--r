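#' Simulate a toy genome with gene models and a deficiency tiling
#'
#' Places `n_genes` non-overlapping gene spans on a single chromosome (0-based
#' half-open coordinates) and tiles the chromosome with `n_deficiencies`
#' deficiencies sharing `tiling_overlap_fraction` of their length with each
#' neighbour. The tiling is gap-free: every base is deleted by at least one
#' deficiency. One gene (`driver_gene_index`) is the true suppressor locus; a
#' deficiency "deletes" a gene when its span overlaps the gene span by at
#' least one base.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with tibbles `genes` (gene_id, chrom,
#'   start, end, is_ribosomal, is_driver), `deficiencies` (deficiency_id,
#'   chrom, start, end, deletes_driver, n_genes_deleted, genes list-column)
#'   and `genome` (chrom, length).
#' @examples
#' g <- simulate_genome(sim_config(genome_length = 1e4, n_genes = 20,
#'                                 n_deficiencies = 5))
#' g$deficiencies
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  ng <- config$n_genes
  nd <- config$n_deficiencies
  o <- config$tiling_overlap_fraction
  chrom <- "chrS"

  if (nd > 0 && L / (nd * (1 - o) + o) < 1) {
    abort("Impossible tiling: `n_deficiencies` too large for `genome_length`.",
          class = "defsup_config_error")
  }

  genes <- withr::with_seed(derive_seed(config$seed, "genome"), {
    slot <- floor(L / ng)
    slot_start <- floor((seq_len(ng) - 1) * L / ng)
    glen <- pmax(1L, round(runif(ng, 0.3, 0.7) * slot))
    offset <- floor(runif(ng, 0, slot - glen + 1))
    start <- slot_start + offset
    ribo_pool <- setdiff(seq_len(ng), config$driver_gene_index)
    ribo <- sort(sample(ribo_pool, config$ribosomal_gene_count))
    tibble(
      gene_id = sprintf("g%04d", seq_len(ng)),
      chrom = chrom,
      start = start,
      end = start + glen,
      is_ribosomal = seq_len(ng) %in% ribo,
      is_driver = seq_len(ng) == config$driver_gene_index
    )
  })

  if (nd == 0) {
    defs <- tibble(
      deficiency_id = character(), chrom = character(),
      start = numeric(), end = numeric(),
      deletes_driver = logical(), n_genes_deleted = integer(),
      genes = list()
    )
  } else {
    dlen <- L / (nd * (1 - o) + o)
    step <- dlen * (1 - o)
    start <- round((seq_len(nd) - 1) * step)
    end <- round((seq_len(nd) - 1) * step + dlen)
    start[1] <- 0
    end[nd] <- L
    driver <- genes[genes$is_driver, ]
    hit <- purrr::map(seq_len(nd), function(i) {
      genes$gene_id[genes$start < end[i] & genes$end > start[i]]
    })
    defs <- tibble(
      deficiency_id = sprintf("Df%03d", seq_len(nd)),
      chrom = chrom,
      start = start,
      end = end,
      deletes_driver = start < driver$end & end > driver$start,
      n_genes_deleted = lengths(hit),
      genes = hit
    )
  }

  structure(
    list(genes = genes, deficiencies = defs,
         genome = tibble(chrom = chrom, length = L),
         config = config),
    class = "sim_genome"
  )
}

#' Simulate the F1 male counts of one deficiency cross
#'
#' `N` zygotes are allocated to the four genotype classes (mutant;Df,
#' mutant;Bal, balancer;Df, balancer;Bal) by a multinomial draw with equal
#' probability 1/4, mirroring Mendelian segregation of the X-linked mutant and
#' the autosomal deficiency. Survival then thins the mutant classes: the
#' mutant;Df class survives with probability `suppressed_viability` when the
#' deficiency deletes the driver gene and `baseline_viability` otherwise; the
#' mutant;Bal class always survives with `baseline_viability`; balancer
#' classes survive unconditionally.
#'
#' Draws use the current RNG state; [simulate_crosses()] seeds one substream
#' per cross so that adding crosses leaves earlier counts unchanged.
#'
#' @param deficiency One-row data frame with `deficiency_id` and
#'   `deletes_driver`.
#' @param config A [sim_config()].
#' @return One-row tibble: deficiency_id, mut_df, mut_bal, bal_df, bal_bal.
#' @export
simulate_cross <- function(deficiency, config) {
  stopifnot(inherits(config, "sim_config"), nrow(deficiency) == 1)
  N <- config$progeny_per_cross
  v0 <- config$baseline_viability
  v1 <- if (isTRUE(deficiency$deletes_driver)) config$suppressed_viability else v0
  z <- if (N > 0) drop(rmultinom(1, N, rep(0.25, 4))) else rep(0L, 4)
  tibble(
    deficiency_id = deficiency$deficiency_id,
    mut_df = rbinom(1, z[1], v1),
    mut_bal = rbinom(1, z[2], v0),
    bal_df = z[3],
    bal_bal = z[4]
  )
}

#' Simulate all crosses of a screen
#'
#' @param genome A [simulate_genome()] result (or a deficiencies tibble with
#'   `deficiency_id` and `deletes_driver`).
#' @param config A [sim_config()].
#' @return Tibble with one row per deficiency cross:
#'   deficiency_id, mut_df, mut_bal, bal_df, bal_bal.
#' @export
simulate_crosses <- function(genome, config) {
  defs <- if (inherits(genome, "sim_genome")) genome$deficiencies else genome
  if (nrow(defs) == 0) {
    return(tibble(deficiency_id = character(), mut_df = integer(),
                  mut_bal = integer(), bal_df = integer(), bal_bal = integer()))
  }
  purrr::map_dfr(seq_len(nrow(defs)), function(i) {
    withr::with_seed(
      derive_seed(config$seed, "cross", defs$deficiency_id[i]),
      simulate_cross(defs[i, ], config)
    )
  })
}

#' Simulate a gene-level expression count matrix
#'
#' Negative-binomial counts for two conditions (control, mutant) with
#' `n_replicates` biological replicates each. Per-gene baseline means are
#' lognormal (median 100, sdlog 1); the driver gene's mean is multiplied by
#' `nmd_fold_change` in the mutant condition, emulating loss of NMD-mediated
#' degradation; ribosomal genes are flagged and unchanged between conditions.
#' Variance follows mu + dispersion * mu^2 with the shared `nb_dispersion`.
#'
#' @param config A [sim_config()].
#' @param genes Gene catalog tibble from [simulate_genome()].
#' @return Long tibble: gene_id, condition ("control"/"mutant"), replicate,
#'   sample, count, is_ribosomal, is_driver.
#' @export
simulate_expression <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) {
    abort("`nb_dispersion` must be positive.", class = "defsup_config_error")
  }
  ng <- nrow(genes)
  nr <- config$n_replicates
  base_mean <- withr::with_seed(
    derive_seed(config$seed, "expression", "means"),
    rlnorm(ng, meanlog = log(100), sdlog = 1)
  )
  size <- 1 / config$nb_dispersion
  grid <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    condition = c("control", "mutant"),
    replicate = seq_len(nr)
  )
  counts <- purrr::map(seq_len(ng), function(i) {
    mu_ctl <- base_mean[i]
    mu_mut <- if (genes$is_driver[i]) mu_ctl * config$nmd_fold_change else mu_ctl
    withr::with_seed(
      derive_seed(config$seed, "expr", genes$gene_id[i]),
      c(rnbinom(nr, mu = mu_ctl, size = size),
        rnbinom(nr, mu = mu_mut, size = size))
    )
  })
  grid$count <- as.integer(unlist(counts))
  grid |>
    mutate(sample = paste(.data$condition, .data$replicate, sep = "_")) |>
    left_join(select(genes, "gene_id", "is_ribosomal", "is_driver"),
              by = "gene_id") |>
    select("gene_id", "condition", "replicate", "sample", "count",
           "is_ribosomal", "is_driver")
}

#' Simulate mRNA decay time courses after transcription shutoff
#'
#' For each configured half-life `h`, relative expression at t in {0, 1, 2}
#' hours equals `2^(-t/h)` times multiplicative lognormal noise with
#' coefficient of variation `decay_noise_cv`; each replicate curve is then
#' normalized to its own t = 0 value, so relative expression at t = 0 is
#' exactly 1. This mirrors an actinomycin-D shutoff assay read at 0, 1 and 2
#' hours by qPCR relative to the pre-treatment level.
#'
#' @param config A [sim_config()].
#' @param halflives Optional override of `config$decay_halflives`.
#' @return Tibble: curve_id, true_halflife, replicate, time_h, rel_expr.
#' @export
simulate_decay <- function(config, halflives = NULL) {
  stopifnot(inherits(config, "sim_config"))
  hs <- halflives %||% config$decay_halflives
  if (length(hs) == 0) abort("`decay_halflives` is empty.", class = "defsup_config_error")
  if (any(hs <= 0)) abort("half-lives must be positive.", class = "defsup_config_error")
  cv <- config$decay_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  times <- c(0, 1, 2)
  purrr::map_dfr(seq_along(hs), function(j) {
    h <- hs[j]
    purrr::map_dfr(seq_len(config$decay_replicates), function(r) {
      vals <- withr::with_seed(
        derive_seed(config$seed, "decay", j, r),
        2^(-times / h) *
          if (cv > 0) rlnorm(length(times), -sdlog^2 / 2, sdlog) else 1
      )
      tibble(
        curve_id = sprintf("curve_%02d", j),
        true_halflife = h,
        replicate = r,
        time_h = times,
        rel_expr = vals / vals[1]
      )
    })
  })
}

#' Simulate a complete synthetic screen
#'
#' Runs all four generators under one seed and returns every input the
#' pipeline consumes, together with the ground truth.
#'
#' @param config A [sim_config()].
#' @param expression,decay Set `FALSE` to skip the expression or decay
#'   components (the genetic screen alone is much cheaper).
#' @return A list of class `sim_screen`: config, genes, deficiencies, genome,
#'   crosses, expression (or NULL), decay (or NULL), truth (deficiency_id,
#'   deletes_driver) and driver (one-row tibble with the driver gene span).
#' @examples
#' scr <- simulate_screen(sim_config(genome_length = 2e4, n_genes = 20,
#'                                   n_deficiencies = 6, ribosomal_gene_count = 5))
#' scr$crosses
#' @export
simulate_screen <- function(config = sim_config(), expression = TRUE, decay = TRUE) {
  genome <- simulate_genome(config)
  crosses <- simulate_crosses(genome, config)
  expr <- if (isTRUE(expression)) simulate_expression(config, genome$genes) else NULL
  dec <- if (isTRUE(decay)) simulate_decay(config) else NULL
  structure(
    list(
      config = config,
      genes = genome$genes,
      deficiencies = genome$deficiencies,
      genome = genome$genome,
      crosses = crosses,
      expression = expr,
      decay = dec,
      truth = select(genome$deficiencies, "deficiency_id", "deletes_driver"),
      driver = genome$genes[genome$genes$is_driver, ]
    ),
    class = "sim_screen"
  )
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("<sim_screen>\n")
  cat(sprintf("  %d genes on %s (%s bases), %d deficiencies (%d delete the driver)\n",
              nrow(x$genes), x$genome$chrom, format(x$genome$length, big.mark = ","),
              nrow(x$deficiencies), sum(x$deficiencies$deletes_driver)))
  cat(sprintf("  %d crosses of %d progeny; expression: %s; decay curves: %s\n",
              nrow(x$crosses), x$config$progeny_per_cross,
              if (is.null(x$expression)) "none" else
                sprintf("%d genes x %d samples", nrow(x$genes), 2 * x$config$n_replicates),
              if (is.null(x$decay)) "none" else
                as.character(length(unique(x$decay$curve_id)))))
  invisible(x)
}

#' Write a simulated screen to disk in the pipeline's file formats
#'
#' Writes crosses.csv, genes.bed, deficiencies.bed, ribosomal.txt,
#' expression.tsv, decay.tsv and truth.tsv under `dir`.
#'
#' @param sim A [simulate_screen()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_screen_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$crosses, file.path(dir, "crosses.csv"))
  write_bed(
    sim$genes |> rename(name = "gene_id"),
    file.path(dir, "genes.bed")
  )
  write_bed(
    sim$deficiencies |> rename(name = "deficiency_id"),
    file.path(dir, "deficiencies.bed")
  )
  writeLines(sim$genes$gene_id[sim$genes$is_ribosomal],
             file.path(dir, "ribosomal.txt"))
  if (!is.null(sim$expression)) {
    readr::write_tsv(
      select(sim$expression, "gene_id", "condition", "replicate", "count",
             "is_ribosomal"),
      file.path(dir, "expression.tsv")
    )
  }
  if (!is.null(sim$decay)) {
    readr::write_tsv(select(sim$decay, "curve_id", "replicate", "time_h", "rel_expr"),
                     file.path(dir, "decay.tsv"))
  }
  truth <- sim$truth |>
    mutate(driver_chrom = sim$driver$chrom,
           driver_start = sim$driver$start,
           driver_end = sim$driver$end)
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$genome, file.path(dir, "genome.tsv"))
  invisible(dir)
}
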