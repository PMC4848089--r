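#' Run the full suppressor-screen analysis
#'
#' Chains the pipeline in screen order: score crosses (DSS), call suppressors
#' at the threshold, refine candidate regions by non-suppressor elimination,
#' and — when expression data are supplied — compute the per-deficiency
#' genomic load and its Pearson correlation with the DSS. When ground truth
#' from the simulator is supplied, the report additionally contains the
#' sensitivity and specificity of the suppressor calls and whether the driver
#' gene lies inside a candidate region.
#'
#' The pipeline is deterministic given its inputs; randomness lives entirely
#' in the generator.
#'
#' @param crosses Cross count tibble (see [compute_dss()]).
#' @param deficiencies Deficiency interval tibble (deficiency_id, chrom,
#'   start, end).
#' @param genome Optional genome-size tibble (chrom, length) for the coverage
#'   fraction.
#' @param genes,expression Optional gene intervals + long expression table for
#'   the load computation.
#' @param truth Optional ground truth (deficiency_id, deletes_driver).
#' @param driver Optional one-row tibble with the driver gene span.
#' @param threshold DSS suppressor cutoff (default 0.1).
#' @param min_support,contained,as_fold Passed to the refinement and load
#'   stages.
#' @return Object of class `screen_report`; supports [tidy()] (candidate
#'   regions) and [glance()] (one-row summary).
#' @examples
#' scr <- simulate_screen(sim_config(genome_length = 5e4, n_genes = 40,
#'                                   n_deficiencies = 10, ribosomal_gene_count = 8,
#'                                   progeny_per_cross = 1000))
#' rep <- run_screen(scr$crosses, scr$deficiencies, genome = scr$genome,
#'                   genes = scr$genes, expression = scr$expression,
#'                   truth = scr$truth, driver = scr$driver)
#' glance(rep)
#' @export
run_screen <- function(crosses, deficiencies,
                       genome = NULL, genes = NULL, expression = NULL,
                       truth = NULL, driver = NULL,
                       threshold = 0.1, min_support = 1,
                       contained = FALSE, as_fold = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
            class = "defsup_stage_error", parent = e)
    })
  }
  empty <- is.null(crosses) || nrow(crosses) == 0
  if (empty) {
    dss <- tibble(deficiency_id = character(), dss = numeric(),
                  is_suppressor = logical())
    scored_defs <- tibble(deficiency_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          is_suppressor = logical())
    candidates <- refine_candidate_regions(scored_defs, min_support)
  } else {
    dss <- stage("score", compute_dss(crosses, threshold))
    scored_defs <- stage("refine-join", {
      defs <- standardize_deficiencies(deficiencies, need_status = FALSE)
      inner_join(defs, select(dss, "deficiency_id", "dss", "is_suppressor"),
                 by = "deficiency_id")
    })
    candidates <- stage("refine", refine_candidate_regions(scored_defs, min_support))
  }
  coverage <- if (!is.null(genome) && nrow(scored_defs)) {
    stage("coverage", genome_coverage_fraction(scored_defs, genome))
  } else NA_real_

  loads <- correlation <- NULL
  if (!is.null(expression) && !is.null(genes) && !empty) {
    loads <- stage("load", {
      expression |>
        rpm_normalize() |>
        ribosomal_rescale() |>
        regional_load(genes, scored_defs, contained = contained, as_fold = as_fold)
    })
    correlation <- stage("correlate", correlate_dss_load(dss, loads))
  }

  recovery <- NULL
  if (!is.null(truth) && !empty) {
    calls <- left_join(truth, select(dss, "deficiency_id", "is_suppressor"),
                       by = "deficiency_id")
    tp <- sum(calls$deletes_driver & calls$is_suppressor, na.rm = TRUE)
    fn <- sum(calls$deletes_driver & !calls$is_suppressor, na.rm = TRUE)
    fp <- sum(!calls$deletes_driver & calls$is_suppressor, na.rm = TRUE)
    tn <- sum(!calls$deletes_driver & !calls$is_suppressor, na.rm = TRUE)
    driver_regions <- if (!is.null(driver) && nrow(candidates)) {
      sum(candidates$chrom == driver$chrom &
            candidates$start <= driver$start &
            candidates$end >= driver$end)
    } else 0L
    recovery <- list(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      true_positives = tp, false_negatives = fn,
      false_positives = fp, true_negatives = tn,
      driver_in_candidate = driver_regions == 1L,
      n_driver_regions = as.integer(driver_regions)
    )
  }

  structure(
    list(
      n_deficiencies = nrow(dss),
      n_suppressors = sum(dss$is_suppressor),
      threshold = threshold,
      coverage_fraction = coverage,
      dss = dss,
      candidates = candidates,
      loads = loads,
      correlation = correlation,
      recovery = recovery
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  deficiencies screened: %d; suppressors (DSS > %.3g): %d\n",
              x$n_deficiencies, x$threshold, x$n_suppressors))
  if (!is.na(x$coverage_fraction)) {
    cat(sprintf("  genome coverage: %.1f%%\n", 100 * x$coverage_fraction))
  }
  cat(sprintf("  candidate regions: %d\n", nrow(x$candidates)))
  if (!is.null(x$correlation)) {
    cat(sprintf("  DSS vs load: r = %.3f, p = %.3g (n = %d)\n",
                x$correlation$r, x$correlation$p_value, x$correlation$n))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  suppressor calls: sensitivity %.2f, specificity %.2f\n",
                x$recovery$sensitivity, x$recovery$specificity))
    cat(sprintf("  driver in exactly one candidate region: %s\n",
                x$recovery$driver_in_candidate))
  }
  invisible(x)
}

#' @rdname run_screen
#' @param x,object A `screen_report`.
#' @param ... Unused.
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) x$candidates

#' @rdname run_screen
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  tibble(
    n_deficiencies = x$n_deficiencies,
    n_suppressors = x$n_suppressors,
    threshold = x$threshold,
    coverage_fraction = x$coverage_fraction,
    n_candidates = nrow(x$candidates),
    r_dss_load = if (is.null(x$correlation)) NA_real_ else x$correlation$r,
    p_dss_load = if (is.null(x$correlation)) NA_real_ else x$correlation$p_value,
    sensitivity = if (is.null(x$recovery)) NA_real_ else x$recovery$sensitivity,
    specificity = if (is.null(x$recovery)) NA_real_ else x$recovery$specificity,
    driver_in_candidate = if (is.null(x$recovery)) NA else x$recovery$driver_in_candidate
  )
}

#' Run the screen pipeline from files on disk
#'
#' File-based front end to [run_screen()], matching the formats written by
#' [write_screen_data()]: crosses.csv, deficiencies.bed, and optionally
#' genome.tsv, genes.bed, expression.tsv (+ ribosomal.txt) and truth.tsv.
#' Paths and flags may come from a YAML config (`config` entries with the
#' argument names below); explicit arguments override the config.
#'
#' @param crosses,deficiencies,genome,genes,expression,ribosomal,truth File
#'   paths (NULL to skip the optional stages).
#' @param config Optional YAML file of the same arguments.
#' @param threshold,min_support,contained,as_fold,one_based Pipeline flags.
#' @return A `screen_report`.
#' @export
run_screen_files <- function(crosses = NULL, deficiencies = NULL,
                             genome = NULL, genes = NULL, expression = NULL,
                             ribosomal = NULL, truth = NULL, config = NULL,
                             threshold = 0.1, min_support = 1,
                             contained = FALSE, as_fold = FALSE,
                             one_based = FALSE) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    pick <- function(arg, val) val %||% cfg[[arg]]
    crosses <- pick("crosses", crosses); deficiencies <- pick("deficiencies", deficiencies)
    genome <- pick("genome", genome); genes <- pick("genes", genes)
    expression <- pick("expression", expression); ribosomal <- pick("ribosomal", ribosomal)
    truth <- pick("truth", truth)
    threshold <- cfg$threshold %||% threshold
    min_support <- cfg$min_support %||% min_support
    contained <- cfg$contained %||% contained
    as_fold <- cfg$as_fold %||% as_fold
    one_based <- cfg$one_based %||% one_based
  }
  if (is.null(crosses) || is.null(deficiencies)) {
    abort("`crosses` and `deficiencies` paths are required.",
          class = "defsup_input_error")
  }
  cross_tbl <- read_crosses(crosses)
  def_tbl <- read_bed(deficiencies, one_based = one_based)
  genome_tbl <- if (!is.null(genome)) readr::read_tsv(genome, show_col_types = FALSE)
  gene_tbl <- if (!is.null(genes)) {
    read_bed(genes, one_based = one_based) |> rename(gene_id = "name")
  }
  expr_tbl <- if (!is.null(expression)) read_expression(expression, ribosomal)
  truth_tbl <- driver_tbl <- NULL
  if (!is.null(truth)) {
    tt <- readr::read_tsv(truth, show_col_types = FALSE)
    truth_tbl <- select(tt, "deficiency_id", "deletes_driver")
    if (all(c("driver_chrom", "driver_start", "driver_end") %in% names(tt))) {
      driver_tbl <- tibble(chrom = tt$driver_chrom[1],
                           start = tt$driver_start[1], end = tt$driver_end[1])
    }
  }
  run_screen(cross_tbl, def_tbl, genome = genome_tbl, genes = gene_tbl,
             expression = expr_tbl, truth = truth_tbl, driver = driver_tbl,
             threshold = threshold, min_support = min_support,
             contained = contained, as_fold = as_fold)
}

#' Serialize a screen report to JSON
#'
#' @param report A `screen_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    n_deficiencies = report$n_deficiencies,
    n_suppressors = report$n_suppressors,
    threshold = report$threshold,
    coverage_fraction = report$coverage_fraction,
    candidates = report$candidates |>
      mutate(supporting_suppressors =
               purrr::map_chr(.data$supporting_suppressors, paste, collapse = ",")),
    correlation = if (!is.null(report$correlation)) glance(report$correlation),
    recovery = report$recovery
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
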