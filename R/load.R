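#' Reads-per-million normalization
#'
#' Scales each sample (condition x replicate library) so its counts sum to
#' one million: `rpm = count * 1e6 / library_total`.
#'
#' @param expr Long expression tibble: gene_id, condition, replicate, count
#'   (a `sample` id is derived if absent).
#' @return The tibble with an `rpm` column.
#' @export
rpm_normalize <- function(expr) {
  expr <- as_tibble(expr)
  if (!"sample" %in% names(expr)) {
    expr <- mutate(expr, sample = paste(.data$condition, .data$replicate, sep = "_"))
  }
  totals <- expr |>
    group_by(.data$sample) |>
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample[totals$total == 0]
  if (length(zero)) {
    abort(paste0("Zero-total sample(s): ", paste(zero, collapse = ", ")),
          class = "defsup_input_error")
  }
  expr |>
    left_join(totals, by = "sample") |>
    mutate(rpm = .data$count * 1e6 / .data$total) |>
    select(-"total")
}

#' Rescale mutant samples to the ribosomal reference set
#'
#' NMD loss inflates the mutant library with stabilized transcripts, so equal
#' sequencing depth does not mean equal cellular mRNA. Ribosomal-protein
#' genes are assumed unchanged: the rescale factor is the ratio of mean
#' ribosomal RPM in mutant samples to that in control samples, and every
#' mutant-sample RPM is divided by it. Control samples are untouched; after
#' rescaling the ribosomal means are equal by construction.
#'
#' @param expr_rpm Output of [rpm_normalize()] with an `is_ribosomal` flag.
#' @return The tibble with `rpm` replaced by its rescaled value (the factor
#'   applied is recorded in attribute `ribosomal_factor`).
#' @export
ribosomal_rescale <- function(expr_rpm) {
  if (!"is_ribosomal" %in% names(expr_rpm) || !any(expr_rpm$is_ribosomal)) {
    abort("Ribosomal rescaling needs a non-empty `is_ribosomal` flag set.",
          class = "defsup_input_error")
  }
  ribo <- filter(expr_rpm, .data$is_ribosomal)
  m_mut <- mean(ribo$rpm[ribo$condition == "mutant"])
  m_ctl <- mean(ribo$rpm[ribo$condition == "control"])
  if (!is.finite(m_mut) || !is.finite(m_ctl) || m_mut == 0 || m_ctl == 0) {
    abort("Zero ribosomal signal in a condition; cannot rescale.",
          class = "defsup_input_error")
  }
  f <- m_mut / m_ctl
  out <- mutate(expr_rpm,
                rpm = ifelse(.data$condition == "mutant", .data$rpm / f, .data$rpm))
  attr(out, "ribosomal_factor") <- f
  out
}

#' Per-deficiency genomic expression load
#'
#' Sums rescaled RPM over the genes removed by each deficiency, per sample;
#' averages the regional sums over replicates within each condition; and
#' reports `percent_increase = (load_mutant - load_control) / 1e6`, the
#' mutant excess as a fraction of a one-million-read library. A gene belongs
#' to a deficiency region when its span overlaps the deficiency's inner span
#' (any overlap; `contained = TRUE` demands full containment).
#'
#' @param expr_rescaled Output of [ribosomal_rescale()] (or [rpm_normalize()]
#'   when no rescaling is wanted).
#' @param genes Gene tibble: gene_id, chrom, start, end.
#' @param deficiencies Deficiency tibble: deficiency_id (or id/name), chrom,
#'   start, end.
#' @param contained Require genes fully inside the deficiency span?
#' @param as_fold Report `(load_mutant - load_control) / load_control`
#'   instead of the divide-by-one-million statistic.
#' @return Tibble: deficiency_id, load_control, load_mutant, percent_increase.
#' @export
regional_load <- function(expr_rescaled, genes, deficiencies,
                          contained = FALSE, as_fold = FALSE) {
  defs <- standardize_deficiencies(deficiencies, need_status = FALSE)
  genes <- as_tibble(genes)
  check_intervals(defs, "deficiency span")
  check_intervals(genes, "gene span")
  membership <- purrr::map_dfr(seq_len(nrow(defs)), function(i) {
    g <- genes[genes$chrom == defs$chrom[i], ]
    hit <- if (contained) {
      g$start >= defs$start[i] & g$end <= defs$end[i]
    } else {
      g$start < defs$end[i] & g$end > defs$start[i]
    }
    tibble(deficiency_id = defs$deficiency_id[i], gene_id = g$gene_id[hit])
  })
  empty <- setdiff(defs$deficiency_id, membership$deficiency_id)
  if (length(empty)) {
    warn(paste0("Deficiency region(s) contain no genes (load 0): ",
                paste(empty, collapse = ", ")))
  }
  per_sample <- membership |>
    inner_join(select(expr_rescaled, "gene_id", "condition", "replicate", "rpm"),
               by = "gene_id", relationship = "many-to-many") |>
    group_by(.data$deficiency_id, .data$condition, .data$replicate) |>
    summarise(load = sum(.data$rpm), .groups = "drop")
  loads <- per_sample |>
    group_by(.data$deficiency_id, .data$condition) |>
    summarise(load = mean(.data$load), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "load",
                       names_prefix = "load_") |>
    bind_rows(tibble(deficiency_id = empty, load_control = 0, load_mutant = 0))
  loads |>
    mutate(percent_increase = if (as_fold) {
      (.data$load_mutant - .data$load_control) / .data$load_control
    } else {
      (.data$load_mutant - .data$load_control) / 1e6
    }) |>
    arrange(match(.data$deficiency_id, defs$deficiency_id))
}

#' Correlate suppression strength with regional expression load
#'
#' Pearson correlation between each deficiency's DSS and the percent
#' increase in genomic load across its region, with the t-based significance
#' test `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. A
#' weak correlation indicates suppression is not explained by bulk mRNA
#' load removal.
#'
#' @param dss A [compute_dss()] result (deficiency_id, dss).
#' @param loads A [regional_load()] result (deficiency_id, percent_increase).
#' @return An object of class `dss_load_cor` with elements r, statistic,
#'   p_value, n and the matched data; supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
correlate_dss_load <- function(dss, loads) {
  matched <- inner_join(select(dss, "deficiency_id", "dss"),
                        select(loads, "deficiency_id", "percent_increase"),
                        by = "deficiency_id")
  if (nrow(matched) < 3) {
    abort("Need >= 3 matched deficiencies.", class = "defsup_input_error")
  }
  if (sd(matched$dss) == 0 || sd(matched$percent_increase) == 0) {
    abort("Correlation undefined: zero variance in DSS or load.",
          class = "defsup_undefined_correlation")
  }
  ht <- cor.test(matched$dss, matched$percent_increase, method = "pearson")
  structure(
    list(r = unname(ht$estimate), statistic = unname(ht$statistic),
         p_value = ht$p.value, n = nrow(matched), data = matched),
    class = "dss_load_cor"
  )
}

#' @export
print.dss_load_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation of DSS vs regional load: r = %.3f (n = %d)\n",
              x$r, x$n))
  cat(sprintf("  t = %.3f on %d df, two-sided p = %.3g\n",
              x$statistic, x$n - 2, x$p_value))
  invisible(x)
}

#' @rdname correlate_dss_load
#' @param x,object A `dss_load_cor` object.
#' @param ... Unused.
#' @method tidy dss_load_cor
#' @export
tidy.dss_load_cor <- function(x, ...) {
  tibble(estimate = x$r, statistic = x$statistic,
         p.value = x$p_value, parameter = x$n - 2, method = "pearson")
}

#' @rdname correlate_dss_load
#' @method glance dss_load_cor
#' @export
glance.dss_load_cor <- function(x, ...) {
  tibble(r = x$r, statistic = x$statistic, p.value = x$p_value, n = x$n)
}

#' @rdname correlate_dss_load
#' @method autoplot dss_load_cor
#' @export
autoplot.dss_load_cor <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$percent_increase, y = .data$dss)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(
      x = "percent increase in regional load",
      y = "Deficiency Suppression Score",
      subtitle = sprintf("Pearson r = %.3f, p = %.3g, n = %d",
                         object$r, object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}
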