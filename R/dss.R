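#' Deficiency Suppression Scores from cross count tables
#'
#' For each deficiency, the DSS is the proportion of Df/+ males that are
#' NMD-mutant minus the proportion of Balancer/+ males that are NMD-mutant:
#' `dss = mut_df/(mut_df + bal_df) - mut_bal/(mut_bal + bal_bal)`.
#' The balancer arm controls for each deficiency's general influence on
#' viability; a DSS strictly greater than `threshold` (default 0.1) calls the
#' deficiency a suppressor of mutant lethality.
#'
#' Replicate rows sharing a `deficiency_id` are summed before scoring.
#'
#' @param crosses Data frame with columns deficiency_id, mut_df, mut_bal,
#'   bal_df, bal_bal (counts of F1 males in the four genotype classes).
#' @param threshold Suppressor call cutoff on the DSS scale; default 0.1.
#' @return Tibble with one row per deficiency: deficiency_id, n_df, n_bal,
#'   p_df, p_bal, dss, is_suppressor, threshold.
#' @examples
#' compute_dss(data.frame(deficiency_id = "Df1", mut_df = 30, mut_bal = 9,
#'                        bal_df = 70, bal_bal = 91))
#' @export
compute_dss <- function(crosses, threshold = 0.1) {
  required <- c("deficiency_id", "mut_df", "mut_bal", "bal_df", "bal_bal")
  missing <- setdiff(required, names(crosses))
  if (length(missing)) {
    abort(paste0("`crosses` lacks column(s): ", paste(missing, collapse = ", ")),
          class = "defsup_input_error")
  }
  counts <- crosses[required]
  if (any(counts[-1] < 0, na.rm = TRUE)) {
    abort("Counts must be nonnegative.", class = "defsup_input_error")
  }
  out <- counts |>
    group_by(.data$deficiency_id) |>
    summarise(across(c("mut_df", "mut_bal", "bal_df", "bal_bal"), sum),
              .groups = "drop") |>
    mutate(
      n_df = .data$mut_df + .data$bal_df,
      n_bal = .data$mut_bal + .data$bal_bal
    )
  bad_df <- out$deficiency_id[out$n_df == 0]
  bad_bal <- out$deficiency_id[out$n_bal == 0]
  if (length(bad_df)) {
    abort(paste0("DSS undefined: no Df/+ males scored for ",
                 paste(bad_df, collapse = ", ")),
          class = "defsup_undefined_score")
  }
  if (length(bad_bal)) {
    abort(paste0("DSS undefined: no Balancer/+ males scored for ",
                 paste(bad_bal, collapse = ", ")),
          class = "defsup_undefined_score")
  }
  out |>
    mutate(
      p_df = .data$mut_df / .data$n_df,
      p_bal = .data$mut_bal / .data$n_bal,
      dss = .data$p_df - .data$p_bal,
      is_suppressor = .data$dss > threshold,
      threshold = threshold
    ) |>
    select("deficiency_id", "mut_df", "mut_bal", "bal_df", "bal_bal",
           "n_df", "n_bal", "p_df", "p_bal", "dss", "is_suppressor", "threshold")
}

#' Rank-ordered DSS plot
#'
#' Deficiencies ranked by score with the suppressor cutoff drawn as a dotted
#' line, the conventional display of a whole-screen score distribution.
#'
#' @param dss A [compute_dss()] result.
#' @return A ggplot object.
#' @export
plot_dss <- function(dss) {
  thr <- dss$threshold[1] %||% 0.1
  dss |>
    arrange(dplyr::desc(.data$dss)) |>
    mutate(rank = row_number()) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rank, y = .data$dss,
                                 colour = .data$is_suppressor)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "grey40"),
                                 name = "suppressor") +
    ggplot2::labs(x = "deficiency rank", y = "Deficiency Suppression Score") +
    ggplot2::theme_minimal()
}
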