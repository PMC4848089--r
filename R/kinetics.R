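#' Fit an exponential decay and half-life to a shutoff time course
#'
#' First-order decay after transcription shutoff: expression follows
#' `E(t) = E0 * exp(-k t)`, so `t1/2 = ln(2) / k`. Replicates are averaged
#' per time point first; the fit is ordinary least squares of
#' `log(mean expression)` against time, matching the short (2-3 point)
#' actinomycin time courses these assays produce. A non-positive fitted rate
#' is reported as a stable transcript (`t_half = Inf`).
#'
#' @param points Data frame with time_h and rel_expr (optionally replicate).
#' @return Object of class `halflife_fit`: k (per hour), t_half (hours),
#'   stable flag, the per-time means and the lm fit. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' fit_halflife(data.frame(time_h = c(0, 1, 2), rel_expr = c(1, 0.5, 0.25)))
#' @export
fit_halflife <- function(points) {
  points <- as_tibble(points)
  if (!all(c("time_h", "rel_expr") %in% names(points))) {
    abort("`points` needs time_h and rel_expr columns.", class = "defsup_input_error")
  }
  if (any(points$rel_expr <= 0)) {
    abort("All relative expression values must be positive.",
          class = "defsup_input_error")
  }
  means <- points |>
    group_by(.data$time_h) |>
    summarise(mean_expr = mean(.data$rel_expr), .groups = "drop") |>
    arrange(.data$time_h)
  if (nrow(means) < 2) {
    abort("Need >= 2 distinct time points.", class = "defsup_input_error")
  }
  fit <- lm(log(mean_expr) ~ time_h, data = means)
  k <- -unname(coef(fit)[2])
  stable <- k <= 0
  structure(
    list(k = k, t_half = if (stable) Inf else log(2) / k,
         stable = stable, means = means, fit = fit),
    class = "halflife_fit"
  )
}

#' @export
print.halflife_fit <- function(x, ...) {
  if (x$stable) {
    cat(sprintf("Stable transcript: fitted rate k = %.4g /h <= 0, t1/2 = Inf\n", x$k))
  } else {
    cat(sprintf("Exponential decay fit: k = %.4g /h, t1/2 = %.4g h (%d time points)\n",
                x$k, x$t_half, nrow(x$means)))
  }
  invisible(x)
}

#' @rdname fit_halflife
#' @param x,object A `halflife_fit` object.
#' @param ... Unused.
#' @method tidy halflife_fit
#' @export
tidy.halflife_fit <- function(x, ...) {
  tibble(term = c("k", "t_half"),
         estimate = c(x$k, x$t_half),
         unit = c("per hour", "hours"))
}

#' @rdname fit_halflife
#' @method glance halflife_fit
#' @export
glance.halflife_fit <- function(x, ...) {
  tibble(k = x$k, t_half = x$t_half, stable = x$stable,
         r.squared = summary(x$fit)$r.squared, n_timepoints = nrow(x$means))
}

#' @rdname fit_halflife
#' @method autoplot halflife_fit
#' @export
autoplot.halflife_fit <- function(object, ...) {
  lab <- if (object$stable) "stable" else sprintf("t[1/2] == %.2g~h", object$t_half)
  grid <- tibble(time_h = seq(min(object$means$time_h),
                              max(object$means$time_h), length.out = 50))
  grid$mean_expr <- exp(predict(object$fit, newdata = grid))
  ggplot2::ggplot(object$means, ggplot2::aes(x = .data$time_h, y = .data$mean_expr)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                      label = lab, parse = !object$stable) +
    ggplot2::labs(x = "time after shutoff (h)", y = "relative expression") +
    ggplot2::theme_minimal()
}

#' Fit half-lives for a table of decay curves
#'
#' @param decay Tibble with curve_id, time_h, rel_expr (e.g. from
#'   [simulate_decay()] or decay.tsv).
#' @return Tibble: curve_id, k, t_half, stable, r.squared, n_timepoints.
#' @export
fit_halflives <- function(decay) {
  decay |>
    group_by(.data$curve_id) |>
    dplyr::group_modify(~ glance(fit_halflife(.x))) |>
    ungroup()
}

#' Reference-normalized relative expression (delta-delta-Ct)
#'
#' qPCR quantification relative to a reference transcript (e.g. RpL32 or
#' Rpl19) and a control condition. With cycle thresholds:
#' `dCt = Ct_target - Ct_reference` per sample, `ddCt` is `dCt` minus the
#' control-condition mean `dCt`, and `fold = 2^-ddCt` (perfect amplification
#' efficiency assumed). Inputs already on the linear scale (`ratio` column)
#' use `fold = (target/ref)_sample / mean (target/ref)_control`.
#'
#' @param tbl Long table with columns sample, condition, gene,
#'   role ("target"/"reference") and ct — or sample, condition, ratio.
#' @param control Name of the control condition (default "control").
#' @return Tibble: sample, condition, fold.
#' @examples
#' qpcr <- tibble::tibble(
#'   sample = rep(c("s1", "s2"), each = 2),
#'   condition = rep(c("control", "mutant"), each = 2),
#'   gene = rep(c("Gadd45", "RpL32"), 2),
#'   role = rep(c("target", "reference"), 2),
#'   ct = c(30, 20, 26, 20)
#' )
#' relative_expression(qpcr)
#' @export
relative_expression <- function(tbl, control = "control") {
  tbl <- as_tibble(tbl)
  if (!control %in% tbl$condition) {
    abort(paste0("Control condition '", control, "' absent."),
          class = "defsup_input_error")
  }
  if ("ratio" %in% names(tbl)) {
    ctl <- mean(tbl$ratio[tbl$condition == control])
    return(tbl |>
             distinct(.data$sample, .data$condition, .data$ratio) |>
             mutate(fold = .data$ratio / ctl) |>
             select("sample", "condition", "fold"))
  }
  if (!all(c("role", "ct") %in% names(tbl))) {
    abort("Need either a `ratio` column or `role` + `ct` columns.",
          class = "defsup_input_error")
  }
  dct <- tbl |>
    group_by(.data$sample, .data$condition, .data$role) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "ct")
  if (!all(c("target", "reference") %in% names(dct)) ||
      anyNA(dct$reference) || anyNA(dct$target)) {
    abort("Missing target or reference measurement for some sample.",
          class = "defsup_input_error")
  }
  dct <- mutate(dct, dct = .data$target - .data$reference)
  ctl_mean <- mean(dct$dct[dct$condition == control])
  dct |>
    mutate(fold = 2^(-(.data$dct - ctl_mean))) |>
    select("sample", "condition", "fold")
}

#' PTC-allele stabilization ratio from a restriction digest gel
#'
#' When a restriction site distinguishes the wild-type allele (cut) from a
#' premature-termination-codon allele (uncut), band intensities report
#' allele mRNA abundance once corrected for fragment length: stain intensity
#' is proportional to mass, so molar signal = intensity / length, with the
#' cut fragments' intensities and lengths summed. The ratio is
#' uncut (PTC) over cut (wild type), optionally normalized to a control
#' condition's ratio.
#'
#' @param cut_intensity Intensities of the cut (wild-type) band(s).
#' @param uncut_intensity Intensity of the uncut (PTC-allele) band.
#' @param cut_lengths Lengths (bp) of the cut fragment(s).
#' @param uncut_length Length (bp) of the uncut fragment.
#' @param control_ratio Optional ratio of the control condition.
#' @return Tibble: ratio, relative_to_control, infinite_ratio flag.
#' @examples
#' allele_ratio_gel(c(700, 500), 2000, c(600, 400), 1000)
#' @export
allele_ratio_gel <- function(cut_intensity, uncut_intensity,
                             cut_lengths, uncut_length, control_ratio = NULL) {
  if (any(c(cut_intensity, uncut_intensity) < 0)) {
    abort("Intensities must be nonnegative.", class = "defsup_input_error")
  }
  if (any(c(cut_lengths, uncut_length) <= 0)) {
    abort("Fragment lengths must be positive.", class = "defsup_input_error")
  }
  molar_cut <- sum(cut_intensity) / sum(cut_lengths)
  molar_uncut <- sum(uncut_intensity) / sum(uncut_length)
  infinite <- molar_cut == 0
  ratio <- if (infinite) Inf else molar_uncut / molar_cut
  tibble(
    ratio = ratio,
    relative_to_control = if (is.null(control_ratio)) NA_real_ else ratio / control_ratio,
    infinite_ratio = infinite
  )
}

#' PTC-allele stabilization ratio from Sanger peak intensities
#'
#' In a heterozygote, the chromatogram peak heights of the two bases at the
#' distinguishing position report relative allele mRNA abundance:
#' ratio = mutant peak / wild-type peak, optionally normalized to a control
#' condition's ratio.
#'
#' @param peak_mut,peak_wt Peak intensities of the PTC and wild-type base.
#' @param control_ratio Optional ratio of the control condition.
#' @return Tibble: ratio, relative_to_control, infinite_ratio flag.
#' @examples
#' allele_ratio_sanger(300, 600)
#' @export
allele_ratio_sanger <- function(peak_mut, peak_wt, control_ratio = NULL) {
  if (any(c(peak_mut, peak_wt) < 0)) {
    abort("Peak intensities must be nonnegative.", class = "defsup_input_error")
  }
  infinite <- peak_wt == 0
  ratio <- if (infinite) Inf else peak_mut / peak_wt
  tibble(
    ratio = ratio,
    relative_to_control = if (is.null(control_ratio)) NA_real_ else ratio / control_ratio,
    infinite_ratio = infinite
  )
}
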