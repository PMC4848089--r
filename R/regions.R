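# Interval tibbles use 0-based half-open coordinates (BED convention)
# throughout; IRanges is 1-based closed, so shift on the way in and out.
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1, end = end)
from_iranges <- function(ir) {
  tibble(start = as.numeric(IRanges::start(ir)) - 1,
         end = as.numeric(IRanges::end(ir)))
}

check_intervals <- function(x, what = "interval") {
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort(paste0("Malformed ", what, ": require 0 <= start < end."),
          class = "defsup_input_error")
  }
  invisible(x)
}

#' Refine candidate suppressor regions by interval elimination
#'
#' Candidate regions are the genomic intervals deleted only by suppressing
#' deficiencies: per chromosome, the union of suppressor spans minus the
#' union of non-suppressor spans. Eliminating every base touched by a
#' non-suppressing deficiency removes false-positive territory and narrows
#' the candidate intervals around the causal locus. Results are maximal
#' disjoint intervals, sorted by coordinate and labeled 1..k genome-wide;
#' abutting intervals merge, zero-length remnants are dropped.
#'
#' Elimination and support both use the certainly-deleted (inner) spans; when
#' breakpoints are uncertain, supply `outer_start`/`outer_end` for coverage
#' summaries — an uncertainly deleted base neither supports nor eliminates.
#'
#' @param deficiencies Data frame with deficiency_id (or id/name), chrom,
#'   start, end and logical is_suppressor (no missing values).
#' @param min_support Keep only regions overlapped by at least this many
#'   suppressing deficiencies (default 1).
#' @return Tibble: label, chrom, start, end, width, n_support,
#'   supporting_suppressors (list-column of deficiency ids).
#' @examples
#' defs <- tibble::tibble(
#'   deficiency_id = c("a", "b", "c"), chrom = "chr2L",
#'   start = c(0, 50, 0), end = c(100, 150, 40),
#'   is_suppressor = c(TRUE, TRUE, FALSE)
#' )
#' refine_candidate_regions(defs)
#' @export
refine_candidate_regions <- function(deficiencies, min_support = 1) {
  defs <- standardize_deficiencies(deficiencies)
  if (anyNA(defs$is_suppressor)) {
    abort("Every deficiency needs a suppressor status.",
          class = "defsup_input_error")
  }
  check_intervals(defs, "deficiency span")
  sup <- defs[defs$is_suppressor, ]
  non <- defs[!defs$is_suppressor, ]
  if (nrow(sup) == 0) {
    return(tibble(label = integer(), chrom = character(), start = numeric(),
                  end = numeric(), width = numeric(), n_support = integer(),
                  supporting_suppressors = list()))
  }
  out <- purrr::map_dfr(sort(unique(sup$chrom)), function(ch) {
    s <- sup[sup$chrom == ch, ]
    sup_ir <- IRanges::reduce(to_iranges(s$start, s$end))
    non_ch <- non[non$chrom == ch, ]
    cand <- if (nrow(non_ch)) {
      IRanges::setdiff(sup_ir, IRanges::reduce(to_iranges(non_ch$start, non_ch$end)))
    } else sup_ir
    if (length(cand) == 0) return(NULL)
    hits <- IRanges::findOverlaps(cand, to_iranges(s$start, s$end))
    support <- split(s$deficiency_id[S4Vectors::subjectHits(hits)],
                     factor(S4Vectors::queryHits(hits), levels = seq_along(cand)))
    from_iranges(cand) |>
      mutate(chrom = ch,
             supporting_suppressors = unname(lapply(support, as.character)),
             n_support = lengths(.data$supporting_suppressors))
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(label = integer(), chrom = character(), start = numeric(),
                  end = numeric(), width = numeric(), n_support = integer(),
                  supporting_suppressors = list()))
  }
  out |>
    filter(.data$n_support >= min_support) |>
    arrange(.data$chrom, .data$start) |>
    mutate(label = row_number(), width = .data$end - .data$start) |>
    select("label", "chrom", "start", "end", "width", "n_support",
           "supporting_suppressors")
}

#' Fraction of the genome covered by deficiencies
#'
#' Length of the union of deficiency spans divided by total genome length.
#' Maximal (outer) spans are used when present, since coverage asks what
#' could possibly be deleted.
#'
#' @param deficiencies Data frame with chrom, start, end (and optionally
#'   outer_start/outer_end).
#' @param genome Data frame with chrom and length (bases).
#' @return A single fraction in [0, 1].
#' @export
genome_coverage_fraction <- function(deficiencies, genome) {
  defs <- standardize_deficiencies(deficiencies, need_status = FALSE)
  if (all(c("outer_start", "outer_end") %in% names(deficiencies))) {
    defs$start <- deficiencies$outer_start
    defs$end <- deficiencies$outer_end
  }
  if (nrow(defs) == 0) return(0)
  check_intervals(defs, "deficiency span")
  unknown <- setdiff(defs$chrom, genome$chrom)
  if (length(unknown)) {
    abort(paste0("Chromosome(s) absent from genome table: ",
                 paste(unknown, collapse = ", ")), class = "defsup_input_error")
  }
  covered <- sum(purrr::map_dbl(unique(defs$chrom), function(ch) {
    len <- genome$length[match(ch, genome$chrom)]
    d <- defs[defs$chrom == ch, ]
    if (any(d$end > len)) {
      abort(paste0("Deficiency extends beyond end of ", ch, "."),
            class = "defsup_input_error")
    }
    sum(IRanges::width(IRanges::reduce(to_iranges(d$start, d$end))))
  }))
  covered / sum(genome$length)
}

# Accept deficiency tables with id under deficiency_id/id/name.
standardize_deficiencies <- function(x, need_status = TRUE) {
  x <- as_tibble(x)
  id_col <- intersect(c("deficiency_id", "id", "name"), names(x))[1]
  if (is.na(id_col)) {
    abort("Deficiency table needs a deficiency_id/id/name column.",
          class = "defsup_input_error")
  }
  out <- tibble(
    deficiency_id = as.character(x[[id_col]]),
    chrom = as.character(x$chrom),
    start = as.numeric(x$start),
    end = as.numeric(x$end)
  )
  if ("is_suppressor" %in% names(x)) {
    out$is_suppressor <- x$is_suppressor
  } else if (need_status) {
    abort("Every deficiency needs a suppressor status (`is_suppressor`).",
          class = "defsup_input_error")
  }
  out
}

#' Plot deficiencies and candidate regions along a chromosome
#'
#' Suppressing deficiencies in green, non-suppressing in grey, candidate
#' regions as black blocks beneath, optionally with the true driver span.
#'
#' @param deficiencies Deficiency tibble with is_suppressor.
#' @param candidates A [refine_candidate_regions()] result.
#' @param driver Optional one-row tibble with chrom/start/end of the causal
#'   locus.
#' @return A ggplot object.
#' @export
plot_candidate_regions <- function(deficiencies, candidates, driver = NULL) {
  defs <- standardize_deficiencies(deficiencies) |>
    arrange(.data$chrom, .data$start) |>
    mutate(y = row_number())
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = defs,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y,
                   yend = .data$y, colour = .data$is_suppressor),
      linewidth = 1.2
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "grey70"),
                                 name = "suppressor") +
    ggplot2::labs(x = "position (bp)", y = "deficiency") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free") +
    ggplot2::theme_minimal()
  if (nrow(candidates)) {
    p <- p + ggplot2::geom_rect(
      data = candidates,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -1.5, ymax = -0.5, fill = "black"
    )
  }
  if (!is.null(driver)) {
    p <- p + ggplot2::geom_rect(
      data = driver,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -1.5, ymax = -0.5, fill = "red"
    )
  }
  p
}
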