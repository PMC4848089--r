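#' Read a BED file of intervals
#'
#' Standard BED: tab-separated chrom, start, end, then optional name, score,
#' strand. Coordinates are 0-based half-open; files in 1-based inclusive
#' convention are converted with `one_based = TRUE` (start - 1). Malformed
#' lines raise a parse error naming the line.
#'
#' @param path BED file path.
#' @param one_based Input uses 1-based inclusive coordinates?
#' @return Tibble: chrom, start, end and whichever of name, score, strand are
#'   present.
#' @export
read_bed <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 fields.",
                  lineno[which(nf < 3)[1]]), class = "defsup_parse_error")
  }
  ncol <- min(nf)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: non-numeric coordinates.",
                  lineno[bad[1]]), class = "defsup_parse_error")
  }
  if (one_based) start <- start - 1
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: require 0 <= start < end.",
                  lineno[bad[1]]), class = "defsup_parse_error")
  }
  out <- tibble(chrom = col(1), start = start, end = end)
  if (ncol >= 4) out$name <- col(4)
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(col(5)))
  if (ncol >= 6) out$strand <- col(6)
  out
}

#' Write intervals to a BED file
#'
#' Writes chrom, start, end, name (from `name`, `deficiency_id` or
#' `gene_id`), score and strand. When the table carries a `dss` column the
#' BED score is `round(dss * 1000)` clamped to [0, 1000] (BED scores are
#' bounded integers), and the exact values are preserved in a sidecar TSV
#' next to the BED file (`<path>.scores.tsv`) unless `sidecar = FALSE`.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @param sidecar Write the exact-score sidecar when `dss` is present?
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, sidecar = TRUE) {
  x <- as_tibble(x)
  check_intervals(x, "record")
  name_col <- intersect(c("name", "deficiency_id", "gene_id"), names(x))[1]
  name <- if (is.na(name_col)) sprintf("feature_%d", seq_len(nrow(x)))
          else as.character(x[[name_col]])
  score <- if ("dss" %in% names(x)) {
    pmin(1000, pmax(0, round(x$dss * 1000)))
  } else if ("score" %in% names(x)) x$score else 0
  bed <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = name, score = score,
                    strand = if ("strand" %in% names(x)) x$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (sidecar && "dss" %in% names(x)) {
    readr::write_tsv(tibble(name = name, dss = x$dss),
                     paste0(path, ".scores.tsv"))
  }
  invisible(path)
}

#' Read a cross count table
#'
#' CSV or TSV with columns deficiency_id, mut_df, mut_bal, bal_df, bal_bal.
#'
#' @param path File path; delimiter inferred from the extension.
#' @return Tibble of cross counts.
#' @export
read_crosses <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  x <- reader(path, show_col_types = FALSE)
  required <- c("deficiency_id", "mut_df", "mut_bal", "bal_df", "bal_bal")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("Cross table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "defsup_parse_error")
  }
  x
}

#' Read a long expression table
#'
#' TSV with columns gene_id, condition, replicate, count and (optionally)
#' is_ribosomal; ribosomal flags may instead come from a one-id-per-line
#' flag file via `ribosomal_path`.
#'
#' @param path expression.tsv path.
#' @param ribosomal_path Optional flag file of ribosomal gene ids.
#' @return Tibble: gene_id, condition, replicate, sample, count, is_ribosomal.
#' @export
read_expression <- function(path, ribosomal_path = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("gene_id", "condition", "replicate", "count")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("Expression table lacks column(s): ",
                 paste(missing, collapse = ", ")), class = "defsup_parse_error")
  }
  if (!is.null(ribosomal_path)) {
    ribo <- readLines(ribosomal_path)
    x$is_ribosomal <- x$gene_id %in% ribo
  } else if (!"is_ribosomal" %in% names(x)) {
    x$is_ribosomal <- FALSE
  }
  mutate(x, sample = paste(.data$condition, .data$replicate, sep = "_"))
}
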