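# Brute-force per-base oracles for interval operations, kept deliberately
# independent of the package's IRanges-based implementation.

# Logical membership mask over a genome of `len` bases (0-based half-open).
base_mask <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  mask
}

# Maximal runs of TRUE as a start/end tibble.
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# Per-base candidate regions: deleted by >=1 suppressor and 0 non-suppressors.
oracle_candidates <- function(defs, len) {
  sup <- defs[defs$is_suppressor, ]
  non <- defs[!defs$is_suppressor, ]
  mask <- base_mask(sup$start, sup$end, len) & !base_mask(non$start, non$end, len)
  mask_to_intervals(mask)
}

oracle_coverage <- function(defs, len) {
  mean(base_mask(defs$start, defs$end, len))
}

# Random deficiency set on a single toy chromosome.
random_deficiencies <- function(n, len, chrom = "chrT") {
  start <- sample.int(len - 1, n, replace = TRUE) - 1
  width <- pmax(1, sample.int(max(1, len %/% 4), n, replace = TRUE))
  tibble::tibble(
    deficiency_id = sprintf("d%03d", seq_len(n)),
    chrom = chrom,
    start = start,
    end = pmin(len, start + width),
    is_suppressor = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

small_config <- function(...) {
  sim_config(genome_length = 5e4, n_genes = 40, n_deficiencies = 10,
             ribosomal_gene_count = 8, progeny_per_cross = 2000, ...)
}
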