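# A tiny fully hand-computable expression set: 3 genes x 2 conditions x 2
# replicates, gene g3 ribosomal, genes laid out so df1 = {g1, g2}, df2 = {g3}.
toy_genes <- tibble::tibble(
  gene_id = c("g1", "g2", "g3"), chrom = "chrT",
  start = c(0, 100, 200), end = c(50, 150, 250)
)
toy_defs <- tibble::tibble(
  deficiency_id = c("df1", "df2"), chrom = "chrT",
  start = c(0, 200), end = c(160, 260)
)
toy_expr <- function(counts) {
  # counts: named list condition -> replicate -> c(g1, g2, g3)
  purrr::imap_dfr(counts, function(reps, cond) {
    purrr::imap_dfr(reps, function(v, r) {
      tibble::tibble(gene_id = c("g1", "g2", "g3"), condition = cond,
                     replicate = as.integer(r), count = v,
                     is_ribosomal = c(FALSE, FALSE, TRUE))
    })
  })
}

test_that("RPM normalization conserves per-sample totals and scale", {
  ex <- toy_expr(list(control = list(`1` = c(10, 30, 60), `2` = c(20, 20, 60)),
                      mutant = list(`1` = c(50, 30, 20), `2` = c(40, 40, 20))))
  rpm <- rpm_normalize(ex)
  sums <- rpm |> dplyr::group_by(sample) |> dplyr::summarise(s = sum(rpm))
  expect_true(all(abs(sums$s - 1e6) < 1e-6))
  expect_equal(rpm$rpm[rpm$gene_id == "g1" & rpm$sample == "control_1"],
               10 / 100 * 1e6)
  # doubling all counts in one sample leaves its RPM unchanged
  doubled <- ex |>
    dplyr::mutate(count = ifelse(condition == "control" & replicate == 1,
                                 count * 2L, count))
  expect_equal(rpm_normalize(doubled)$rpm, rpm$rpm)
})

test_that("a zero-total sample is reported by name", {
  ex <- toy_expr(list(control = list(`1` = c(0, 0, 0)),
                      mutant = list(`1` = c(1, 1, 1))))
  expect_error(rpm_normalize(ex), regexp = "control_1",
               class = "defsup_input_error")
})

test_that("ribosomal rescaling equalizes the reference means", {
  # mutant ribosomal RPM is exactly 2x control -> mutant values halved
  ex <- toy_expr(list(control = list(`1` = c(45, 30, 25)),
                      mutant = list(`1` = c(25, 25, 50))))
  rpm <- rpm_normalize(ex)
  scaled <- ribosomal_rescale(rpm)
  expect_equal(attr(scaled, "ribosomal_factor"), 2)
  mut <- scaled$rpm[scaled$condition == "mutant"]
  expect_equal(mut, rpm$rpm[rpm$condition == "mutant"] / 2)
  expect_equal(scaled$rpm[scaled$condition == "control"],
               rpm$rpm[rpm$condition == "control"])
  # fixed point: ribosomal means now equal
  ribo <- scaled[scaled$is_ribosomal, ]
  expect_equal(mean(ribo$rpm[ribo$condition == "mutant"]),
               mean(ribo$rpm[ribo$condition == "control"]))
  # balanced signal -> identity
  bal <- rpm_normalize(toy_expr(list(control = list(`1` = c(30, 30, 40)),
                                     mutant = list(`1` = c(35, 25, 40)))))
  expect_equal(ribosomal_rescale(bal)$rpm, bal$rpm)
  expect_error(ribosomal_rescale(dplyr::mutate(rpm, is_ribosomal = FALSE)),
               class = "defsup_input_error")
})

test_that("regional load reproduces a hand-computed worked example", {
  # control r1: totals 100 -> RPM per count x 1e4; mutant r1 total 200
  ex <- toy_expr(list(control = list(`1` = c(10, 30, 60), `2` = c(20, 20, 60)),
                      mutant = list(`1` = c(80, 60, 60), `2` = c(70, 40, 40))))
  chain <- ex |> rpm_normalize() |> ribosomal_rescale()
  # hand chain: RPM control r1 = (1e5, 3e5, 6e5), r2 = (2e5, 2e5, 6e5)
  # mutant r1 = (4e5, 3e5, 3e5), r2 ~ (70,40,40)/150 x 1e6
  # ribosomal factor f = mean(3e5, 40/150*1e6) / mean(6e5, 6e5)
  f <- mean(c(3e5, 40 / 150 * 1e6)) / 6e5
  load <- regional_load(chain, toy_genes, toy_defs)
  ctl_df1 <- mean(c(1e5 + 3e5, 2e5 + 2e5))
  mut_df1 <- mean(c(4e5 + 3e5, (70 + 40) / 150 * 1e6) / f)
  expect_equal(load$load_control[load$deficiency_id == "df1"], ctl_df1)
  expect_equal(load$load_mutant[load$deficiency_id == "df1"], mut_df1)
  expect_equal(load$percent_increase[load$deficiency_id == "df1"],
               (mut_df1 - ctl_df1) / 1e6)
  # the as-fold alternative view
  fold <- regional_load(chain, toy_genes, toy_defs, as_fold = TRUE)
  expect_equal(fold$percent_increase[1], (mut_df1 - ctl_df1) / ctl_df1)
})

test_that("identical conditions give zero percent increase everywhere", {
  ex <- toy_expr(list(control = list(`1` = c(10, 30, 60)),
                      mutant = list(`1` = c(10, 30, 60))))
  load <- ex |> rpm_normalize() |> ribosomal_rescale() |>
    regional_load(toy_genes, toy_defs)
  expect_equal(load$percent_increase, c(0, 0))
})

test_that("loads add over a split region and empty regions warn with load 0", {
  ex <- toy_expr(list(control = list(`1` = c(10, 30, 60)),
                      mutant = list(`1` = c(30, 30, 40))))
  chain <- ex |> rpm_normalize() |> ribosomal_rescale()
  whole <- regional_load(chain, toy_genes, toy_defs)
  halves <- tibble::tibble(deficiency_id = c("h1", "h2"), chrom = "chrT",
                           start = c(0, 60), end = c(60, 160))
  split <- regional_load(chain, toy_genes, halves)
  expect_equal(sum(split$load_control), whole$load_control[1])
  expect_equal(sum(split$load_mutant), whole$load_mutant[1])

  gap <- tibble::tibble(deficiency_id = "empty", chrom = "chrT",
                        start = 160, end = 190)
  expect_warning(res <- regional_load(chain, toy_genes, gap), regexp = "empty")
  expect_equal(res$load_control, 0)
  expect_equal(res$percent_increase, 0)
})

test_that("gene membership honours the containment flag", {
  straddler <- tibble::tibble(deficiency_id = "d", chrom = "chrT",
                              start = 120, end = 260)
  ex <- toy_expr(list(control = list(`1` = c(10, 30, 60)),
                      mutant = list(`1` = c(10, 30, 60))))
  chain <- ex |> rpm_normalize() |> ribosomal_rescale()
  any_ol <- regional_load(chain, toy_genes, straddler)   # g2 overlaps, g3 inside
  cont <- regional_load(chain, toy_genes, straddler, contained = TRUE)  # g3 only
  expect_gt(any_ol$load_control, cont$load_control)
  expect_equal(cont$load_control, 6e5)
})

test_that("swapping RPM and rescale stages matters unless the factor is 1", {
  ex <- toy_expr(list(control = list(`1` = c(45, 30, 25)),
                      mutant = list(`1` = c(25, 25, 50))))
  proper <- ex |> rpm_normalize() |> ribosomal_rescale()
  # rescale on raw counts first, then RPM: RPM renormalizes the rescale away
  swapped <- ex |>
    dplyr::mutate(rpm = count) |> ribosomal_rescale() |>
    dplyr::mutate(count = rpm) |> dplyr::select(-rpm) |> rpm_normalize()
  expect_false(isTRUE(all.equal(proper$rpm, swapped$rpm)))

  bal <- toy_expr(list(control = list(`1` = c(30, 30, 40)),
                       mutant = list(`1` = c(35, 25, 40))))
  proper_b <- bal |> rpm_normalize() |> ribosomal_rescale()
  swapped_b <- bal |>
    dplyr::mutate(rpm = count) |> ribosomal_rescale() |>
    dplyr::mutate(count = rpm) |> dplyr::select(-rpm) |> rpm_normalize()
  expect_equal(proper_b$rpm, swapped_b$rpm)
})

test_that("Pearson correlation matches the closed formula and edge cases", {
  dss <- tibble::tibble(deficiency_id = c("a", "b", "c"), dss = c(0, 1, 2))
  loads <- tibble::tibble(deficiency_id = c("a", "b", "c"),
                          percent_increase = c(0, 1, 4))
  res <- correlate_dss_load(dss, loads)
  x <- c(0, 1, 2); y <- c(0, 1, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand)
  expect_equal(res$statistic, r_hand * sqrt((3 - 2) / (1 - r_hand^2)))
  expect_equal(res$p_value,
               2 * stats::pt(abs(res$statistic), 1, lower.tail = FALSE))
  g <- glance(res)
  expect_equal(g$r, r_hand)

  collinear <- correlate_dss_load(
    dss, tibble::tibble(deficiency_id = c("a", "b", "c"),
                        percent_increase = c(0, 2, 4))
  )
  expect_equal(collinear$r, 1)
  expect_lt(collinear$p_value, 1e-8)

  expect_error(correlate_dss_load(dss[1:2, ], loads[1:2, ]),
               class = "defsup_input_error")
  expect_error(
    correlate_dss_load(dplyr::mutate(dss, dss = 1), loads),
    class = "defsup_undefined_correlation"
  )
})

test_that("load is null-centred when no deficiency touches the driver", {
  # deficiencies tile only the left half; driver sits on the right
  rs <- withr::with_seed(301L, vapply(1:30, function(i) {
    cfg <- sim_config(genome_length = 8e4, n_genes = 80, n_deficiencies = 16,
                      ribosomal_gene_count = 16, driver_gene_index = 80,
                      n_replicates = 2, seed = 300L + i)
    g <- simulate_genome(cfg)
    defs <- dplyr::filter(g$deficiencies, end <= 4e4)
    ex <- simulate_expression(cfg, g$genes)
    load <- ex |> rpm_normalize() |> ribosomal_rescale() |>
      regional_load(g$genes, defs)
    dss <- tibble::tibble(deficiency_id = defs$deficiency_id,
                          dss = withr::with_seed(600L + i, runif(nrow(defs))))
    correlate_dss_load(dss, load)$r
  }, numeric(1)))
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("driver-deleting deficiencies carry the larger load increase", {
  cfg <- sim_config(genome_length = 5e4, n_genes = 60, n_deficiencies = 10,
                    ribosomal_gene_count = 12, n_replicates = 2, seed = 88L)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, g$genes)
  load <- ex |> rpm_normalize() |> ribosomal_rescale() |>
    regional_load(g$genes, g$deficiencies)
  joined <- dplyr::inner_join(load,
                              g$deficiencies[c("deficiency_id", "deletes_driver")],
                              by = "deficiency_id")
  expect_gt(min(joined$percent_increase[joined$deletes_driver]),
            max(joined$percent_increase[!joined$deletes_driver]))
})
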