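test_that("identical config and seed reproduce identical outputs", {
  cfg <- small_config(seed = 42L)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$deficiencies, b$deficiencies)
  expect_identical(a$crosses, b$crosses)
  expect_identical(a$expression, b$expression)
  expect_identical(a$decay, b$decay)
})

test_that("adding crosses does not perturb earlier draws", {
  cfg <- small_config(seed = 7L)
  g <- simulate_genome(cfg)
  all10 <- simulate_crosses(g$deficiencies, cfg)
  first5 <- simulate_crosses(g$deficiencies[1:5, ], cfg)
  expect_identical(all10[1:5, ], first5)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(baseline_viability = 0), class = "defsup_config_error")
  expect_error(sim_config(baseline_viability = 0.5, suppressed_viability = 0.2),
               class = "defsup_config_error")
  expect_error(sim_config(genome_length = 10, n_genes = 20),
               class = "defsup_config_error")
  expect_error(sim_config(n_genes = 50, ribosomal_gene_count = 50),
               class = "defsup_config_error")
  expect_error(sim_config(tiling_overlap_fraction = 1), class = "defsup_config_error")
  expect_error(sim_config(nb_dispersion = 0), class = "defsup_config_error")
  expect_error(sim_config(decay_halflives = c(1, -1)), class = "defsup_config_error")
  expect_error(
    simulate_genome(sim_config(genome_length = 100, n_genes = 5,
                               ribosomal_gene_count = 2, n_deficiencies = 500)),
    class = "defsup_config_error"
  )
})

test_that("zero deficiencies yield an empty tiling but a full gene catalog", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 20, n_deficiencies = 0,
                    ribosomal_gene_count = 5)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$deficiencies), 0)
  expect_equal(nrow(g$genes), 20)
})

test_that("gene spans are non-overlapping, half-open and in-bounds", {
  g <- simulate_genome(small_config(seed = 3L))$genes
  expect_true(all(g$start >= 0 & g$start < g$end & g$end <= 5e4))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  expect_equal(sum(g$is_ribosomal), 8)
  expect_equal(sum(g$is_driver), 1)
  expect_false(g$is_ribosomal[g$is_driver])
})

test_that("zero-overlap tiling partitions the genome; tilings are gap-free", {
  cfg0 <- sim_config(genome_length = 1e4, n_genes = 20, n_deficiencies = 10,
                     ribosomal_gene_count = 5, tiling_overlap_fraction = 0)
  d0 <- simulate_genome(cfg0)$deficiencies
  expect_true(all(d0$start[-1] == d0$end[-nrow(d0)]))  # disjoint and abutting
  expect_equal(sum(d0$end - d0$start), 1e4)            # union = sum of lengths

  for (o in c(0, 0.15, 0.5)) {
    cfg <- sim_config(genome_length = 1e4, n_genes = 20, n_deficiencies = 10,
                      ribosomal_gene_count = 5, tiling_overlap_fraction = o)
    d <- simulate_genome(cfg)$deficiencies
    expect_true(all(base_mask(d$start, d$end, 1e4)),
                label = sprintf("every base covered at overlap %.2f", o))
  }
})

test_that("deficiencies list the genes they delete (any overlap)", {
  g <- simulate_genome(small_config(seed = 11L))
  for (i in seq_len(nrow(g$deficiencies))) {
    d <- g$deficiencies[i, ]
    expected <- g$genes$gene_id[g$genes$start < d$end & g$genes$end > d$start]
    expect_identical(d$genes[[1]], expected)
  }
  driver <- g$genes[g$genes$is_driver, ]
  expect_identical(
    g$deficiencies$deletes_driver,
    purrr::map_lgl(g$deficiencies$genes, ~ driver$gene_id %in% .x)
  )
})

test_that("cross counts respect zygote conservation and the no-thinning limit", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 20, n_deficiencies = 4,
                    ribosomal_gene_count = 5, baseline_viability = 1,
                    suppressed_viability = 1, progeny_per_cross = 40000)
  g <- simulate_genome(cfg)
  cr <- simulate_crosses(g, cfg)
  totals <- cr$mut_df + cr$mut_bal + cr$bal_df + cr$bal_bal
  expect_true(all(totals == 40000))  # v0 = v1 = 1: nothing dies
  # each class within 5 sd of N/4
  sdq <- sqrt(40000 * 0.25 * 0.75)
  for (col in c("mut_df", "mut_bal", "bal_df", "bal_bal")) {
    expect_true(all(abs(cr[[col]] - 10000) < 5 * sdq), label = col)
  }

  cfg2 <- small_config(seed = 5L)
  cr2 <- simulate_crosses(simulate_genome(cfg2), cfg2)
  expect_true(all(cr2$mut_df + cr2$mut_bal + cr2$bal_df + cr2$bal_bal <= 2000))
  expect_true(all(as.matrix(cr2[-1]) >= 0))
})

test_that("mean empirical DSS matches the closed-form thinning expectation", {
  # E[DSS] ~ v1/(1+v1) - v0/(1+v0) under multinomial allocation + thinning
  v0 <- 0.1; v1 <- 0.3; N <- 4000; reps <- 200
  cfg <- sim_config(genome_length = 1e4, n_genes = 20, n_deficiencies = 2,
                    ribosomal_gene_count = 5, baseline_viability = v0,
                    suppressed_viability = v1, progeny_per_cross = N, seed = 9L)
  dss <- withr::with_seed(99L, vapply(seq_len(reps), function(i) {
    tab <- simulate_cross(tibble::tibble(deficiency_id = "d", deletes_driver = TRUE), cfg)
    compute_dss(tab)$dss
  }, numeric(1)))
  expected <- v1 / (1 + v1) - v0 / (1 + v0)
  mc_se <- sd(dss) / sqrt(reps)
  expect_lt(abs(mean(dss) - expected), 3 * mc_se + 1e-12)
})

test_that("expression counts carry the configured driver fold change", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 30, n_deficiencies = 2,
                    ribosomal_gene_count = 6, n_replicates = 300,
                    nb_dispersion = 0.1, seed = 21L)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, g$genes)
  drv <- dplyr::filter(ex, is_driver)
  fold <- mean(drv$count[drv$condition == "mutant"]) /
    mean(drv$count[drv$condition == "control"])
  expect_lt(abs(fold - 16.7) / 16.7, 0.15)
  # ribosomal genes unchanged between conditions (ratio of grand means ~ 1)
  ribo <- dplyr::filter(ex, is_ribosomal)
  rf <- mean(ribo$count[ribo$condition == "mutant"]) /
    mean(ribo$count[ribo$condition == "control"])
  expect_lt(abs(rf - 1), 0.1)
})

test_that("a unit fold change makes conditions exchangeable in expectation", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 30, n_deficiencies = 2,
                    ribosomal_gene_count = 6, n_replicates = 200,
                    nmd_fold_change = 1, seed = 22L)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, g$genes)
  drv <- dplyr::filter(ex, is_driver)
  fold <- mean(drv$count[drv$condition == "mutant"]) /
    mean(drv$count[drv$condition == "control"])
  expect_lt(abs(fold - 1), 0.1)
})

test_that("vanishing dispersion approaches the Poisson variance-mean identity", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 5, n_deficiencies = 2,
                    ribosomal_gene_count = 2, n_replicates = 2000,
                    nb_dispersion = 1e-6, seed = 23L)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, g$genes)
  one <- ex$count[ex$gene_id == ex$gene_id[1] & ex$condition == "control"]
  expect_lt(abs(var(one) / mean(one) - 1), 0.2)
})

test_that("decay curves are exact without noise and flat for huge half-lives", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 20, n_deficiencies = 2,
                    ribosomal_gene_count = 5, decay_noise_cv = 0,
                    decay_halflives = c(1, 1e9), decay_replicates = 1)
  d <- simulate_decay(cfg)
  c1 <- d[d$true_halflife == 1, ]
  expect_equal(c1$rel_expr, c(1, 0.5, 0.25))
  c2 <- d[d$true_halflife == 1e9, ]
  expect_equal(c2$rel_expr, c(1, 1, 1), tolerance = 1e-8)
  expect_true(all(d$rel_expr[d$time_h == 0] == 1))
  expect_error(simulate_decay(cfg, halflives = -1), class = "defsup_config_error")
})
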