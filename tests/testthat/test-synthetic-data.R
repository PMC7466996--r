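test_that("gene catalog honors counts, determinism, and the TATA tail", {
  cfg <- small_config(n_genes = 100L, tata_fraction = 0.2)
  cat1 <- gen_gene_catalog(cfg)
  expect_equal(nrow(cat1), 100L)
  expect_equal(sum(cat1$is_tata), 20L)
  expect_identical(cat1, gen_gene_catalog(small_config(n_genes = 100L,
                                                       tata_fraction = 0.2)))
  # TATA genes come from the upper attempt-rate tail
  expect_gt(min(cat1$attempt_rate[cat1$is_tata]),
            stats::quantile(cat1$attempt_rate, 0.5))
  # strand-aware promoter-to-terminator order
  plus <- cat1$strand == "+"
  expect_true(all(cat1$tss[plus] < cat1$tts[plus]))
  expect_true(all(cat1$tss[!plus] > cat1$tts[!plus]))
  # degenerate spectrum
  flat <- gen_gene_catalog(small_config(abundance_log_sd = 0))
  expect_equal(length(unique(flat$attempt_rate)), 1L)
  expect_error(gen_gene_catalog(small_config(n_genes = 0L)), "empty")
})

test_that("burden library follows the dead-time mean-field model", {
  cfg <- small_config(noise_log2_sd = 0)
  catalog <- gen_gene_catalog(cfg)
  # no burden, no noise: identical strains
  lib_flat <- gen_burden_library(catalog, small_config(noise_log2_sd = 0,
                                                       capacity_slope = 0))
  expect_true(all(lib_flat$expression == lib_flat$expression[, 1]))
  # tau = 0: pure global scaling by g(c)
  cfg0 <- small_config(noise_log2_sd = 0, dead_time_s = 0)
  lib0 <- gen_burden_library(gen_gene_catalog(cfg0), cfg0)
  g20 <- 1 + cfg0$capacity_slope * 20
  expect_equal(lib0$expression[, "copy20"] / lib0$expression[, "copy00"],
               rep(g20, nrow(catalog)), ignore_attr = TRUE)
  # tau > 0: fold change decreasing in attempt rate, below g
  lib <- gen_burden_library(catalog, cfg)
  fc <- lib$expression[, "copy20"] / lib$expression[, "copy00"]
  g <- 1 + cfg$capacity_slope * 20
  expect_true(all(fc < g & fc > 1))
  ord <- order(catalog$attempt_rate)
  expect_true(all(diff(fc[ord]) <= 1e-12))
  # analytic fold-change oracle, gene by gene
  a <- catalog$attempt_rate
  tau <- cfg$dead_time_s
  expect_equal(unname(fc),
               (g * a / (1 + g * a * tau)) / (a / (1 + a * tau)))
  # strain table: linear growth loss and size gain
  expect_equal(lib$strains$relative_growth_rate,
               1 - cfg$growth_slope * lib$strains$copy_number)
  expect_equal(lib$strains$relative_size,
               1 + cfg$size_slope * lib$strains$copy_number)
  expect_error(
    gen_burden_library(catalog, small_config(growth_slope = 0.06)),
    "negative growth")
})

test_that("mutant compendium carries its three truth classes", {
  cfg <- small_config(n_mutants = 12L)
  catalog <- gen_gene_catalog(cfg)
  comp <- gen_mutant_compendium(catalog, cfg, noise_log2_sd = 0)
  expect_equal(ncol(comp$signatures), 12L)
  expect_setequal(unique(comp$mutants$class),
                  c("capacity", "slow_growth", "null"))
  # null mutants at zero noise: all-zero signatures
  nulls <- comp$signatures[, comp$mutants$class == "null", drop = FALSE]
  expect_true(all(nulls == 0))
  # slow-growth mutants share one program: pairwise r = 1 at zero noise
  slows <- comp$signatures[, comp$mutants$class == "slow_growth"]
  expect_equal(min(cor(slows)), 1)
  # capacity mutant (g < 1): signature slope vs log abundance is positive
  # (near-saturated genes drop least when capacity falls)
  wt <- wt_reference_abundance(catalog, cfg$dead_time_s)
  caps <- which(comp$mutants$class == "capacity")
  pmb <- per_mutant_bias(comp$signatures[, caps, drop = FALSE], wt,
                         comp$mutants$relative_growth_rate[caps])
  expect_true(all(pmb$delta > 0))
})

test_that("competition series follow the stated log2-odds dynamics", {
  flat <- gen_competition_series(0, n_timepoints = 5, f0 = 0.4,
                                 noise_sd = 0, seed = 1)
  expect_equal(flat$f_wt, rep(0.4, 5))
  s <- gen_competition_series(0.05, n_timepoints = 6,
                              generations_per_interval = 2, f0 = 0.5,
                              noise_sd = 0, seed = 1)
  lo <- log2(s$f_wt / (1 - s$f_wt))
  expect_equal(diff(lo), rep(0.05 * 2, 5))
  expect_error(gen_competition_series(0, f0 = 1), "f0")
})

test_that("spike-in counts scale with true mRNA content", {
  s <- gen_spikein_counts(c(1, 1, 2), cells = c(10, 10, 10),
                          spike_ratio_constant = 10, depth = 4e5, seed = 3)
  v <- total_mrna_per_cell(s)
  expect_equal(v[2] / v[1], 1, tolerance = 0.02)
  expect_equal(v[3] / v[1], 2, tolerance = 0.02)
})

test_that("chip tracks place strand starts a fragment apart", {
  cfg <- small_config(n_genes = 3L, background_rate = 0)
  catalog <- gen_gene_catalog(cfg)
  tr <- gen_chip_tracks(catalog, cfg, c(1, 0, 0), plasmid_weight = 0,
                        n_signal_reads = 2e4, jitter_sd = 0, seed = 2)
  chr <- tr$contigs$chrI
  expect_equal(which.max(chr$minus) - which.max(chr$plus),
               cfg$frag_len_bp - 1L)
  expect_equal(sum(tr$contigs$plasmid$plus) + sum(tr$contigs$plasmid$minus),
               0)
  expect_equal(track_total_reads(tr), 2e4)
})
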