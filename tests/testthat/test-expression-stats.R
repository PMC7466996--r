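test_that("mean-normalization gives per-condition row means of one", {
  m <- rbind(a = c(1, 2, 4), b = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  lg <- normalize_log2(m)
  expect_equal(unname(lg["a", ]), log2(c(3 / 7, 6 / 7, 12 / 7)))
  expect_equal(unname(lg["b", ]), c(0, 0, 0))
  # two conditions normalized independently
  m2 <- cbind(m, s4 = c(8, 10), s5 = c(2, 30))
  lg2 <- normalize_log2(m2, conditions = c("A", "A", "A", "B", "B"))
  expect_equal(rowMeans(2^lg2[, 1:3]), c(a = 1, b = 1))
  expect_equal(rowMeans(2^lg2[, 4:5]), c(a = 1, b = 1))
  m_bad <- m; m_bad["a", 2] <- 0
  expect_error(normalize_log2(m_bad), "gene a")
})

test_that("growth response recovers constructed slopes exactly", {
  strains <- data.frame(sample_id = paste0("s", 1:5),
                        relative_growth_rate = c(1, 0.9, 0.8, 0.7, 0.6))
  y <- 0.5 * strains$relative_growth_rate + 1
  mat <- rbind(lin = y, flat = rep(2, 5), shift = y + 3)
  colnames(mat) <- strains$sample_id
  gr <- growth_response(mat, strains)
  expect_equal(gr$E_g[gr$gene_id == "lin"], 0.5)
  expect_equal(gr$E_g[gr$gene_id == "flat"], 0)
  # adding a constant leaves the slope unchanged
  expect_equal(gr$E_g[gr$gene_id == "shift"], 0.5)
  expect_equal(gr$stderr[gr$gene_id == "lin"], 0)
  # genes with < 3 informative samples are omitted
  mat2 <- rbind(mat, sparse = c(1, 2, NA, NA, NA))
  expect_message(gr2 <- growth_response(mat2, strains), "omitted")
  expect_false("sparse" %in% gr2$gene_id)
})

test_that("noisy slope recovery: SE scales as sigma over sqrt(n)", {
  strains <- data.frame(sample_id = paste0("s", 1:12),
                        relative_growth_rate = seq(1, 0.67, length.out = 12))
  set.seed(17)
  ests <- replicate(100, {
    y <- matrix(0.8 * strains$relative_growth_rate + rnorm(12, 0, 0.1),
                nrow = 1, dimnames = list("g", strains$sample_id))
    growth_response(y, strains)$E_g
  })
  xc <- strains$relative_growth_rate - mean(strains$relative_growth_rate)
  theo_se <- 0.1 / sqrt(sum(xc^2))
  expect_lt(abs(mean(ests) - 0.8), 3 * theo_se / sqrt(100))
  expect_lt(abs(sd(ests) / theo_se - 1), 0.3)
})

test_that("signature correlation matches the brute-force formula", {
  x <- c(g1 = 1.2, g2 = -0.4, g3 = 0.3, g4 = 2.0, g5 = -1.1)
  y <- c(g1 = 0.8, g2 = 0.1, g3 = -0.2, g4 = 1.4, g5 = -0.9)
  sc <- signature_correlation(x, y)
  expect_equal(sc$r, pearson_brute(x, y))
  expect_equal(sc$n_genes, 5L)
  expect_equal(signature_correlation(x, x)$r, 1)
  expect_equal(signature_correlation(x, -x)$r, -1)
  expect_error(signature_correlation(x[1:2], y[1:2]), "fewer than 3")
  # only shared genes enter
  y2 <- c(y, g9 = 5)
  expect_equal(signature_correlation(x, y2)$n_genes, 5L)
})

test_that("delta is zero under uniform scaling and shifts only intercept", {
  set.seed(3)
  ab <- 10^runif(50, 0, 3)
  uniform <- rep(0.3, 50)
  b <- expression_bias(uniform, ab)
  expect_equal(b$delta[b$subset == "all"], 0)
  sloped <- 0.2 * log10(ab) + rnorm(50, 0, 0.01)
  b1 <- expression_bias(sloped, ab)
  b2 <- expression_bias(sloped, ab * 100)  # x-translation in log space
  expect_equal(b1$delta[1], b2$delta[1])
  expect_equal(b1$delta[1], 0.2, tolerance = 0.05)
})

test_that("burden library delta pipeline has the dead-time signature", {
  cfg <- small_config(n_genes = 800L)
  catalog <- gen_gene_catalog(cfg)
  lib <- gen_burden_library(catalog, cfg)
  wt <- wt_reference_abundance(catalog, cfg$dead_time_s)
  b <- expression_bias(burden_signature(lib), wt, catalog$is_tata)
  d <- function(s) b$delta[b$subset == s]
  expect_lt(d("all") + 3 * b$sem[b$subset == "all"], 0)
  expect_lt(d("TATA"), d("non-TATA"))
  # stronger capacity increase, more negative delta
  cfg_hi <- small_config(n_genes = 800L, capacity_slope = 0.06)
  lib_hi <- gen_burden_library(gen_gene_catalog(cfg_hi), cfg_hi)
  b_hi <- expression_bias(burden_signature(lib_hi), wt)
  expect_lt(b_hi$delta[1], d("all"))
})

test_that("mutant classes separate in the burden-growth plane", {
  cfg <- small_config(n_genes = 500L)
  catalog <- gen_gene_catalog(cfg)
  lib <- gen_burden_library(catalog, cfg)
  eg <- as_profile(growth_response(normalize_log2(lib$expression),
                                   lib$strains))
  comp <- gen_mutant_compendium(catalog, cfg)
  # external growth program: what slow-growth signatures are built from
  growth_prof <- stats::setNames(
    rowMeans(comp$signatures[, comp$mutants$class == "slow_growth"]),
    rownames(comp$signatures))
  plane <- burden_growth_plane(comp$signatures, eg, growth_prof)
  cls <- comp$mutants$class
  expect_gt(min(plane$r_burden[cls == "capacity"]),
            max(plane$r_burden[cls != "capacity"]))
  expect_gt(min(plane$r_growth[cls == "slow_growth"]),
            max(plane$r_growth[cls != "slow_growth"]))
  # null mutants cluster near the origin
  expect_lt(max(abs(plane$r_burden[cls == "null"])), 0.3)
  expect_lt(max(abs(plane$r_growth[cls == "null"])), 0.3)
  # averaging over a list of profiles is the mean of per-profile r
  two <- burden_growth_plane(comp$signatures, list(eg, eg), growth_prof)
  expect_equal(two$r_burden, plane$r_burden)
})

test_that("top and bottom responder sets are ranked and disjoint", {
  prof <- data.frame(gene_id = c("a", "b", "c"), E_g = c(-1, 0, 2))
  tb <- top_bottom_sets(prof, 1)
  expect_equal(tb$top, "c")
  expect_equal(tb$bottom, "a")
  prof2 <- data.frame(gene_id = sprintf("g%03d", 1:40),
                      E_g = rep(c(1, 2), each = 20))
  tb2 <- top_bottom_sets(prof2, 20)
  expect_length(intersect(tb2$top, tb2$bottom), 0)
  expect_length(tb2$top, 20)
  # ties broken lexicographically
  expect_equal(sort(tb2$top), sprintf("g%03d", 21:40))
  expect_error(top_bottom_sets(prof, 2), "half")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  u <- sprintf("g%02d", 1:10)
  res <- enrichment(u[1:5], list(grp = u[1:5]), u)
  expect_equal(res$p_value, 1 / choose(10, 5))  # 1/252
  expect_equal(res$p_value, hyper_tail_enum(10, 5, 5, 5))
  # no overlap: tail at k = 0 is 1
  res0 <- enrichment(u[6:7], list(grp = u[1:2]), u)
  expect_equal(res0$p_value, 1)
  # query = universe: every overlap is the group size, p = 1
  resu <- enrichment(u, list(grp = u[1:4]), u)
  expect_equal(resu$overlap, 4L)
  expect_equal(resu$p_value, 1)
  # BH adjustment across groups
  groups <- list(a = u[1:5], b = u[6:9], c = u[c(1, 6)])
  resm <- enrichment(u[1:5], groups, u)
  expect_equal(resm$p_adjusted, p.adjust(resm$p_value, "BH"))
  expect_error(enrichment(c(u[1], "zz"), groups, u), "outside")
  expect_error(enrichment(u[1], groups, character(0)), "empty universe")
})

test_that("gfp ratio analysis filters, averages, and smooths", {
  set.seed(8)
  ab <- 10^runif(60, 1, 4)
  low <- 100 + ab * 0.5
  # identical libraries: all ratios 1, zero mean increase
  same <- gfp_ratio_trend(low, low, ab, autofluorescence_threshold = 0)
  expect_equal(same$mean_increase_pct, 0)
  expect_true(all(same$table$ratio == 1))
  # uniform 15% increase
  up <- gfp_ratio_trend(1.15 * low, low, ab, autofluorescence_threshold = 0)
  expect_equal(up$mean_increase_pct, 15)
  # sub-threshold proteins are excluded from the mean
  low2 <- c(150, rep(1000, 9))
  high2 <- c(1500, rep(1150, 9))
  ab2 <- rep(1000, 10)
  tr <- gfp_ratio_trend(high2, low2, ab2, autofluorescence_threshold = 200)
  expect_false(tr$table$included[1])
  expect_equal(tr$mean_increase_pct, 15)
  expect_error(gfp_ratio_trend(100, 100, 1, autofluorescence_threshold = 200),
               "threshold")
})
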