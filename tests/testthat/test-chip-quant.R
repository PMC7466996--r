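# Build a minimal track by hand: two contigs, explicit start positions.
manual_track <- function(lens = c(chrI = 1000L, plasmid = 200L)) {
  contigs <- lapply(lens, function(L)
    list(length = L, plus = integer(L), minus = integer(L)))
  structure(list(contigs = contigs), class = "read_start_track")
}

add_reads <- function(track, contig, strand, pos0) {
  # pos0: 0-based start positions
  track$contigs[[contig]][[strand]] <-
    track$contigs[[contig]][[strand]] +
    tabulate(pos0 + 1L, nbins = track$contigs[[contig]]$length)
  track
}

test_that("read extension covers the declared intervals and conserves mass", {
  tr <- manual_track()
  tr <- add_reads(tr, "chrI", "plus", 100L)
  cov <- extend_reads(tr, 50)
  expect_equal(which(cov$contigs$chrI > 0), 101:150)  # [100, 150) 0-based
  expect_equal(sum(cov$contigs$chrI), 50)
  # paired starts from one fragment give identical coverage
  tr2 <- manual_track()
  tr2 <- add_reads(tr2, "chrI", "plus", 300L)
  tr2 <- add_reads(tr2, "chrI", "minus", 300L + 120L - 1L)
  cov2 <- extend_reads(tr2, 120)
  expect_equal(unique(cov2$contigs$chrI[301:420]), 2)
  expect_equal(sum(cov2$contigs$chrI > 0), 120)
  # boundary truncation: interior mass only
  tr3 <- add_reads(manual_track(), "chrI", "plus", 990L)
  expect_equal(sum(extend_reads(tr3, 50)$contigs$chrI), 10)
  tr4 <- add_reads(manual_track(), "chrI", "minus", 5L)
  expect_equal(sum(extend_reads(tr4, 50)$contigs$chrI), 6)
})

test_that("fragment length estimation finds the strand offset", {
  tr <- manual_track()
  set.seed(4)
  starts <- sample.int(800, 500, replace = TRUE)
  tr <- add_reads(tr, "chrI", "plus", starts)
  tr <- add_reads(tr, "chrI", "minus", starts + 120L - 1L)
  expect_equal(estimate_fragment_length(tr, 50:300), 119L)
  # identical strand profiles: zero shift
  tr5 <- manual_track()
  tr5 <- add_reads(tr5, "chrI", "plus", starts)
  tr5 <- add_reads(tr5, "chrI", "minus", starts)
  expect_equal(estimate_fragment_length(tr5, 0:300), 0L)
  expect_error(estimate_fragment_length(manual_track()), "no reads")
})

test_that("normalization subtracts background and clips negatives", {
  # catalog with one + strand gene to define a signal region
  cfg <- small_config(n_genes = 2L, gene_len_bp = 1000L,
                      intergenic_bp = 2000L)
  catalog <- gen_gene_catalog(cfg)
  regions <- chip_regions(catalog, upstream = 500)
  expect_equal(regions$end - regions$start, rep(1500L, 2))
  genome_len <- attr(catalog, "genome_len")
  # constructed coverage: background height b everywhere, block of h on
  # the first gene's signal region
  cov <- structure(list(contigs = list(
    chrI = rep(2, genome_len)), total_reads = 5e5),
    class = "coverage_track")
  sig_idx <- (regions$start[1] + 1L):regions$end[1]
  cov$contigs$chrI[sig_idx] <- 10
  norm <- normalize_subtract(cov, regions)
  scale <- 1e6 / 5e5
  expect_equal(unique(norm$contigs$chrI[sig_idx]), (10 - 2) * scale)
  bg_idx <- setdiff(seq_len(genome_len),
                    c(sig_idx, (regions$start[2] + 1L):regions$end[2]))
  expect_true(all(norm$contigs$chrI[bg_idx] == 0))
  # idempotent once the background is zero
  again <- normalize_subtract(norm, regions)
  expect_equal(again$contigs$chrI, norm$contigs$chrI)
  # uniform coverage is pure background: all-zero output
  flat <- structure(list(contigs = list(chrI = rep(3, genome_len)),
                         total_reads = 1e4), class = "coverage_track")
  expect_true(all(normalize_subtract(flat, regions)$contigs$chrI == 0))
})

test_that("promoter binding recovers generating weights end to end", {
  cfg <- small_config(n_genes = 30L, noise_log2_sd = 0,
                      background_rate = 0.01)
  catalog <- gen_gene_catalog(cfg)
  w <- rep(c(1, 2, 4), each = 10)
  tr <- gen_chip_tracks(catalog, cfg, w, plasmid_weight = 0,
                        n_signal_reads = 6e4, seed = 12)
  cov <- extend_reads(tr, cfg$frag_len_bp)
  regions <- chip_regions(catalog)
  norm <- normalize_subtract(cov, regions)
  pb <- promoter_binding(norm, regions)
  grp <- tapply(pb$mean_signal, rep(1:3, each = 10), mean)
  expect_equal(unname(grp[2] / grp[1]), 2, tolerance = 0.1)
  expect_equal(unname(grp[3] / grp[1]), 4, tolerance = 0.1)
  # identical samples correlate perfectly; empty track gives zeros
  expect_equal(cor(pb$mean_signal, promoter_binding(norm, regions)$mean_signal), 1)
  zero <- structure(list(contigs = list(
    chrI = numeric(attr(catalog, "genome_len"))), total_reads = 1),
    class = "coverage_track")
  expect_true(all(promoter_binding(zero, regions)$mean_signal == 0))
})

test_that("plasmid occupancy is the raw plasmid read share", {
  tr <- manual_track()
  tr <- add_reads(tr, "chrI", "plus", rep(1:189, 5))          # 945 reads
  tr <- add_reads(tr, "plasmid", "plus", rep(10L, 30))
  tr <- add_reads(tr, "plasmid", "minus", rep(20L, 25))
  expect_equal(plasmid_occupancy(tr), 55 / 1000)
  only <- add_reads(manual_track(), "plasmid", "plus", 1:10)
  expect_equal(plasmid_occupancy(only), 1)
  none <- add_reads(manual_track(), "chrI", "plus", 1:10)
  expect_equal(plasmid_occupancy(none), 0)
  expect_error(plasmid_occupancy(manual_track()), "no reads")
})
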