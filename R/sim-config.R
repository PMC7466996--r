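#' Configuration of the synthetic burden-study generators
#'
#' One object holds every knob of the synthetic data: the gene catalog
#' (attempt-rate spectrum, TATA fraction, decay), the burden library
#' (copy numbers, per-copy capacity/growth/size slopes, measurement
#' noise), the mutant compendium size, and the ChIP/plasmid geometry.
#' Identical configs (including `seed`) reproduce identical outputs.
#'
#' Defaults emulate the study conditions of a tandem-integration burden
#' library: 0-20 copies of a strong-promoter reporter, a linear ~-30%
#' growth loss and ~+50% size gain at 20 copies, a global
#' transcription-capacity scale-up reaching ~1.75x at 20 copies (the
#' magnitude of the total-mRNA increase seen in heavily burdened
#' cells), a dead time of 1.05 s (35 bp polymerase footprint at
#' 2 kb/min elongation), and a log-normal attempt-rate spectrum whose
#' upper tail reaches saturation (`a * tau ~ 1`) where the TATA/bursty
#' genes sit.
#'
#' @param seed Integer seed; all generators derive their randomness
#'   from it.
#' @param n_genes Number of genes in the catalog.
#' @param tata_fraction Fraction of genes flagged TATA, in `[0, 1]`.
#' @param abundance_log_mean,abundance_log_sd Natural-log mean/sd of the
#'   log-normal attempt-rate spectrum (attempts/s).
#' @param dead_time_s Promoter-clearance dead time tau, seconds.
#' @param copy_numbers Reporter copy numbers of the library strains
#'   (non-negative integers, including 0 = wild type).
#' @param capacity_slope Global attempt-rate scale-up per copy:
#'   `g(c) = 1 + capacity_slope * c`.
#' @param growth_slope Relative growth rate lost per copy.
#' @param size_slope Relative cell size gained per copy.
#' @param noise_log2_sd Multiplicative log-normal measurement noise, sd
#'   in log2 units, per gene x sample.
#' @param n_mutants Number of deletion mutants in the synthetic
#'   compendium.
#' @param frag_len_bp ChIP fragment length, bp.
#' @param background_rate ChIP background, reads per bp.
#' @param plasmid_len_bp Length of the integrated-plasmid contig, bp.
#' @param decay_rate mRNA decay rate, 1/s (shared across genes; it sets
#'   the abundance scale `m = r / decay`).
#' @param gene_len_bp,intergenic_bp Gene body length and intergenic gap
#'   used to lay the catalog on one synthetic chromosome.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       tata_fraction = 0.2,
                       abundance_log_mean = log(0.02),
                       abundance_log_sd = 2,
                       dead_time_s = 1.05,
                       copy_numbers = c(0L, 2L, 5L, 10L, 15L, 20L),
                       capacity_slope = 0.0375,
                       growth_slope = 0.015,
                       size_slope = 0.025,
                       noise_log2_sd = 0.2,
                       n_mutants = 30L,
                       frag_len_bp = 120L,
                       background_rate = 0.02,
                       plasmid_len_bp = 5000L,
                       decay_rate = 1 / 600,
                       gene_len_bp = 1500L,
                       intergenic_bp = 1000L) {
  stop_if_not_number(seed, "seed")
  stop_if_not_number(n_genes, "n_genes", lower = 0)
  stop_if_not_number(tata_fraction, "tata_fraction", lower = 0, upper = 1)
  stop_if_not_number(abundance_log_mean, "abundance_log_mean")
  stop_if_not_number(abundance_log_sd, "abundance_log_sd", lower = 0)
  stop_if_not_number(dead_time_s, "dead_time_s", lower = 0)
  stopifnot(is.numeric(copy_numbers), length(copy_numbers) >= 1,
            all(copy_numbers >= 0), all(copy_numbers == round(copy_numbers)))
  stop_if_not_number(capacity_slope, "capacity_slope", lower = 0)
  stop_if_not_number(growth_slope, "growth_slope", lower = 0)
  stop_if_not_number(size_slope, "size_slope", lower = 0)
  stop_if_not_number(noise_log2_sd, "noise_log2_sd", lower = 0)
  stop_if_not_number(n_mutants, "n_mutants", lower = 0)
  stop_if_not_number(frag_len_bp, "frag_len_bp", lower = 1)
  stop_if_not_number(background_rate, "background_rate", lower = 0)
  stop_if_not_number(plasmid_len_bp, "plasmid_len_bp", lower = 1)
  stop_if_not_number(decay_rate, "decay_rate", lower = 0)
  stop_if_not_number(gene_len_bp, "gene_len_bp", lower = 1)
  stop_if_not_number(intergenic_bp, "intergenic_bp", lower = 0)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         tata_fraction = tata_fraction,
         abundance_log_mean = abundance_log_mean,
         abundance_log_sd = abundance_log_sd,
         dead_time_s = dead_time_s,
         copy_numbers = as.integer(sort(copy_numbers)),
         capacity_slope = capacity_slope, growth_slope = growth_slope,
         size_slope = size_slope, noise_log2_sd = noise_log2_sd,
         n_mutants = as.integer(n_mutants),
         frag_len_bp = as.integer(frag_len_bp),
         background_rate = background_rate,
         plasmid_len_bp = as.integer(plasmid_len_bp),
         decay_rate = decay_rate,
         gene_len_bp = as.integer(gene_len_bp),
         intergenic_bp = as.integer(intergenic_bp)),
    class = "sim_config"
  )
}

#' Generate the synthetic gene catalog
#'
#' Draws `n_genes` genes with log-normal attempt rates, flags
#' `round(tata_fraction * n_genes)` of them as TATA by sampling from the
#' top attempt-rate quantile (TATA promoters are the bursty,
#' high-expression class), and lays the genes head-to-tail on one
#' synthetic chromosome with random strands. Coordinates are 0-based,
#' half-open (BED convention); `tss`/`tts` are stored
#' promoter-to-terminator in strand-aware order, so `tss > tts` on the
#' minus strand.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `gene_catalog` with columns `gene_id`,
#'   `attempt_rate`, `is_tata`, `decay_rate`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tts`; the chromosome length is in
#'   `attr(, "genome_len")`.
#' @export
gen_gene_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) stop("empty catalog: `n_genes` is 0", call. = FALSE)
  with_seed(config$seed, {
    a <- rlnorm(n, config$abundance_log_mean, config$abundance_log_sd)
    n_tata <- round(config$tata_fraction * n)
    is_tata <- logical(n)
    if (n_tata > 0) {
      pool <- order(a, decreasing = TRUE)[seq_len(min(n, 2L * n_tata))]
      is_tata[sample(pool, n_tata)] <- TRUE
    }
    pitch <- config$gene_len_bp + config$intergenic_bp
    start <- (seq_len(n) - 1L) * pitch + config$intergenic_bp
    end <- start + config$gene_len_bp
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cat <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n)),
      attempt_rate = a,
      is_tata = is_tata,
      decay_rate = config$decay_rate,
      chrom = "chrI",
      start = start,
      end = end,
      strand = strand,
      tss = ifelse(strand == "+", start, end),
      tts = ifelse(strand == "+", end, start),
      stringsAsFactors = FALSE
    )
    attr(cat, "genome_len") <- n * pitch + config$intergenic_bp
    class(cat) <- c("gene_catalog", "data.frame")
    cat
  })
}
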