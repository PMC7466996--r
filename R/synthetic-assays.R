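#' Generate a synthetic competition time series
#'
#' Two strains compete under constant selection: the log2 odds of the
#' wild-type frequency changes by `true_advantage` per generation
#' (positive = wild type wins). Observation noise is added on the
#' log2-odds scale before back-transforming to frequencies, emulating
#' flow-cytometry counting error.
#'
#' @param true_advantage Per-generation log2-odds slope of the wild
#'   type (the wild type's selection coefficient).
#' @param n_timepoints Number of measurements (>= 2).
#' @param generations_per_interval Generations elapsing between
#'   consecutive measurements (from the dilution factor; a daily 1:100
#'   dilution gives log2(100) ~ 6.6).
#' @param f0 Initial wild-type frequency, in (0, 1).
#' @param noise_sd Observation noise sd on the log2-odds scale.
#' @param seed Integer seed.
#' @return A data.frame of class `competition_series` with columns
#'   `generations` (cumulative) and `f_wt`.
#' @export
gen_competition_series <- function(true_advantage, n_timepoints = 8L,
                                   generations_per_interval = log2(100),
                                   f0 = 0.5, noise_sd = 0, seed = 1L) {
  stop_if_not_number(true_advantage, "true_advantage")
  stop_if_not_number(n_timepoints, "n_timepoints", lower = 2)
  stop_if_not_number(generations_per_interval, "generations_per_interval",
                     lower = 0)
  stop_if_not_number(f0, "f0")
  if (f0 <= 0 || f0 >= 1) stop("`f0` must be in (0, 1)", call. = FALSE)
  stop_if_not_number(noise_sd, "noise_sd", lower = 0)
  gens <- (seq_len(n_timepoints) - 1) * generations_per_interval
  with_seed(seed, {
    lo <- log2(f0 / (1 - f0)) + true_advantage * gens +
      rnorm(n_timepoints, 0, noise_sd)
    out <- data.frame(generations = gens, f_wt = 2^lo / (1 + 2^lo))
    class(out) <- c("competition_series", "data.frame")
    out
  })
}

#' Generate synthetic stranded ChIP read-start tracks
#'
#' Emulates single-end ChIP sequencing over a joint reference (one
#' synthetic chromosome plus an integrated-plasmid contig). Fragments
#' of length `frag_len_bp` are centered (with Gaussian jitter) on
#' promoter points — each gene's TSS, plus one site in the middle of
#' the plasmid — with per-promoter intensity proportional to the given
#' weights; each fragment is sequenced from one random end, yielding a
#' plus-strand read start at the fragment's left end or a minus-strand
#' start at its right end. Uniform background reads are added at
#' `background_rate` reads/bp on both contigs.
#'
#' @param catalog A [gen_gene_catalog()] catalog.
#' @param config The [sim_config()] (fragment length, background rate,
#'   plasmid length).
#' @param promoter_weights Non-negative weight per catalog gene.
#' @param plasmid_weight Non-negative weight of the plasmid site.
#' @param n_signal_reads Total promoter-derived reads to draw.
#' @param jitter_sd Gaussian jitter of fragment centers, bp.
#' @param seed Integer seed (defaults to the config seed).
#' @return A `read_start_track`: list with `contigs`, each holding
#'   `length`, `plus` and `minus` integer count vectors (one entry per
#'   position). Ground truth (reads drawn per promoter, per contig) is
#'   attached as `attr(, "truth")`. Fragments extending past a contig
#'   end are truncated to it and counted in `truth$n_truncated`.
#' @export
gen_chip_tracks <- function(catalog, config, promoter_weights,
                            plasmid_weight, n_signal_reads = 1e5,
                            jitter_sd = 20, seed = config$seed) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "sim_config"))
  stopifnot(is.numeric(promoter_weights),
            length(promoter_weights) == nrow(catalog),
            all(promoter_weights >= 0))
  stop_if_not_number(plasmid_weight, "plasmid_weight", lower = 0)
  genome_len <- attr(catalog, "genome_len")
  plas_len <- config$plasmid_len_bp
  frag <- config$frag_len_bp
  # promoter points: TSS (0-based position of the first transcribed base)
  points <- ifelse(catalog$strand == "+", catalog$tss, catalog$tss - 1L)
  w <- c(promoter_weights, plasmid_weight)
  if (sum(w) <= 0) stop("all promoter weights are zero", call. = FALSE)
  with_seed(seed, {
    counts <- as.integer(rmultinom(1, n_signal_reads, w))
    contig_of <- c(rep("chrI", nrow(catalog)), "plasmid")
    point_of <- c(points, plas_len %/% 2L)
    len_of <- c(chrI = genome_len, plasmid = plas_len)
    tracks <- list(
      chrI = list(length = genome_len,
                  plus = integer(genome_len), minus = integer(genome_len)),
      plasmid = list(length = plas_len,
                     plus = integer(plas_len), minus = integer(plas_len))
    )
    n_trunc <- 0L
    for (k in seq_along(point_of)) {
      nk <- counts[k]
      if (nk == 0L) next
      ctg <- contig_of[k]
      L <- len_of[[ctg]]
      centers <- point_of[k] + round(rnorm(nk, 0, jitter_sd))
      s <- centers - frag %/% 2L
      n_trunc <- n_trunc + sum(s < 0L | s + frag > L)
      s <- pmax(0L, pmin(s, L - frag))
      on_plus <- runif(nk) < 0.5
      start_pos <- ifelse(on_plus, s, s + frag - 1L)
      for (str in c("plus", "minus")) {
        pos <- start_pos[if (str == "plus") on_plus else !on_plus]
        if (length(pos)) {
          tracks[[ctg]][[str]] <- tracks[[ctg]][[str]] +
            tabulate(pos + 1L, nbins = L)
        }
      }
    }
    bg_reads <- integer(2)
    for (i in seq_along(tracks)) {
      L <- tracks[[i]]$length
      for (str in c("plus", "minus")) {
        nb <- rpois(1, config$background_rate * L / 2)
        bg_reads[i] <- bg_reads[i] + nb
        if (nb > 0) {
          pos <- sample.int(L, nb, replace = TRUE)
          tracks[[i]][[str]] <- tracks[[i]][[str]] + tabulate(pos, nbins = L)
        }
      }
    }
    if (n_trunc > 0) {
      message(n_trunc, " fragments extended past a contig end and were ",
              "truncated")
    }
    structure(list(contigs = tracks),
              class = "read_start_track",
              truth = list(promoter_reads = counts[seq_len(nrow(catalog))],
                           plasmid_signal_reads = counts[length(counts)],
                           background_reads = stats::setNames(
                             bg_reads, names(tracks)),
                           n_truncated = n_trunc))
  })
}

#' Total reads in a read-start track
#' @param track A `read_start_track`.
#' @return Integer count over all contigs and strands.
#' @export
track_total_reads <- function(track) {
  stopifnot(inherits(track, "read_start_track"))
  sum(vapply(track$contigs, function(ct) sum(ct$plus) + sum(ct$minus),
             numeric(1)))
}

#' Generate synthetic two-species spike-in read counts
#'
#' Emulates mixed-species sequencing in which every *S. cerevisiae*
#' sample is mixed with a fixed amount of *S. paradoxus* cells (constant
#' OD ratio across samples). Reads split between the two species with
#' expected cerevisiae:paradoxus ratio proportional to
#' `(true_mrna_per_cell * cells) : spike_ratio_constant`; counts are
#' binomially sampled at the given depth.
#'
#' @param true_mrna_per_cell True relative total mRNA per cell, one per
#'   sample (> 0).
#' @param cells Counted *S. cerevisiae* cells in each mixed aliquot.
#' @param spike_ratio_constant Spike-in mRNA amount, same arbitrary
#'   units as `true_mrna_per_cell * cells`.
#' @param depth Total reads per sample.
#' @param seed Integer seed.
#' @param condition Optional condition label per sample.
#' @return A data.frame of class `spikein_samples` with columns
#'   `sample_id`, `condition`, `cer_reads`, `par_reads`, `cells`.
#' @export
gen_spikein_counts <- function(true_mrna_per_cell, cells,
                               spike_ratio_constant = 1, depth = 1e5,
                               seed = 1L, condition = NULL) {
  stopifnot(is.numeric(true_mrna_per_cell), all(true_mrna_per_cell > 0),
            is.numeric(cells), all(cells > 0),
            length(cells) == length(true_mrna_per_cell))
  stop_if_not_number(spike_ratio_constant, "spike_ratio_constant")
  if (spike_ratio_constant <= 0) {
    stop("`spike_ratio_constant` must be > 0", call. = FALSE)
  }
  stop_if_not_number(depth, "depth", lower = 1)
  n <- length(true_mrna_per_cell)
  if (is.null(condition)) condition <- rep("cond1", n)
  with_seed(seed, {
    p <- true_mrna_per_cell * cells /
      (true_mrna_per_cell * cells + spike_ratio_constant)
    cer <- rbinom(n, size = round(depth), prob = p)
    out <- data.frame(
      sample_id = sprintf("s%02d", seq_len(n)),
      condition = condition,
      cer_reads = cer,
      par_reads = round(depth) - cer,
      cells = cells,
      stringsAsFactors = FALSE
    )
    class(out) <- c("spikein_samples", "data.frame")
    out
  })
}
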