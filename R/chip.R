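#' Gene signal regions for ChIP quantification
#'
#' Builds each gene's signal region — from 500 bp upstream of the TSS
#' (strand-aware) to the TTS — in genomic 0-based half-open
#' coordinates, clipped to the contig. The background is the complement
#' of the union of signal regions on the genome contigs; the plasmid
#' contig belongs to neither.
#'
#' @param catalog A [gen_gene_catalog()] catalog.
#' @param upstream Upstream extension of the promoter side, bp.
#' @return data.frame of class `region_set` with `gene_id`, `contig`,
#'   `start`, `end` (half-open); the genome length is carried in
#'   `attr(, "genome_len")`.
#' @export
chip_regions <- function(catalog, upstream = 500L) {
  stopifnot(inherits(catalog, "gene_catalog"))
  stop_if_not_number(upstream, "upstream", lower = 0)
  genome_len <- attr(catalog, "genome_len")
  start <- ifelse(catalog$strand == "+",
                  pmax(0L, catalog$start - upstream), catalog$start)
  end <- ifelse(catalog$strand == "+",
                catalog$end, pmin(genome_len, catalog$end + upstream))
  out <- data.frame(gene_id = catalog$gene_id, contig = catalog$chrom,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  attr(out, "genome_len") <- genome_len
  class(out) <- c("region_set", "data.frame")
  out
}

# Logical signal mask per genome contig (merged over overlapping genes).
.signal_mask <- function(regions, contig_len) {
  mask <- logical(contig_len)
  for (i in seq_len(nrow(regions))) {
    mask[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  }
  mask
}

#' Estimate the physical fragment length by strand cross-correlation
#'
#' Single-end plus- and minus-strand read starts sit at opposite ends
#' of each fragment, so shifting the minus-strand starts left by the
#' fragment span best aligns the two profiles. Returns the shift (bp)
#' maximizing the cross-correlation over `shift_range`; ties go to the
#' smallest shift.
#'
#' @param track A `read_start_track`.
#' @param shift_range Integer shifts to scan (default 50-300 bp,
#'   bracketing the 100-130 bp fragments typical of sonicated ChIP).
#' @return Estimated fragment span in bp.
#' @export
estimate_fragment_length <- function(track, shift_range = 50:300) {
  stopifnot(inherits(track, "read_start_track"))
  plus <- unlist(lapply(track$contigs, `[[`, "plus"), use.names = FALSE)
  minus <- unlist(lapply(track$contigs, `[[`, "minus"), use.names = FALSE)
  if (sum(plus) == 0 || sum(minus) == 0) {
    stop("a strand has no reads", call. = FALSE)
  }
  shift_range <- sort(unique(as.integer(shift_range)))
  n <- length(plus)
  score <- vapply(shift_range, function(s) {
    if (s >= n) return(-Inf)
    sum(plus[seq_len(n - s)] * minus[(s + 1L):n])
  }, numeric(1))
  shift_range[which.max(score)]  # which.max takes the first (smallest) tie
}

#' Extend read starts into fragment coverage
#'
#' Each plus-strand start at position `p` contributes coverage over
#' `[p, p + frag_len)`; each minus-strand start contributes over
#' `(p - frag_len, p]`. Fragments running past a contig end are
#' truncated. Strand information is dropped after extension.
#'
#' @param track A `read_start_track`.
#' @param frag_len Fragment length in bp (>= 1).
#' @return A `coverage_track`: list with `contigs` (named numeric
#'   coverage vectors) and `total_reads`.
#' @export
extend_reads <- function(track, frag_len) {
  stopifnot(inherits(track, "read_start_track"))
  stop_if_not_number(frag_len, "frag_len", lower = 1)
  frag_len <- as.integer(frag_len)
  contigs <- lapply(track$contigs, function(ct) {
    L <- ct$length
    f <- min(frag_len, L)
    # plus: coverage at p = number of starts in (p - f, p]
    csp <- cumsum(ct$plus)
    cov_p <- csp - c(rep(0, f), head(csp, L - f))
    # minus: coverage at p = number of starts in [p, p + f)
    csm <- c(0, cumsum(ct$minus))
    hi <- pmin(L, seq_len(L) + f - 1L)
    cov_m <- csm[hi + 1L] - csm[seq_len(L)]
    cov_p + cov_m
  })
  structure(list(contigs = contigs, total_reads = track_total_reads(track)),
            class = "coverage_track")
}

#' Depth-normalize and background-subtract a coverage track
#'
#' The Methods-style background removal: (1) scale the whole track to
#' 1,000,000 reads; (2) take the background as the complement of the
#' gene signal regions on the genome contigs (the plasmid contig is in
#' neither set); (3) subtract the mean background level from every
#' position of every contig, plasmid included; (4) clip negative values
#' to zero. The returned track's `total_reads` is set to 1e6, so
#' reapplying the operation to a track whose background is already zero
#' changes nothing.
#'
#' @param coverage A `coverage_track` from [extend_reads()].
#' @param regions A [chip_regions()] region set.
#' @return A normalized `coverage_track`; the subtracted background
#'   mean (on the normalized scale) is in `attr(, "background_mean")`.
#' @export
normalize_subtract <- function(coverage, regions) {
  stopifnot(inherits(coverage, "coverage_track"),
            inherits(regions, "region_set"))
  scale <- 1e6 / coverage$total_reads
  genome_contigs <- intersect(names(coverage$contigs),
                              unique(regions$contig))
  bg_sum <- 0
  bg_n <- 0
  for (ctg in genome_contigs) {
    cov <- coverage$contigs[[ctg]] * scale
    mask <- .signal_mask(regions[regions$contig == ctg, ],
                         length(cov))
    bg_sum <- bg_sum + sum(cov[!mask])
    bg_n <- bg_n + sum(!mask)
  }
  if (bg_n == 0) stop("background is empty", call. = FALSE)
  bg_mean <- bg_sum / bg_n
  contigs <- lapply(coverage$contigs, function(cov) {
    pmax(cov * scale - bg_mean, 0)
  })
  structure(list(contigs = contigs, total_reads = 1e6),
            class = "coverage_track", background_mean = bg_mean)
}

#' Promoter-averaged binding signal per gene
#'
#' Mean of the processed coverage over each gene's signal region.
#'
#' @param coverage A (normalized) `coverage_track`.
#' @param regions A [chip_regions()] region set.
#' @return data.frame with `gene_id` and `mean_signal`.
#' @export
promoter_binding <- function(coverage, regions) {
  stopifnot(inherits(coverage, "coverage_track"),
            inherits(regions, "region_set"))
  if (any(regions$end <= regions$start)) {
    stop("zero-length signal region", call. = FALSE)
  }
  means <- vapply(seq_len(nrow(regions)), function(i) {
    cov <- coverage$contigs[[regions$contig[i]]]
    mean(cov[(regions$start[i] + 1L):regions$end[i]])
  }, numeric(1))
  data.frame(gene_id = regions$gene_id, mean_signal = means,
             stringsAsFactors = FALSE)
}

#' Fraction of reads on the integrated-plasmid contig
#'
#' The share of raw reads (pre-normalization, both strands) mapping to
#' the plasmid — the fraction of the profiled factor bound to the
#' burden construct.
#'
#' @param track A `read_start_track`.
#' @param plasmid_contig Name of the plasmid contig.
#' @return Fraction in `[0, 1]`.
#' @export
plasmid_occupancy <- function(track, plasmid_contig = "plasmid") {
  stopifnot(inherits(track, "read_start_track"))
  if (!plasmid_contig %in% names(track$contigs)) {
    stop("plasmid contig not present", call. = FALSE)
  }
  total <- track_total_reads(track)
  if (total == 0) stop("track has no reads", call. = FALSE)
  ct <- track$contigs[[plasmid_contig]]
  (sum(ct$plus) + sum(ct$minus)) / total
}
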