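#' Relative total mRNA per cell from spike-in counts
#'
#' Normalizes each sample's reads to the ratio between the
#' *S. cerevisiae* and *S. paradoxus* (spike-in) read sums, then to the
#' counted cell number: `(cer_reads / par_reads) / cells`. Because the
#' spike-in amount is constant across samples, the values are
#' comparable within one experiment (arbitrary units). Invariant to
#' sequencing depth.
#'
#' @param cer_reads,par_reads Species-assigned read counts (> 0 for the
#'   spike-in).
#' @param cells Counted *S. cerevisiae* cells in the mixed aliquot.
#'   All arguments vectorized over samples; a `spikein_samples`
#'   data.frame can be passed as the single first argument instead.
#' @return Numeric vector of relative total mRNA per cell.
#' @export
total_mrna_per_cell <- function(cer_reads, par_reads = NULL, cells = NULL) {
  if (is.data.frame(cer_reads)) {
    df <- cer_reads
    stopifnot(all(c("cer_reads", "par_reads", "cells") %in% names(df)))
    return(total_mrna_per_cell(df$cer_reads, df$par_reads, df$cells))
  }
  stopifnot(is.numeric(cer_reads), is.numeric(par_reads),
            is.numeric(cells))
  if (any(par_reads <= 0)) stop("zero spike-in reads", call. = FALSE)
  if (any(cells <= 0)) stop("non-positive cell count", call. = FALSE)
  (cer_reads / par_reads) / cells
}

# Delta-method standard error of (cer/par)/cells from Poisson-scale
# counting noise in both species' read counts.
total_mrna_se <- function(cer_reads, par_reads, cells) {
  total_mrna_per_cell(cer_reads, par_reads, cells) *
    sqrt(1 / cer_reads + 1 / par_reads)
}

#' Per-condition summary of total-mRNA values
#'
#' Mean and standard error of per-sample total-mRNA-per-cell values
#' within each condition. The SE is `sd / sqrt(n)`; it is `NA` for
#' single-replicate conditions.
#'
#' @param samples A `spikein_samples` data.frame (columns `condition`,
#'   `cer_reads`, `par_reads`, `cells`).
#' @return data.frame with `condition`, `mean`, `se`, `n`.
#' @export
condition_summary <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("condition", "cer_reads", "par_reads", "cells") %in%
                  names(samples)))
  values <- total_mrna_per_cell(samples)
  rows <- lapply(unique(samples$condition), function(cond) {
    v <- values[samples$condition == cond]
    data.frame(condition = cond, mean = mean(v),
               se = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag spike-in samples with aberrant spike recovery
#'
#' QC: samples whose spike-in (*S. paradoxus*) read counts deviate by
#' more than `k` MADs from the batch median are flagged; the constant
#' OD mixing ratio makes gross deviations suspicious. The flag does not
#' enter the estimator.
#'
#' @param samples A `spikein_samples` data.frame.
#' @param k MAD multiplier (default 3).
#' @return Logical vector, `TRUE` for flagged samples.
#' @export
flag_spike_outliers <- function(samples, k = 3) {
  stopifnot(is.data.frame(samples), "par_reads" %in% names(samples))
  med <- stats::median(samples$par_reads)
  mad <- stats::mad(samples$par_reads)
  if (mad == 0) return(rep(FALSE, nrow(samples)))
  abs(samples$par_reads - med) > k * mad
}
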