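#' Mean-normalize and log2-transform an expression matrix
#'
#' Divides each gene's values by their mean within each condition and
#' log2-transforms, so the back-transformed row means are 1 per
#' condition and values read as log2 deviations from the condition
#' mean.
#'
#' @param mat Gene x sample numeric matrix of strictly positive
#'   linear-scale abundances, with dimnames.
#' @param conditions Condition label per column; a single condition is
#'   assumed when omitted.
#' @return Matrix of the same shape, log2 scale.
#' @export
normalize_log2 <- function(mat, conditions = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  bad <- which(mat <= 0 | !is.finite(mat), arr.ind = TRUE)
  if (nrow(bad <- unique(bad[, 1, drop = FALSE])) > 0) {
    gene <- if (!is.null(rownames(mat))) rownames(mat)[bad[1, 1]] else
      paste("row", bad[1, 1])
    stop("non-positive expression value in gene ", gene, call. = FALSE)
  }
  if (is.null(conditions)) conditions <- rep("all", ncol(mat))
  stopifnot(length(conditions) == ncol(mat))
  out <- mat
  for (cond in unique(conditions)) {
    idx <- which(conditions == cond)
    out[, idx] <- log2(mat[, idx, drop = FALSE] /
                         rowMeans(mat[, idx, drop = FALSE]))
  }
  out
}

#' Within-sample relative abundance
#'
#' Normalizes each column of a linear-scale expression matrix to sum 1,
#' so values are relative abundances and a pure global scale-up of all
#' genes reads as no change.
#'
#' @param mat Gene x sample matrix of positive values.
#' @return Matrix of column-wise relative abundances.
#' @export
relative_abundance <- function(mat) {
  stopifnot(is.matrix(mat), all(mat > 0))
  sweep(mat, 2, colSums(mat), "/")
}

#' Per-gene growth-rate expression response (E_g)
#'
#' For each gene, the ordinary least-squares slope of log2 expression on
#' the strains' relative growth rate — the growth-rate response E_g.
#' The intercept is discarded; the slope's standard error comes from
#' the residuals. Genes with fewer than 3 informative (finite) samples
#' are omitted with a message.
#'
#' @param log2_mat Gene x sample matrix on the log2 scale (e.g. from
#'   [normalize_log2()]).
#' @param strains Strain table with `sample_id` and
#'   `relative_growth_rate`, matching the matrix columns.
#' @return data.frame of class `growth_response` with columns
#'   `gene_id`, `E_g`, `stderr`, `n_samples`.
#' @export
growth_response <- function(log2_mat, strains) {
  stopifnot(is.matrix(log2_mat),
            all(c("sample_id", "relative_growth_rate") %in% names(strains)))
  idx <- match(colnames(log2_mat), strains$sample_id)
  if (anyNA(idx)) stop("matrix columns missing from strain table",
                       call. = FALSE)
  x <- strains$relative_growth_rate[idx]
  fit <- .row_ols(log2_mat, x)
  dropped <- sum(fit$n < 3)
  if (dropped > 0) {
    message(dropped, " genes with < 3 informative samples omitted")
  }
  keep <- fit$n >= 3
  out <- data.frame(
    gene_id = rownames(log2_mat)[keep],
    E_g = fit$slope[keep],
    stderr = fit$se[keep],
    n_samples = fit$n[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("growth_response", "data.frame")
  out
}

# Row-wise OLS slope of Y on x; rows with any NA fall back to pairwise
# complete fits. Returns slope, residual-based SE and n per row.
.row_ols <- function(Y, x) {
  n_col <- ncol(Y)
  complete <- rowSums(!is.finite(Y)) == 0
  slope <- se <- rep(NA_real_, nrow(Y))
  n <- integer(nrow(Y))
  if (any(complete)) {
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) stop("no variation in growth rate", call. = FALSE)
    Yc <- Y[complete, , drop = FALSE]
    b <- as.vector(Yc %*% xc) / sxx
    res <- Yc - tcrossprod(b, xc) -
      (rowMeans(Yc))  # residuals about the fitted line
    rss <- rowSums(res^2)
    slope[complete] <- b
    se[complete] <- sqrt(rss / (n_col - 2) / sxx)
    n[complete] <- n_col
  }
  for (i in which(!complete)) {
    ok <- is.finite(Y[i, ])
    n[i] <- sum(ok)
    if (n[i] >= 3 && length(unique(x[ok])) > 1) {
      f <- lm(Y[i, ok] ~ x[ok])
      slope[i] <- coef(f)[2]
      se[i] <- summary(f)$coefficients[2, 2]
    } else {
      n[i] <- 0L  # uninformative
    }
  }
  list(slope = slope, se = se, n = n)
}

#' Expression-dependent bias (delta)
#'
#' The slope delta of a strain's per-gene relative expression change
#' (log2, versus wild type) on log10 wild-type abundance, fit by
#' unweighted OLS for all genes and for the TATA / non-TATA subsets. A
#' negative delta means highly expressed genes failed to follow a
#' global expression scale-up — the footprint of initiation saturation.
#'
#' @param relative_change Per-gene log2 change of relative abundance
#'   versus wild type (see [relative_abundance()]).
#' @param wt_abundance Positive wild-type abundances, same genes.
#' @param tata_flags Optional logical TATA flag per gene; when given,
#'   `TATA` and `non-TATA` subset fits are added.
#' @return data.frame of class `bias_result` with columns `subset`,
#'   `delta` (log2 units per decade of abundance), `sem`, `n_genes`.
#'   Subsets with fewer than 3 genes are omitted.
#' @export
expression_bias <- function(relative_change, wt_abundance,
                            tata_flags = NULL) {
  stopifnot(is.numeric(relative_change), is.numeric(wt_abundance),
            length(relative_change) == length(wt_abundance))
  if (any(wt_abundance <= 0)) stop("abundances must be positive",
                                   call. = FALSE)
  subsets <- list(all = rep(TRUE, length(relative_change)))
  if (!is.null(tata_flags)) {
    stopifnot(is.logical(tata_flags),
              length(tata_flags) == length(relative_change))
    subsets$TATA <- tata_flags
    subsets$`non-TATA` <- !tata_flags
  }
  rows <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]] & is.finite(relative_change)
    if (sum(sel) < 3) return(NULL)
    x <- log10(wt_abundance[sel])
    y <- relative_change[sel]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) stop("no spread in abundance", call. = FALSE)
    delta <- sum(xc * y) / sxx
    rss <- sum((y - mean(y) - delta * xc)^2)
    data.frame(subset = nm,
               delta = delta,
               sem = sqrt(rss / (length(y) - 2) / sxx),
               n_genes = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bias_result", "data.frame")
  out
}

#' Expression-dependent bias per compendium mutant
#'
#' Computes delta (as in [expression_bias()], all-genes subset) for
#' each mutant signature column and pairs it with the mutant's relative
#' growth rate, reproducing the delta-versus-growth plane that
#' separates transcription-capacity mutants from merely slow-growing
#' ones.
#'
#' @param signatures Gene x mutant matrix of log2 relative signatures.
#' @param wt_abundance Positive wild-type abundance per gene.
#' @param growth_rates Relative growth rate per mutant.
#' @return data.frame with `mutant_id`, `delta`, `sem`,
#'   `relative_growth_rate`.
#' @export
per_mutant_bias <- function(signatures, wt_abundance, growth_rates) {
  stopifnot(is.matrix(signatures),
            length(wt_abundance) == nrow(signatures),
            length(growth_rates) == ncol(signatures))
  rows <- lapply(seq_len(ncol(signatures)), function(j) {
    b <- expression_bias(signatures[, j], wt_abundance)
    data.frame(mutant_id = colnames(signatures)[j],
               delta = b$delta[b$subset == "all"],
               sem = b$sem[b$subset == "all"],
               relative_growth_rate = growth_rates[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top and bottom responding gene sets
#'
#' Ranks genes by their growth-rate response E_g and returns the `n`
#' highest and `n` lowest. Ties are broken lexicographically by
#' `gene_id`.
#'
#' @param profile A [growth_response()] data.frame.
#' @param n Set size; must be at most half the number of genes.
#' @return List with character vectors `top` and `bottom` (disjoint).
#' @export
top_bottom_sets <- function(profile, n) {
  stopifnot(is.data.frame(profile),
            all(c("gene_id", "E_g") %in% names(profile)))
  stop_if_not_number(n, "n", lower = 1)
  if (n > nrow(profile) / 2) stop("`n` exceeds half the gene count",
                                  call. = FALSE)
  ord <- order(-profile$E_g, profile$gene_id)
  list(top = profile$gene_id[ord[seq_len(n)]],
       bottom = rev(profile$gene_id[rev(ord)[seq_len(n)]]))
}

#' Noise-free wild-type reference abundance
#'
#' The analytic wild-type mRNA abundance of each catalog gene,
#' `a / (1 + a tau) / decay` — the independent reference used as the
#' abundance axis of [expression_bias()] so that measurement noise in
#' the wild-type sample does not leak into both regression axes.
#'
#' @param catalog A `gene_catalog`.
#' @param dead_time_s Dead time tau used by the generator, seconds.
#' @return Positive abundance per gene (arbitrary units).
#' @export
wt_reference_abundance <- function(catalog, dead_time_s) {
  stopifnot(inherits(catalog, "gene_catalog"))
  stop_if_not_number(dead_time_s, "dead_time_s", lower = 0)
  a <- catalog$attempt_rate
  (a / (1 + a * dead_time_s)) / catalog$decay_rate
}

#' Relative expression change of one burden strain versus wild type
#'
#' Per-gene log2 ratio of within-sample relative abundances between a
#' burden strain and the copy-0 wild type, so a pure global expression
#' scale-up reads as zero change.
#'
#' @param library A `burden_library` from [gen_burden_library()].
#' @param sample Column name of the burden strain (default: the
#'   highest-copy strain).
#' @param reference Column name of the wild type.
#' @return Named numeric vector of log2 relative changes.
#' @export
burden_signature <- function(library, sample = NULL,
                             reference = "copy00") {
  stopifnot(inherits(library, "burden_library"))
  if (is.null(sample)) sample <- tail(colnames(library$expression), 1)
  rel <- relative_abundance(library$expression)
  log2(rel[, sample] / rel[, reference])
}
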