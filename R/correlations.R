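#' Pearson correlation between two gene-level profiles
#'
#' Correlates two named numeric profiles (e.g. growth-rate responses or
#' mutant signatures) over the genes that are present and finite in
#' both. At least 3 shared genes are required.
#'
#' @param profile_a,profile_b Named numeric vectors (names = gene ids).
#' @param gene_subset Optional character vector restricting the gene
#'   universe.
#' @return List with `r` (Pearson correlation) and `n_genes`.
#' @export
signature_correlation <- function(profile_a, profile_b,
                                  gene_subset = NULL) {
  stopifnot(is.numeric(profile_a), is.numeric(profile_b),
            !is.null(names(profile_a)), !is.null(names(profile_b)))
  shared <- intersect(names(profile_a), names(profile_b))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  a <- profile_a[shared]
  b <- profile_b[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 shared finite genes", call. = FALSE)
  list(r = cor(a[ok], b[ok]), n_genes = sum(ok))
}

#' Per-mutant correlations with burden and growth responses
#'
#' For each mutant signature, the Pearson correlation with the burden
#' growth-rate response and with the (external-compendium) growth
#' response — the plane that distinguishes mutants resembling the
#' burden specifically from mutants merely tracking slow growth. When a
#' list of profiles is given for either axis, the per-profile
#' correlations are averaged arithmetically (e.g. the burden response
#' over its three growth conditions).
#'
#' @param signatures Gene x mutant matrix with dimnames.
#' @param burden_profile Named numeric vector of burden E_g values, or
#'   a list of such vectors to average over.
#' @param growth_profile Same, for the growth-rate response.
#' @return data.frame with `mutant_id`, `r_burden`, `r_growth`.
#' @export
burden_growth_plane <- function(signatures, burden_profile,
                                growth_profile) {
  stopifnot(is.matrix(signatures), !is.null(dimnames(signatures)))
  if (!is.list(burden_profile)) burden_profile <- list(burden_profile)
  if (!is.list(growth_profile)) growth_profile <- list(growth_profile)
  avg_cor <- function(sig, profiles) {
    mean(vapply(profiles, function(p) signature_correlation(sig, p)$r,
                numeric(1)))
  }
  rows <- lapply(seq_len(ncol(signatures)), function(j) {
    sig <- signatures[, j]
    data.frame(mutant_id = colnames(signatures)[j],
               r_burden = avg_cor(sig, burden_profile),
               r_growth = avg_cor(sig, growth_profile),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Area under the ROC curve for a score separating two classes
#'
#' Mann-Whitney formulation: the probability that a random positive
#' scores above a random negative (ties count 1/2). Used to quantify
#' how cleanly e.g. capacity mutants rank above other compendium
#' classes by their burden correlation.
#'
#' @param scores Numeric scores.
#' @param labels Logical, `TRUE` for the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(is.numeric(scores), is.logical(labels),
            length(scores) == length(labels),
            any(labels), any(!labels))
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Convert a growth-response table to a named profile vector
#'
#' @param profile A [growth_response()] data.frame.
#' @return Named numeric vector of E_g values.
#' @export
as_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("gene_id", "E_g") %in% names(profile)))
  stats::setNames(profile$E_g, profile$gene_id)
}
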