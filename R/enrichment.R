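#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of the overlap between a query
#' gene set and each predefined gene group, against a fixed universe:
#' `P(X >= overlap)` for X hypergeometric(|group|, |universe| - |group|,
#' |query|), with Benjamini-Hochberg adjustment across groups.
#'
#' @param query_set Character vector of query genes (subset of the
#'   universe).
#' @param gene_groups Named list of character vectors (each a subset of
#'   the universe).
#' @param universe Character vector, the gene universe.
#' @return data.frame with `group`, `overlap`, `group_size`,
#'   `query_size`, `p_value`, `p_adjusted`.
#' @export
#' @examples
#' enrichment(letters[1:3], list(g = letters[1:4]), letters[1:10])
enrichment <- function(query_set, gene_groups, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stopifnot(is.list(gene_groups), !is.null(names(gene_groups)))
  query_set <- unique(query_set)
  if (!all(query_set %in% universe)) {
    stop("query set contains genes outside the universe", call. = FALSE)
  }
  n_u <- length(universe)
  n_q <- length(query_set)
  rows <- lapply(names(gene_groups), function(nm) {
    grp <- unique(intersect(gene_groups[[nm]], universe))
    k <- length(intersect(query_set, grp))
    p <- phyper(k - 1, length(grp), n_u - length(grp), n_q,
                lower.tail = FALSE)
    data.frame(group = nm, overlap = k, group_size = length(grp),
               query_size = n_q, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
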