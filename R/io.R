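#' Write a data.frame or matrix as TSV
#'
#' @param x data.frame or matrix; matrices are written with a leading
#'   `gene_id` column from their rownames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene catalog as BED6
#'
#' 0-based half-open intervals, score column carrying the attempt rate.
#'
#' @param catalog A `gene_catalog`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  bed <- data.frame(catalog$chrom, catalog$start, catalog$end,
                    catalog$gene_id, signif(catalog$attempt_rate, 6),
                    catalog$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write one strand of a read-start track (or a coverage track) as bedGraph
#'
#' Runs of equal values are merged into intervals; zero runs are
#' skipped.
#'
#' @param track A `read_start_track` or `coverage_track`.
#' @param path Output file.
#' @param strand `"plus"` or `"minus"` (ignored for coverage tracks).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$contigs)) {
    v <- if (inherits(track, "coverage_track")) track$contigs[[ctg]]
         else track$contigs[[ctg]][[strand]]
    r <- rle(as.numeric(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", ctg, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}
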