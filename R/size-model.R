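#' Parameters of the critical-size growth model
#'
#' A minimal proteome-allocation argument for why maximizing mRNA
#' production pays off: ribosome number grows with cell protein content
#' (a fixed proteome fraction is ribosomal), but the transcriptome can
#' only employ a bounded number of ribosomes
#' (`mrna_count * max_ribosomes_per_transcript`). Below that capacity,
#' cells grow at the optimal rate; above it, the surplus ribosomes are
#' idle and growth dilutes with size. The crossover defines a critical
#' protein content P*.
#'
#' This piecewise form is this package's formalization of a verbal
#' argument; defaults carry commonly cited yeast numbers (~200,000
#' ribosomes vs ~35,000 transcripts; note the literature rounds their
#' ratio to "~8 ribosomes per mRNA" although the direct quotient is
#' ~5.7).
#'
#' @param mrna_count Transcripts per cell.
#' @param max_ribosomes_per_transcript Ribosomes one transcript can
#'   productively engage.
#' @param ribosomal_fraction Fraction of the proteome that is ribosomal
#'   (in (0, 1)).
#' @param proteins_per_ribosome_unit Protein content (same arbitrary
#'   units as the grid) amounting to one ribosome.
#' @param mu_opt Optimal growth rate, 1/h.
#' @return An object of class `size_model_params`.
#' @export
size_model_params <- function(mrna_count = 35000,
                              max_ribosomes_per_transcript = 8,
                              ribosomal_fraction = 0.2,
                              proteins_per_ribosome_unit = 1,
                              mu_opt = 0.45) {
  stop_if_not_number(mrna_count, "mrna_count")
  stop_if_not_number(max_ribosomes_per_transcript,
                     "max_ribosomes_per_transcript")
  stop_if_not_number(ribosomal_fraction, "ribosomal_fraction")
  stop_if_not_number(proteins_per_ribosome_unit, "proteins_per_ribosome_unit")
  stop_if_not_number(mu_opt, "mu_opt")
  vals <- c(mrna_count, max_ribosomes_per_transcript, ribosomal_fraction,
            proteins_per_ribosome_unit, mu_opt)
  if (any(vals <= 0)) stop("all parameters must be positive", call. = FALSE)
  if (ribosomal_fraction >= 1) {
    stop("`ribosomal_fraction` must be < 1", call. = FALSE)
  }
  structure(
    list(mrna_count = mrna_count,
         max_ribosomes_per_transcript = max_ribosomes_per_transcript,
         ribosomal_fraction = ribosomal_fraction,
         proteins_per_ribosome_unit = proteins_per_ribosome_unit,
         mu_opt = mu_opt),
    class = "size_model_params"
  )
}

#' Growth rate versus cell protein content under bounded mRNA capacity
#'
#' Evaluates the critical-size model on a grid of protein contents.
#' Ribosome count is `R(P) = ribosomal_fraction * P /
#' proteins_per_ribosome_unit`; transcriptome capacity is
#' `C = mrna_count * max_ribosomes_per_transcript`; growth is `mu_opt`
#' while `R(P) <= C` and `mu_opt * C / R(P)` beyond. The curve is
#' non-increasing and continuous at the critical content
#' `P* = C * proteins_per_ribosome_unit / ribosomal_fraction`.
#'
#' @param params A [size_model_params()] object.
#' @param protein_content_grid Positive protein contents to evaluate.
#' @return List with `curve` (data.frame `protein_content`,
#'   `growth_rate`) and `critical_protein_content` (P*).
#' @export
#' @examples
#' p <- size_model_params()
#' cs <- critical_size_curve(p, c(0.5, 1, 2) * 1.4e6)
#' cs$critical_protein_content
critical_size_curve <- function(params, protein_content_grid) {
  stopifnot(inherits(params, "size_model_params"),
            is.numeric(protein_content_grid),
            all(protein_content_grid > 0))
  cap <- params$mrna_count * params$max_ribosomes_per_transcript
  ribosomes <- params$ribosomal_fraction * protein_content_grid /
    params$proteins_per_ribosome_unit
  mu <- ifelse(ribosomes <= cap, params$mu_opt,
               params$mu_opt * cap / ribosomes)
  p_star <- cap * params$proteins_per_ribosome_unit /
    params$ribosomal_fraction
  list(curve = data.frame(protein_content = protein_content_grid,
                          growth_rate = mu),
       critical_protein_content = p_star)
}
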