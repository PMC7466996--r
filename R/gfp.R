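#' GFP-library expression ratios between burden levels
#'
#' For a fluorescent-fusion library measured under high and low burden,
#' computes the per-protein ratio of gated median GFP levels, excludes
#' proteins whose signal does not rise above the autofluorescence
#' threshold, fits a lowess trend of the ratio against log10 control
#' abundance, and reports the mean percentage increase over the
#' informative proteins.
#'
#' @param high_burden_medians,low_burden_medians Paired per-protein
#'   median GFP levels (arbitrary units).
#' @param control_abundance Positive per-protein abundance in the
#'   control (x-axis of the trend).
#' @param autofluorescence_threshold Detection limit (A.U.); proteins
#'   with either median below it are excluded.
#' @param span Lowess span (fraction of points).
#' @param iterations Lowess robustness iterations.
#' @return List with `table` (data.frame `ratio`, `control_abundance`,
#'   `included`), `trend` (lowess fit over included proteins, x =
#'   log10 abundance), and `mean_increase_pct`.
#' @export
gfp_ratio_trend <- function(high_burden_medians, low_burden_medians,
                            control_abundance,
                            autofluorescence_threshold = 200,
                            span = 0.3, iterations = 2) {
  n <- length(high_burden_medians)
  stopifnot(length(low_burden_medians) == n,
            length(control_abundance) == n,
            all(control_abundance > 0))
  included <- is.finite(high_burden_medians) &
    is.finite(low_burden_medians) &
    pmin(high_burden_medians, low_burden_medians) >=
      autofluorescence_threshold
  if (!any(included)) {
    stop("all proteins fall below the autofluorescence threshold",
         call. = FALSE)
  }
  ratio <- high_burden_medians / low_burden_medians
  trend <- lowess(log10(control_abundance[included]), ratio[included],
                  f = span, iter = iterations)
  list(
    table = data.frame(ratio = ratio,
                       control_abundance = control_abundance,
                       included = included),
    trend = trend,
    mean_increase_pct = 100 * (mean(ratio[included]) - 1)
  )
}
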