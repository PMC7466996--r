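#' Generations elapsed from a culture dilution factor
#'
#' A culture diluted by factor `d` and regrown to the same density has
#' doubled `log2(d)` times.
#'
#' @param dilution_factor Dilution factor (>= 1).
#' @return Number of generations.
#' @export
#' @examples
#' generations_from_dilution(1024)  # 10
generations_from_dilution <- function(dilution_factor) {
  stopifnot(is.numeric(dilution_factor))
  if (any(dilution_factor < 1)) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  log2(dilution_factor)
}

# The fitted log2-odds slope is taken directly as the wild type's
# per-generation advantage (no further conversion). Isolated here so
# the interpretation can be swapped in one place.
advantage_from_slope <- function(slope) -slope

#' Fitness from a competition time series
#'
#' Fits the log2 odds of the wild-type reference frequency against
#' generations by ordinary least squares. Under constant selection the
#' log2 odds are exactly linear in generations, so the slope is the
#' wild type's per-generation advantage; the competing (burden)
#' strain's `fitness_advantage` is its negative, and its division rate
#' relative to wild type is `100 * (1 + fitness_advantage)` percent.
#' Points with frequency exactly 0 or 1 carry no log-odds information
#' and are excluded with a message.
#'
#' @param series A `competition_series` data.frame (`generations`,
#'   `f_wt`), e.g. from [gen_competition_series()].
#' @return List of class `fitness_result`: `slope` (log2-odds per
#'   generation), `fitness_advantage` (of the competing strain),
#'   `pct_wt_division_rate`, `n_points`.
#' @export
competition_fitness <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("generations", "f_wt") %in% names(series)))
  ok <- is.finite(series$f_wt) & series$f_wt > 0 & series$f_wt < 1 &
    is.finite(series$generations)
  if (sum(!ok) > 0) {
    message(sum(!ok), " fixed or missing frequency points excluded")
  }
  if (sum(ok) < 2) stop("fewer than 2 usable timepoints", call. = FALSE)
  g <- series$generations[ok]
  if (length(unique(g)) < 2) stop("no spread in generations", call. = FALSE)
  lo <- log2(series$f_wt[ok] / (1 - series$f_wt[ok]))
  slope <- unname(coef(lm(lo ~ g))[2])
  adv <- advantage_from_slope(slope)
  structure(
    list(slope = slope, fitness_advantage = adv,
         pct_wt_division_rate = 100 * (1 + adv), n_points = sum(ok)),
    class = "fitness_result"
  )
}

#' Burden effect per integrated reporter copy
#'
#' Linear fit of relative division rate on reporter copy number across
#' a burden library. The slope S is the per-copy growth cost (expected
#' negative); the per-copy fitness is `wx = 1 + S`.
#'
#' @param copy_numbers Integer copy numbers (>= 3 strains, including a
#'   copy-0 wild type).
#' @param relative_mu Relative division rates (fraction of wild type).
#' @return List of class `burden_fit`: `S`, `per_copy_fitness`, `fit`
#'   (the `lm` object), `n_strains`.
#' @export
burden_per_copy <- function(copy_numbers, relative_mu) {
  stopifnot(is.numeric(copy_numbers), is.numeric(relative_mu),
            length(copy_numbers) == length(relative_mu))
  if (length(copy_numbers) < 3) stop("need >= 3 strains", call. = FALSE)
  if (!any(copy_numbers == 0)) {
    stop("library must include the copy-0 wild type", call. = FALSE)
  }
  if (length(unique(copy_numbers)) < 2) {
    stop("copy numbers are degenerate", call. = FALSE)
  }
  fit <- lm(relative_mu ~ copy_numbers)
  s <- unname(coef(fit)[2])
  structure(list(S = s, per_copy_fitness = 1 + s, fit = fit,
                 n_strains = length(copy_numbers)),
            class = "burden_fit")
}

#' Scaled epistasis between two fitness perturbations
#'
#' Deviation of the double-perturbation fitness from the multiplicative
#' expectation, scaled to `[-1, 1]`:
#' `epsilon = wxy - wx * wy`, divided by `|min(wx, wy) - wx * wy|` when
#' positive (buffering saturates when the double mutant is no fitter
#' than the better single) and by `wx * wy` when negative (aggravation
#' saturates at synthetic lethality, `wxy = 0`). Exactly 0 on the
#' multiplicative boundary; values outside `[-1, 1]` (possible with
#' noisy fitness estimates) are clamped with a warning.
#'
#' @param wx Relative fitness of perturbation x (e.g. burden per copy).
#' @param wy Relative fitness of perturbation y (e.g. a deletion).
#' @param wxy Relative fitness of the double perturbation. All three in
#'   `[0, 1.5]`; vectorized.
#' @return Scaled epistasis, same length as the inputs.
#' @export
#' @examples
#' scaled_epistasis(0.9, 0.8, 0.72)  #  0: multiplicative
#' scaled_epistasis(0.9, 0.8, 0.80)  # +1: full buffering
#' scaled_epistasis(0.9, 0.8, 0.00)  # -1: synthetic lethal
scaled_epistasis <- function(wx, wy, wxy) {
  n <- max(length(wx), length(wy), length(wxy))
  wx <- rep_len(wx, n); wy <- rep_len(wy, n); wxy <- rep_len(wxy, n)
  if (any(!is.finite(c(wx, wy, wxy))) ||
      any(c(wx, wy, wxy) < 0) || any(c(wx, wy, wxy) > 1.5)) {
    stop("fitness values must be finite and in [0, 1.5]", call. = FALSE)
  }
  eps <- wxy - wx * wy
  out <- numeric(n)
  pos <- eps > 0
  neg <- eps < 0
  if (any(pos)) {
    denom <- abs(pmin(wx, wy)[pos] - (wx * wy)[pos])
    if (any(denom == 0)) {
      stop("undefined scaling: min(wx, wy) equals wx * wy with wxy above it",
           call. = FALSE)
    }
    out[pos] <- eps[pos] / denom
  }
  if (any(neg)) {
    out[neg] <- eps[neg] / (wx * wy)[neg]  # lethality bound w~xy = 0
  }
  clamped <- abs(out) > 1
  if (any(clamped)) {
    warning(sum(clamped), " values clamped to [-1, 1]", call. = FALSE)
    out <- pmax(-1, pmin(1, out))
  }
  out
}
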