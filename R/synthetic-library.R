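#' Generate a synthetic burden expression library
#'
#' Builds the mean-field expression matrix of a tandem-integration
#' burden library. A strain with `c` reporter copies scales every
#' promoter's attempt rate by `g(c) = 1 + capacity_slope * c`; the
#' realized initiation rate follows the non-paralyzable dead-time mean
#' `r_i(c) = g(c) a_i / (1 + g(c) a_i tau)` and mRNA abundance is
#' `m_i(c) = r_i(c) / decay_i`, perturbed by multiplicative log-normal
#' measurement noise. Strain growth rate decreases and cell size
#' increases linearly with copy number.
#'
#' The analytic dead-time mean is used here (fast, deterministic); the
#' event-level simulator in [simulate_initiation()] is the independent
#' cross-check of that mean.
#'
#' @param catalog A [gen_gene_catalog()] catalog.
#' @param config The [sim_config()] that produced it.
#' @return A list of class `burden_library`: `expression` (gene x strain
#'   matrix of linear-scale abundances), `strains` (data.frame
#'   `sample_id`, `copy_number`, `relative_growth_rate`,
#'   `relative_size`).
#' @export
gen_burden_library <- function(catalog, config) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "sim_config"))
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  copies <- config$copy_numbers
  mu <- 1 - config$growth_slope * copies
  if (any(mu <= 0)) {
    stop("growth_slope * max(copy_numbers) >= 1: negative growth rate",
         call. = FALSE)
  }
  tau <- config$dead_time_s
  with_seed(config$seed + 1L, {
    expr <- vapply(copies, function(cc) {
      g <- 1 + config$capacity_slope * cc
      r <- g * catalog$attempt_rate / (1 + g * catalog$attempt_rate * tau)
      m <- r / catalog$decay_rate
      m * 2^rnorm(nrow(catalog), 0, config$noise_log2_sd)
    }, numeric(nrow(catalog)))
    dimnames(expr) <- list(catalog$gene_id, sprintf("copy%02d", copies))
    strains <- data.frame(
      sample_id = colnames(expr),
      copy_number = copies,
      relative_growth_rate = mu,
      relative_size = 1 + config$size_slope * copies,
      stringsAsFactors = FALSE
    )
    structure(list(expression = expr, strains = strains),
              class = "burden_library")
  })
}

#' Generate a synthetic deletion-mutant signature compendium
#'
#' Emulates a compendium of deletion-mutant transcription signatures
#' (gene x mutant log2 ratios versus wild type) containing three truth
#' classes, kept as labels for testing:
#' \describe{
#'   \item{capacity}{transcription-capacity mutants: global capacity
#'     factor `g < 1`; their relative signature follows the dead-time
#'     model, so highly expressed (near-saturated) genes drop the least
#'     and the signature slope versus log abundance is positive.}
#'   \item{slow_growth}{mutants expressing only a shared slow-growth
#'     program: signature proportional to one program vector drawn
#'     independently of abundance.}
#'   \item{null}{no systematic signature, noise only.}
#' }
#' Signatures are relative (each strain's abundances are normalized to
#' their sum before the log2 ratio), matching how burden signatures are
#' computed.
#'
#' @param catalog A [gen_gene_catalog()] catalog.
#' @param config The [sim_config()]; `n_mutants` must be >= 2.
#' @param noise_log2_sd Signature noise sd (log2 units); defaults to
#'   the config's `noise_log2_sd`.
#' @return A list of class `mutant_compendium`: `signatures` (gene x
#'   mutant matrix), `mutants` (data.frame `mutant_id`, `class`,
#'   `capacity_factor`, `relative_growth_rate`).
#' @export
gen_mutant_compendium <- function(catalog, config,
                                  noise_log2_sd = config$noise_log2_sd) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "sim_config"))
  n_mut <- config$n_mutants
  if (n_mut < 2L) stop("`n_mutants` must be >= 2", call. = FALSE)
  n_cap <- ceiling(n_mut / 3)
  n_slow <- ceiling((n_mut - n_cap) / 2)
  n_null <- n_mut - n_cap - n_slow
  a <- catalog$attempt_rate
  tau <- config$dead_time_s
  rel_wt <- .sum_norm(a / (1 + a * tau))
  with_seed(config$seed + 2L, {
    program <- rnorm(nrow(catalog))  # shared slow-growth program
    g_cap <- runif(n_cap, 0.5, 0.9)
    mu_slow <- runif(n_slow, 0.5, 0.9)
    mu_null <- runif(max(n_null, 0L), 0.97, 1.03)
    cols <- vector("list", n_mut)
    meta <- data.frame(
      mutant_id = sprintf("mut%03d", seq_len(n_mut)),
      class = rep(c("capacity", "slow_growth", "null"),
                  times = c(n_cap, n_slow, n_null)),
      capacity_factor = c(g_cap, rep(NA_real_, n_slow + n_null)),
      relative_growth_rate = c(g_cap, mu_slow, mu_null),
      stringsAsFactors = FALSE
    )
    for (j in seq_len(n_cap)) {
      g <- g_cap[j]
      rel_mut <- .sum_norm(g * a / (1 + g * a * tau))
      cols[[j]] <- log2(rel_mut / rel_wt)
    }
    for (j in seq_len(n_slow)) {
      cols[[n_cap + j]] <- 2 * (1 - mu_slow[j]) * program
    }
    for (j in seq_len(n_null)) {
      cols[[n_cap + n_slow + j]] <- numeric(nrow(catalog))
    }
    sig <- do.call(cbind, cols) +
      matrix(rnorm(nrow(catalog) * n_mut, 0, noise_log2_sd),
             nrow = nrow(catalog))
    dimnames(sig) <- list(catalog$gene_id, meta$mutant_id)
    structure(list(signatures = sig, mutants = meta),
              class = "mutant_compendium")
  })
}

# Normalize a positive vector to sum 1 (within-sample relative abundance).
.sum_norm <- function(x) x / sum(x)
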