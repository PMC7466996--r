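#' Promoter parameters for the initiation model
#'
#' Describes one promoter for the dead-time initiation model: initiation
#' attempts arrive stochastically at `attempt_rate`, and an attempt
#' succeeds only if at least `dead_time` seconds have passed since the
#' last successful initiation (the time the polymerase needs to clear
#' the start site). Optionally, a two-state (telegraph) promoter can be
#' layered on top: attempts are then only possible while the promoter is
#' in the ON state.
#'
#' @param attempt_rate Initiation attempts per second (>= 0).
#' @param dead_time Promoter-clearance dead time tau, in seconds (> 0).
#' @param burst_on_rate,burst_off_rate Optional OFF->ON and ON->OFF
#'   switching rates (1/s) of the two-state promoter. Either both are
#'   given or neither.
#' @return An object of class `initiation_params`.
#' @export
#' @examples
#' initiation_params(attempt_rate = 0.5, dead_time = 1.05)
initiation_params <- function(attempt_rate, dead_time,
                              burst_on_rate = NULL, burst_off_rate = NULL) {
  stop_if_not_number(attempt_rate, "attempt_rate", lower = 0)
  stop_if_not_number(dead_time, "dead_time")
  if (dead_time <= 0) stop("`dead_time` must be > 0", call. = FALSE)
  if (is.null(burst_on_rate) != is.null(burst_off_rate)) {
    stop("burst rates must be given together or not at all", call. = FALSE)
  }
  bursting <- !is.null(burst_on_rate)
  if (bursting) {
    stop_if_not_number(burst_on_rate, "burst_on_rate", lower = 0)
    stop_if_not_number(burst_off_rate, "burst_off_rate", lower = 0)
    if (burst_on_rate <= 0 || burst_off_rate <= 0) {
      stop("burst rates must be > 0 when set", call. = FALSE)
    }
  }
  structure(
    list(attempt_rate = attempt_rate, dead_time = dead_time,
         burst_on_rate = burst_on_rate, burst_off_rate = burst_off_rate,
         bursting = bursting),
    class = "initiation_params"
  )
}

#' Minimal promoter-clearance time from polymerase geometry
#'
#' The shortest possible interval between two successful initiation
#' events is the time the polymerase needs to elongate its own DNA
#' footprint away from the start site: `footprint_bp` divided by the
#' elongation velocity. Its reciprocal is the maximal initiation rate a
#' promoter can sustain. With the commonly cited yeast values (35 bp
#' footprint, 2 kb/min elongation) the quotient is 1.05 s per
#' transcript.
#'
#' @param footprint_bp Polymerase footprint on DNA, base pairs (> 0).
#' @param elongation_bp_per_min Elongation velocity, bp per minute (> 0).
#' @return Clearance time in seconds.
#' @export
#' @examples
#' clearance_time(35, 2000)      # 1.05 s
#' 1 / clearance_time(35, 2000)  # maximal initiation rate, ~0.95 /s
clearance_time <- function(footprint_bp = 35, elongation_bp_per_min = 2000) {
  stop_if_not_number(footprint_bp, "footprint_bp")
  stop_if_not_number(elongation_bp_per_min, "elongation_bp_per_min")
  if (footprint_bp <= 0) stop("`footprint_bp` must be > 0", call. = FALSE)
  if (elongation_bp_per_min <= 0) {
    stop("`elongation_bp_per_min` must be > 0", call. = FALSE)
  }
  footprint_bp / (elongation_bp_per_min / 60)
}

#' Mean successful-initiation rate of the dead-time model
#'
#' For a constitutive promoter with Poisson attempts at rate `a` and a
#' non-paralyzable dead time `tau`, renewal theory gives the mean rate
#' of successful initiations in closed form: the interval between
#' successes is `tau` plus an Exp(a) waiting time, so the effective rate
#' is `a / (1 + a * tau)`. It rises linearly at small `a` and saturates
#' at `1 / tau`.
#'
#' @param params An [initiation_params()] object without burst kinetics
#'   (no closed form is implemented for the bursting promoter).
#' @return Successful initiations per second.
#' @export
#' @examples
#' p <- initiation_params(1, 1)
#' analytic_effective_rate(p)  # 1/2: at a = 1/tau half the attempts land
analytic_effective_rate <- function(params) {
  stopifnot(inherits(params, "initiation_params"))
  if (params$bursting) {
    stop("no closed form for bursting promoters; use simulate_initiation()",
         call. = FALSE)
  }
  .eff_rate(params$attempt_rate, params$dead_time)
}

.eff_rate <- function(a, tau) a / (1 + a * tau)

# Standard error of the simulated effective rate over duration T, from
# renewal CLT: inter-success intervals are tau + Exp(1/a), so
# var(N(T)) ~ T * sigma^2 / mu1^3 with mu1 = tau + 1/a, sigma = 1/a.
.eff_rate_se <- function(a, tau, duration_s) {
  if (a == 0) return(0)
  mu1 <- tau + 1 / a
  (1 / a) / sqrt(mu1^3 * duration_s)
}

#' Simulate stochastic initiation gated by a dead time
#'
#' Draws initiation attempts as a Poisson process at the promoter's
#' attempt rate (thinned to ON periods when burst kinetics are set) and
#' accepts an attempt iff at least `dead_time` seconds have elapsed
#' since the previous accepted attempt; the first attempt of a run
#' always succeeds.
#'
#' @param params An [initiation_params()] object.
#' @param duration_s Simulated time, seconds (> 0).
#' @param seed Integer seed for this run.
#' @return An object of class `initiation_sim`: a list with
#'   `duration_s`, `n_attempts`, `n_success`, `effective_rate`
#'   (successes per second) and `success_times`.
#' @seealso [analytic_effective_rate()] for the closed-form oracle.
#' @export
#' @examples
#' sim <- simulate_initiation(initiation_params(2, 1), 1e4, seed = 1)
#' sim$effective_rate          # close to 2/3
simulate_initiation <- function(params, duration_s, seed = 1L) {
  stopifnot(inherits(params, "initiation_params"))
  stop_if_not_number(duration_s, "duration_s")
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  a <- params$attempt_rate
  attempts <- if (a == 0) numeric(0) else with_seed(seed, {
    t <- .poisson_times(a, duration_s)
    if (params$bursting) {
      t <- t[.in_on_state(t, duration_s,
                          params$burst_on_rate, params$burst_off_rate)]
    }
    t
  })
  succ <- dead_time_filter(attempts, params$dead_time)
  structure(
    list(duration_s = duration_s,
         n_attempts = length(attempts),
         n_success = length(succ),
         effective_rate = length(succ) / duration_s,
         success_times = succ),
    class = "initiation_sim"
  )
}

# Event times of a homogeneous Poisson process on [0, duration].
.poisson_times <- function(rate, duration) {
  n_draw <- qpois(1 - 1e-12, rate * duration) + 10L
  t <- cumsum(rexp(n_draw, rate))
  while (t[length(t)] < duration) {  # astronomically rare top-up
    t <- c(t, t[length(t)] + cumsum(rexp(n_draw, rate)))
  }
  t[t <= duration]
}

# For each event time, is the telegraph promoter ON? State alternates
# with exponential dwell times; the initial state is drawn from the
# stationary distribution.
.in_on_state <- function(times, duration, on_rate, off_rate) {
  start_on <- runif(1) < on_rate / (on_rate + off_rate)
  # dwell i is ON if (i odd) == start_on; rates alternate accordingly
  bounds <- numeric(0)
  t_end <- 0
  state_on <- start_on
  repeat {
    dwell <- rexp(1, if (state_on) off_rate else on_rate)
    t_end <- t_end + dwell
    bounds <- c(bounds, t_end)
    state_on <- !state_on
    if (t_end > duration) break
  }
  seg <- findInterval(times, bounds) # 0-based segment index
  if (start_on) seg %% 2 == 0 else seg %% 2 == 1
}

#' Effective initiation rate across a grid of attempt rates
#'
#' Runs one [simulate_initiation()] per attempt rate and returns the
#' simulated rate-response curve: statistically increasing, concave, and
#' saturating at `1 / dead_time`.
#'
#' @param a_grid Sorted ascending attempt rates (1/s).
#' @param dead_time Dead time tau, seconds.
#' @param duration_s Simulated time per grid point.
#' @param seed Base seed; grid point i uses `seed + i - 1`.
#' @return data.frame with columns `attempt_rate`, `effective_rate`,
#'   `analytic_rate`, `se` (renewal-theory standard error).
#' @export
rate_response_curve <- function(a_grid, dead_time, duration_s, seed = 1L) {
  stopifnot(is.numeric(a_grid), length(a_grid) >= 1, !is.unsorted(a_grid))
  eff <- vapply(seq_along(a_grid), function(i) {
    simulate_initiation(initiation_params(a_grid[i], dead_time),
                        duration_s, seed = seed + i - 1L)$effective_rate
  }, numeric(1))
  data.frame(
    attempt_rate = a_grid,
    effective_rate = eff,
    analytic_rate = .eff_rate(a_grid, dead_time),
    se = vapply(a_grid, .eff_rate_se, numeric(1),
                tau = dead_time, duration_s = duration_s)
  )
}

#' Fold change of the effective rate under a capacity increase
#'
#' When the global transcription capacity rises by a factor `g` (as
#' assumed in burdened cells), a promoter's attempt rate scales from `a`
#' to `g * a` while the dead time is unchanged. The resulting fold
#' change of the successful-initiation rate,
#' `[g a / (1 + g a tau)] / [a / (1 + a tau)] = g (1 + a tau) / (1 + g a tau)`,
#' equals `g` for rarely transcribed genes and falls to 1 for genes
#' already at saturation: highly expressed genes cannot follow a global
#' scale-up.
#'
#' @param params [initiation_params()] without burst kinetics.
#' @param g Capacity factor (>= 1 expected; `g < 1` is computed with a
#'   warning and describes a capacity *loss*).
#' @return Dimensionless fold change in `[min(1, g), max(1, g)]`.
#' @export
#' @examples
#' burden_fold_change(initiation_params(1, 1), g = 2)  # 4/3
burden_fold_change <- function(params, g) {
  stopifnot(inherits(params, "initiation_params"))
  if (params$bursting) {
    stop("closed-form fold change requires a constitutive promoter",
         call. = FALSE)
  }
  stop_if_not_number(g, "g", lower = 0)
  if (g < 1) warning("g < 1: computing a capacity loss", call. = FALSE)
  a <- params$attempt_rate
  tau <- params$dead_time
  if (a == 0) return(g)  # limit a -> 0
  g * (1 + a * tau) / (1 + g * a * tau)
}
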