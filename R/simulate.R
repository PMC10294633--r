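#' One step of the discrete-time infection recursion
#'
#' The simulator advances in steps of one predator life cycle
#' (`cycle_step_min` minutes) over three compartments: free attack-phase
#' predators `F`, occupied bdelloplasts `B`, and unattacked prey `P`.  In a
#' step, every free predator that can find prey attacks (attachments
#' `A = min(F, P)`), each attacked prey becomes a bdelloplast, and every
#' bdelloplast formed in the *previous* step lyses, releasing
#' `progeny_mean` progeny that immediately join the free pool:
#'
#' \deqn{P' = P - A, \quad B' = A, \quad F' = (F - A) + p \cdot B.}
#'
#' Populations are real-valued (the progeny mean may be fractional, e.g.
#' 3.5); no rounding occurs during iteration.
#'
#' @param state list with fields `step_index`, `t_min`, `free_predators`,
#'   `bdelloplasts`, `unattacked_prey` (see [population_state()]).
#' @param params a [load_prey_params()] bundle (fields `progeny_mean` and
#'   `cycle_step_min` are used).
#' @return the next `population_state`.
#' @export
sim_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"))
  p <- params$progeny_mean
  dt <- params$cycle_step_min
  if (!is.finite(dt) || dt <= 0) stop("params must carry a positive cycle_step_min")
  a <- min(state$free_predators, state$unattacked_prey)
  population_state(
    step_index = state$step_index + 1L,
    cycle_step_min = dt,
    free_predators = (state$free_predators - a) + p * state$bdelloplasts,
    bdelloplasts = a,
    unattacked_prey = state$unattacked_prey - a
  )
}

#' Construct a population state
#'
#' @param step_index integer step number (0 = inoculation).
#' @param cycle_step_min duration of one step in minutes; `t_min` is always
#'   `step_index * cycle_step_min`.
#' @param free_predators,bdelloplasts,unattacked_prey compartment counts
#'   (real-valued, `>= 0`).
#' @return an object of class `population_state`.
#' @export
population_state <- function(step_index, cycle_step_min, free_predators,
                             bdelloplasts, unattacked_prey) {
  if (step_index < 0 || step_index != round(step_index)) {
    stop("step_index must be a non-negative integer")
  }
  counts <- c(free_predators, bdelloplasts, unattacked_prey)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all compartments must be finite and >= 0")
  }
  structure(
    list(step_index = as.integer(step_index),
         t_min = step_index * cycle_step_min,
         cycle_step_min = cycle_step_min,
         free_predators = free_predators,
         bdelloplasts = bdelloplasts,
         unattacked_prey = unattacked_prey),
    class = "population_state"
  )
}

#' Run the infection simulation to complete lysis
#'
#' Iterates [sim_step()] from `(F = initial_predators, B = 0,
#' P = initial_prey)` until no unattacked prey and no occupied bdelloplasts
#' remain, or `max_steps` is reached.  By default the initial prey count is
#' the killing-curve culture: `culture_volume_ml * cells_per_ml_at_od1`
#' cells at OD600 = 1.0.  Prey do not replicate and predators do not die
#' (the killing-curve buffer conditions).
#'
#' @param params a [load_prey_params()] bundle.
#' @param initial_predators free predator cells at time 0 (default: the
#'   printed inoculum).
#' @param initial_prey unattacked prey cells at time 0.
#' @param max_steps iteration cap; reaching it without termination is
#'   flagged (`attr(, "terminated") == FALSE`), never silently truncated.
#' @return a `predation_trajectory`: a data frame with columns `step`,
#'   `t_min`, `free_predators`, `bdelloplasts`, `unattacked_prey` (one row
#'   per state, including the initial one), with attributes `params` and
#'   `terminated`.
#' @examples
#' traj <- simulate_predation(load_prey_params("P_mirabilis"))
#' complete_lysis_time(traj)  # 2500 min
#' @export
simulate_predation <- function(params,
                               initial_predators = params$predator_inoculum,
                               initial_prey = params$culture_volume_ml *
                                 params$cells_per_ml_at_od1,
                               max_steps = 10000L) {
  if (!is.finite(initial_predators) || initial_predators <= 0) {
    stop("initial_predators must be positive")
  }
  if (!is.finite(initial_prey) || initial_prey <= 0) {
    stop("initial_prey must be positive")
  }
  if (!is_count(max_steps)) stop("max_steps must be a positive integer")
  state <- population_state(0L, params$cycle_step_min,
                            initial_predators, 0, initial_prey)
  states <- vector("list", 64L)
  states[[1L]] <- state
  n <- 1L
  terminated <- FALSE
  while (state$step_index < max_steps) {
    state <- sim_step(state, params)
    n <- n + 1L
    if (n > length(states)) states <- c(states, vector("list", length(states)))
    states[[n]] <- state
    if (state$unattacked_prey == 0 && state$bdelloplasts == 0) {
      terminated <- TRUE
      break
    }
  }
  states <- states[seq_len(n)]
  traj <- data.frame(
    step = vapply(states, `[[`, integer(1), "step_index"),
    t_min = vapply(states, `[[`, numeric(1), "t_min"),
    free_predators = vapply(states, `[[`, numeric(1), "free_predators"),
    bdelloplasts = vapply(states, `[[`, numeric(1), "bdelloplasts"),
    unattacked_prey = vapply(states, `[[`, numeric(1), "unattacked_prey")
  )
  structure(traj,
            params = params,
            terminated = terminated,
            class = c("predation_trajectory", "data.frame"))
}

#' Time of complete prey lysis
#'
#' Complete lysis is declared at the first step at which both the
#' unattacked prey and the occupied bdelloplasts are zero: prey still
#' enclosed in a bdelloplast counts as not yet lysed.
#'
#' @param traj a terminated `predation_trajectory`.
#' @return time in minutes.
#' @export
complete_lysis_time <- function(traj) {
  stopifnot(inherits(traj, "predation_trajectory"))
  if (!isTRUE(attr(traj, "terminated"))) {
    stop("trajectory did not reach complete lysis within max_steps")
  }
  i <- which(traj$unattacked_prey == 0 & traj$bdelloplasts == 0)[1L]
  traj$t_min[i]
}

#' Project a trajectory onto an OD600-like kill curve
#'
#' Intact biomass (unattacked prey plus bdelloplasts, which retain the prey
#' envelope until lysis) scatters light; the optical density is taken as an
#' affine function of the intact fraction:
#' `OD(t) = od_floor + (od_top - od_floor) * (P_t + B_t) / P_0`.
#' By default the curve is evaluated at the simulated states; `times`
#' resamples it by linear interpolation onto an arbitrary grid (e.g. the
#' 20-min Bioscreen reading schedule), holding the final value beyond the
#' last state.
#'
#' @param traj a `predation_trajectory`.
#' @param od_top OD600 at time 0 (must exceed `od_floor`).
#' @param od_floor OD600 after complete lysis.
#' @param times optional numeric vector of evaluation times (minutes).
#' @return a [kill_curve()] data frame.
#' @export
od_projection <- function(traj, od_top = 1.0, od_floor = 0.05, times = NULL) {
  stopifnot(inherits(traj, "predation_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory")
  if (!(od_top > od_floor)) stop("od_top must exceed od_floor")
  frac <- (traj$unattacked_prey + traj$bdelloplasts) / traj$unattacked_prey[1L]
  if (is.null(times)) {
    kill_curve(traj$t_min, od_floor + (od_top - od_floor) * frac,
               species = attr(traj, "params")$species)
  } else {
    f <- stats::approx(traj$t_min, frac, xout = times, rule = 2)$y
    kill_curve(times, od_floor + (od_top - od_floor) * f,
               species = attr(traj, "params")$species)
  }
}

#' @export
print.predation_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<predation_trajectory: %s, %d states, %s>\n",
              p$species, nrow(x),
              if (isTRUE(attr(x, "terminated"))) {
                sprintf("complete lysis at %g min", complete_lysis_time(x))
              } else "not terminated"))
  print.data.frame(utils::head(as.data.frame(x), 12L))
  if (nrow(x) > 12L) cat(sprintf("  ... %d more states\n", nrow(x) - 12L))
  invisible(x)
}
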