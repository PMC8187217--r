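#' Trajectory configuration for the stochastic simulation algorithm
#'
#' @param x0 initial state (integer vector over species).
#' @param t_end end time (may be `Inf` when `max_events` is finite).
#' @param max_events maximum number of reaction events.
#' @param burn_in fraction of simulated time discarded before estimating
#'   occupancies, in `[0, 1)`.
#' @param seed integer random seed; a fixed seed gives a bit-identical
#'   trajectory.
#' @return An object of class `"crn_trajectory_config"`.
#' @export
trajectory_config <- function(x0, t_end = Inf, max_events = 10000L,
                              burn_in = 0.1, seed = 1L) {
  stopifnot(burn_in >= 0, burn_in < 1,
            is.finite(t_end) || is.finite(max_events))
  structure(list(x0 = as.integer(x0), t_end = t_end,
                 max_events = max_events, burn_in = burn_in,
                 seed = as.integer(seed)),
            class = "crn_trajectory_config")
}

#' Exact stochastic simulation (Gillespie) of a reaction network
#'
#' Samples the continuous-time Markov chain exactly: exponential waiting
#' times with the total intensity, reaction selection proportional to the
#' per-reaction intensities (cumulative-sum inversion, ties broken in
#' reaction file order). Terminates at the end time, the event bound, or
#' absorption (no active reaction), which is reported, not an error.
#'
#' @inheritParams intensity
#' @param cfg a [trajectory_config()].
#' @return A list with `times` (event times, starting at 0), `states`
#'   (integer matrix, one row per event time), and `absorbed` (logical).
#' @export
ssa_trajectory <- function(g, cfg, kin = NULL) {
  kin <- resolve_kinetics(g, kin)
  x <- as_state(g, cfg$x0)
  set.seed(cfg$seed)
  xi <- reaction_vectors(g)
  times <- numeric(cfg$max_events + 1L)
  states <- matrix(0L, cfg$max_events + 1L, length(x))
  states[1L, ] <- x
  t <- 0
  n <- 1L
  absorbed <- FALSE
  while (n <= cfg$max_events) {
    lam <- propensities(g, kin, x)
    total <- sum(lam)
    if (total <= 0) { absorbed <- TRUE; break }
    dt <- stats::rexp(1L, rate = total)
    if (t + dt > cfg$t_end) { t <- cfg$t_end; break }
    t <- t + dt
    j <- findInterval(stats::runif(1L) * total, cumsum(lam),
                      left.open = TRUE) + 1L
    x <- x + xi[j, ]
    n <- n + 1L
    times[n] <- t
    states[n, ] <- x
  }
  list(times = times[seq_len(n)], states = states[seq_len(n), , drop = FALSE],
       absorbed = absorbed)
}

#' Empirical stationary distribution from a trajectory
#'
#' Time-weighted occupancy of the states of a finite closed component after
#' discarding the burn-in fraction of the simulated time span (the
#' stationary law of a CTMC weights states by holding times, so event
#' counting would be biased). Standard errors are binomial-style, based on
#' an effective sample size of post-burn-in events.
#'
#' @inheritParams ssa_trajectory
#' @param comp a finite closed `"crn_component"` containing the initial
#'   state.
#' @return A `"crn_distribution"` with attribute `"se"` (per-state standard
#'   errors) and `"n_events"`.
#' @export
empirical_stationary <- function(g, cfg, comp, kin = NULL) {
  kin <- resolve_kinetics(g, kin)
  if (comp$truncated || !comp$closed)
    stop("empirical estimation needs a finite closed component")
  traj <- ssa_trajectory(g, cfg, kin)
  nt <- length(traj$times)
  keys0 <- state_keys(comp$states)
  if (nt < 2L) {
    ## absorbed immediately: all mass on the initial state
    p0 <- as.numeric(keys0 == state_key(traj$states[1L, ]))
    dist <- new_distribution(g, comp, p = p0)
    attr(dist, "se") <- rep(0, length(p0))
    attr(dist, "n_events") <- 0L
    return(dist)
  }
  t_total <- traj$times[nt]
  t_burn <- cfg$burn_in * t_total
  keys <- state_keys(comp$states)
  occ <- stats::setNames(numeric(length(keys)), keys)
  tr_keys <- state_keys(traj$states)
  unknown <- setdiff(unique(tr_keys), keys)
  if (length(unknown))
    stop("trajectory left the component (state ", unknown[1],
         "): closure bug")
  n_eff <- 0L
  for (i in seq_len(nt - 1L)) {
    a <- max(traj$times[i], t_burn)
    b <- traj$times[i + 1L]
    if (b <= a) next
    occ[tr_keys[i]] <- occ[tr_keys[i]] + (b - a)
    n_eff <- n_eff + 1L
  }
  ## the final holding interval is censored; weight it to the end time
  if (t_total > t_burn && traj$times[nt] < t_total) {
    occ[tr_keys[nt]] <- occ[tr_keys[nt]] + t_total - max(traj$times[nt], t_burn)
  }
  p <- occ / sum(occ)
  dist <- new_distribution(g, comp, p = pmax(p, 0))
  attr(dist, "se") <- sqrt(pmax(p * (1 - p), 0) / max(1L, n_eff))
  attr(dist, "n_events") <- nt - 1L
  dist
}
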