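#' Conditional rate of a single-bond transition
#'
#' The rate at which the aggregation graph moves to the Hamming neighbour
#' obtained by toggling \{u, v\}: `rate = A / (1 + exp(beta * dH - dS))`,
#' where `dH` is the energy difference of the move (from [change_stats()])
#' and `dS` the difference in log reference measure (0 under the counting
#' measure). Uphill moves with `beta * dH >> 1` recover the Arrhenius form
#' `A * exp(-beta * dH)`; strongly downhill moves saturate at the collision
#' frequency `A`.
#'
#' @param g An [aggregation_graph()].
#' @param u,v The dyad to toggle.
#' @param p A [model_params()] object.
#' @return Rate in events per unit time, strictly inside `(0, A)`.
#' @export
transition_rate <- function(g, u, v, p) {
  stopifnot(inherits(p, "model_params"))
  dH <- sum(hamiltonian_coefficients(p) * change_stats(g, u, v))
  p$A / (1 + exp(beta_of(p) * dH))
}

#' Exit rate and transition probabilities over all Hamming neighbours
#'
#' For the current state `i`, computes the rate `r_ij` of every single-bond
#' toggle, the exit rate `R_i+ = sum_j r_ij`, and the probability
#' `P_ij = r_ij / R_i+` that the next realised transition is to neighbour
#' `j`. The waiting time to leave state `i` is exponential with mean
#' `1 / R_i+`.
#'
#' @param g An [aggregation_graph()] with at least 2 vertices.
#' @param p A [model_params()] object.
#' @return List with `dyads` (two-column matrix in canonical order),
#'   `rates`, `exit_rate` and `probs` (summing to 1).
#' @export
transition_distribution <- function(g, p) {
  stopifnot_graph(g)
  stopifnot(inherits(p, "model_params"))
  if (g$n < 2L) stop("no transitions exist for n < 2")
  rates <- cpp_all_rates(g$n, zero_based(g$edges),
                         hamiltonian_coefficients(p), beta_of(p), p$A)
  exit <- sum(rates)
  list(dyads = all_dyads(g$n), rates = rates, exit_rate = exit,
       probs = rates / exit)
}

#' Kinetic simulation of fibrillization from free monomers
#'
#' Simulates the continuous-time Markov chain of aggregation-graph dynamics:
#' starting from the empty graph (all monomers free) at time 0, each step
#' draws an exponential waiting time with rate equal to the current exit
#' rate, then realises one single-bond toggle with probability proportional
#' to its transition rate. Time is reported in units of inverse collision
#' rate (so `A = 1` makes one time unit one expected collision per dyad
#' pathway).
#'
#' @param n Monomer count (>= 2).
#' @param p A [model_params()] object.
#' @param max_events Stop after this many bond-change events (optional).
#' @param max_time Stop when the next event would pass this time (optional).
#'   At least one stopping criterion must be given.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param frame_interval Events between stored full snapshots when frames
#'   are materialised (see [trajectory_graph()]); the event stream itself is
#'   always complete.
#' @param method `"incremental"` updates only the transition rates whose
#'   change statistics the last toggle can have affected; `"naive"`
#'   recomputes every dyad rate after each event. The two are event-for-event
#'   identical; naive mode exists as an internal cross-check.
#' @return An object of class `fibril_trajectory`: list with `n`, `events`
#'   (data frame `event`, `time`, `u`, `v`, `action`), `end_time`, `seed`,
#'   `frame_interval` and `params`.
#' @export
simulate_fibrillization <- function(n, p, max_events = NULL, max_time = NULL,
                                    seed, frame_interval = 100L,
                                    method = c("incremental", "naive")) {
  n <- as.integer(n)
  stopifnot(inherits(p, "model_params"))
  if (n < 2L) stop("n must be >= 2")
  method <- match.arg(method)
  if (is.null(max_events) && is.null(max_time))
    stop("give max_events and/or max_time")
  if (!is.null(max_events) && max_events < 1) stop("max_events must be >= 1")
  if (!is.null(max_time) && max_time <= 0) stop("max_time must be > 0")
  set.seed(as.integer(seed))
  res <- cpp_simulate(n, hamiltonian_coefficients(p), beta_of(p), p$A,
                      if (is.null(max_events)) 0 else as.numeric(max_events),
                      if (is.null(max_time)) 0 else as.numeric(max_time),
                      method == "naive")
  events <- data.frame(event = seq_along(res$time),
                       time = res$time,
                       u = res$u + 1L,
                       v = res$v + 1L,
                       action = ifelse(res$add == 1L, "add", "del"),
                       stringsAsFactors = FALSE)
  new_trajectory(n, events, end_time = res$end_time, seed = as.integer(seed),
                 frame_interval = as.integer(frame_interval), params = p)
}

new_trajectory <- function(n, events, end_time, seed, frame_interval, params) {
  structure(list(n = n, events = events, end_time = end_time, seed = seed,
                 frame_interval = frame_interval, params = params),
            class = "fibril_trajectory")
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fibril_trajectory> %d monomers, %d events, t in [0, %.4g]\n",
    x$n, nrow(x$events), x$end_time))
  invisible(x)
}

#' Graph state at a point along a trajectory
#'
#' Replays the event stream and returns the aggregation graph after the
#' given number of events (0 gives the initial empty graph).
#'
#' @param traj A `fibril_trajectory`.
#' @param event Number of events applied, in `0..nrow(traj$events)`.
#' @return An [aggregation_graph()].
#' @export
trajectory_graph <- function(traj, event = nrow(traj$events)) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  event <- as.integer(event)
  if (event < 0L || event > nrow(traj$events))
    stop("event out of range")
  if (event == 0L) return(aggregation_graph(traj$n))
  ev <- traj$events[seq_len(event), , drop = FALSE]
  # net effect: a dyad is present iff its last action was "add"
  key <- paste(pmin(ev$u, ev$v), pmax(ev$u, ev$v))
  last <- !duplicated(key, fromLast = TRUE)
  on <- ev$action[last] == "add"
  keep <- ev[last, c("u", "v"), drop = FALSE][on, , drop = FALSE]
  aggregation_graph(traj$n, as.matrix(keep))
}

#' Frozen (event-free) trajectory from a static graph
#'
#' Wraps a fixed aggregation state as a trajectory whose graph never
#' changes, by emitting its edges as instantaneous initial additions. Used
#' for fixtures and for running the metric layer on a single structure.
#'
#' @param g An [aggregation_graph()].
#' @param end_time Nominal duration of the frozen interval.
#' @return A `fibril_trajectory`.
#' @export
frozen_trajectory <- function(g, end_time = 1) {
  stopifnot_graph(g)
  m <- nrow(g$edges)
  # edges appear in a vanishingly short initial window so that event times
  # stay strictly increasing while the state is effectively constant
  events <- data.frame(event = seq_len(m),
                       time = seq_len(m) * (end_time * 1e-12),
                       u = g$edges[, 1L], v = g$edges[, 2L],
                       action = rep("add", m),
                       stringsAsFactors = FALSE)
  new_trajectory(g$n, events, end_time = end_time, seed = NA_integer_,
                 frame_interval = max(1L, m), params = NULL)
}
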