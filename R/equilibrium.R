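#' Dyads of a graph on n vertices
#'
#' All unordered vertex pairs in the canonical order used throughout the
#' package (lexicographic in `(u, v)` with `u < v`).
#'
#' @param n Vertex count.
#' @return Two-column integer matrix with `choose(n, 2)` rows.
#' @export
all_dyads <- function(n) {
  n <- as.integer(n)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- utils::combn(n, 2L)
  cbind(idx[1L, ], idx[2L, ])
}

#' Exact equilibrium distribution by enumeration
#'
#' Enumerates all `2^choose(n,2)` labelled graph microstates on `n` monomers
#' and assigns each the Boltzmann probability
#' `Pr(G = g) = exp(-H(g)/(k_B T)) h(g) / Z`. Feasible only for tiny systems
#' (`n <= 5`, 1024 microstates); it serves as the exact reference against
#' which the samplers are validated.
#'
#' @param n Monomer count, at most 5.
#' @param p A [model_params()] object.
#' @param log_h Optional function taking an [aggregation_graph()] and
#'   returning the log reference measure; defaults to the counting measure
#'   (identically 0).
#' @return An object of class `graph_distribution`: list with `n`, `support`
#'   (list of [aggregation_graph()]s), `codes` (dyad bitmask per microstate),
#'   `probs` (summing to 1) and `energies`.
#' @export
brute_force_distribution <- function(n, p, log_h = NULL) {
  n <- as.integer(n)
  stopifnot(inherits(p, "model_params"))
  if (n < 1L) stop("n must be >= 1")
  if (n > 5L)
    stop("brute-force enumeration is limited to n <= 5 (2^choose(n,2) microstates)")
  dyads <- all_dyads(n)
  ndyad <- nrow(dyads)
  nstates <- 2L^ndyad
  coef <- hamiltonian_coefficients(p)
  beta <- beta_of(p)
  support <- vector("list", nstates)
  energies <- numeric(nstates)
  logw <- numeric(nstates)
  for (code in seq_len(nstates) - 1L) {
    on <- bitwAnd(code, bitwShiftL(1L, seq_len(ndyad) - 1L)) != 0L
    g <- aggregation_graph(n, dyads[on, , drop = FALSE])
    support[[code + 1L]] <- g
    energies[code + 1L] <- sum(coef * sufficient_stats(g))
    logw[code + 1L] <- -beta * energies[code + 1L] +
      if (is.null(log_h)) 0 else log_h(g)
  }
  logw <- logw - max(logw)
  probs <- exp(logw) / sum(exp(logw))
  structure(list(n = n, support = support, codes = seq_len(nstates) - 1L,
                 probs = probs, energies = energies),
            class = "graph_distribution")
}

#' @export
print.graph_distribution <- function(x, ...) {
  cat(sprintf("<graph_distribution> n = %d, %d microstates\n",
              x$n, length(x$probs)))
  invisible(x)
}

#' Graph code (dyad bitmask)
#'
#' Encodes a small graph as an integer whose bit `k` records the presence of
#' the `k`-th dyad in canonical order. Used to compare sampler output with
#' [brute_force_distribution()] microstate by microstate.
#'
#' @param g An [aggregation_graph()] with `choose(n,2) <= 31`.
#' @return Integer code.
#' @export
graph_code <- function(g) {
  stopifnot_graph(g)
  ndyad <- choose(g$n, 2L)
  if (ndyad > 31) stop("graph codes require choose(n,2) <= 31")
  dyads <- all_dyads(g$n)
  key <- paste(dyads[, 1L], dyads[, 2L])
  on <- key %in% paste(g$edges[, 1L], g$edges[, 2L])
  sum(bitwShiftL(1L, which(on) - 1L))
}

code_to_graph <- function(n, code) {
  dyads <- all_dyads(n)
  on <- bitwAnd(code, bitwShiftL(1L, seq_len(nrow(dyads)) - 1L)) != 0L
  aggregation_graph(n, dyads[on, , drop = FALSE])
}

#' Metropolis-Hastings sampling of the equilibrium distribution
#'
#' Samples aggregation graphs from the Boltzmann (ERGM) distribution by
#' Metropolis-Hastings over uniformly proposed single-bond toggles, with
#' acceptance probability `min(1, exp(-beta * dH))` computed from change
#' statistics. The chain starts from the empty graph.
#'
#' @param n Monomer count.
#' @param p A [model_params()] object.
#' @param steps Number of MH steps (>= 1).
#' @param seed Integer seed; identical seeds give identical chains.
#' @param thin Record every `thin`-th post-burn-in state.
#' @param burnin Steps discarded before recording; defaults to 10% of
#'   `steps`.
#' @param return `"graphs"` for a list of [aggregation_graph()]s,
#'   `"codes"` for an integer vector of dyad bitmasks (small `n` only;
#'   cheap enough to record every step of long chains).
#' @return List with elements `samples` (list of graphs or integer codes),
#'   `final` (last state) and `acceptance_rate`.
#' @export
mcmc_sample <- function(n, p, steps, seed, thin = 1L,
                        burnin = floor(steps / 10),
                        return = c("graphs", "codes")) {
  n <- as.integer(n)
  stopifnot(inherits(p, "model_params"))
  if (steps < 1) stop("steps must be >= 1")
  return <- match.arg(return)
  set.seed(as.integer(seed))
  record <- if (return == "codes") 1L else 2L
  res <- cpp_mcmc(n, hamiltonian_coefficients(p), beta_of(p),
                  as.numeric(steps), as.numeric(burnin), as.numeric(thin),
                  record)
  samples <- if (return == "codes") {
    res$codes
  } else {
    lapply(res$graphs, function(em) aggregation_graph(n, em + 1L))
  }
  list(samples = samples,
       final = aggregation_graph(n, res$final + 1L),
       acceptance_rate = res$accepted / steps)
}

#' Total-variation distance between two distributions on graph codes
#'
#' @param probs Named or code-indexed reference probabilities (from
#'   [brute_force_distribution()]).
#' @param codes Integer codes of sampled states.
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance_codes <- function(probs, codes) {
  emp <- tabulate(codes + 1L, nbins = length(probs)) / length(codes)
  sum(abs(emp - probs)) / 2
}
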