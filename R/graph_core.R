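#' @useDynLib fibrilnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

STAT_NAMES <- c("e", "2s", "NSP1", "NSP2", "ESP0", "ESP1", "C5", "C6", "C7")

#' Aggregation graph
#'
#' An aggregation graph is the coarse-grained state of an aggregating protein
#' system: each vertex is a protein monomer and each edge a non-covalent
#' inter-monomer contact. The graph is simple and undirected; vertices are
#' labelled `1..n`.
#'
#' @param n Number of monomers (vertices), a positive integer.
#' @param edges Two-column integer matrix (or `NULL` for the empty graph) of
#'   vertex pairs in `1..n`. Self-loops are rejected; duplicate and reversed
#'   pairs are collapsed.
#' @return An object of class `aggregation_graph` with fields `n` and `edges`
#'   (a canonically ordered two-column matrix).
#' @examples
#' g <- aggregation_graph(3, rbind(c(1, 2), c(2, 3)))
#' sufficient_stats(g)
#' @export
aggregation_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n must be a positive integer")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
    if (anyNA(edges) || any(edges < 1L) || any(edges > n))
      stop("edge endpoints must lie in 1..n")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    edges <- canonical_edges(edges)
  }
  structure(list(n = n, edges = edges), class = "aggregation_graph")
}

canonical_edges <- function(edges) {
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  m <- unique(cbind(u, v))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' @export
print.aggregation_graph <- function(x, ...) {
  cat(sprintf("<aggregation_graph> %d monomers, %d bonds\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' @export
format.aggregation_graph <- function(x, ...) {
  sprintf("aggregation_graph(n = %d, edges = %d)", x$n, nrow(x$edges))
}

is_aggregation_graph <- function(x) inherits(x, "aggregation_graph")

stopifnot_graph <- function(g) {
  if (!is_aggregation_graph(g)) stop("expected an aggregation_graph")
  invisible(g)
}

#' Toggle a bond
#'
#' Flips the presence of edge \{u, v\}: absent bonds are formed, present bonds
#' broken. This is the elementary kinetic move (a single Hamming step).
#'
#' @param g An [aggregation_graph()].
#' @param u,v Distinct vertex labels in `1..n`.
#' @return The toggled graph.
#' @export
toggle_edge <- function(g, u, v) {
  stopifnot_graph(g)
  u <- as.integer(u); v <- as.integer(v)
  check_dyad(g, u, v)
  key <- paste(pmin(u, v), pmax(u, v))
  keys <- paste(g$edges[, 1L], g$edges[, 2L])
  if (key %in% keys) {
    g$edges <- g$edges[keys != key, , drop = FALSE]
  } else {
    g$edges <- canonical_edges(rbind(g$edges, c(u, v)))
  }
  g
}

has_edge <- function(g, u, v) {
  any(g$edges[, 1L] == min(u, v) & g$edges[, 2L] == max(u, v))
}

check_dyad <- function(g, u, v) {
  if (length(u) != 1L || length(v) != 1L || is.na(u) || is.na(v))
    stop("u and v must be single vertex labels")
  if (u == v) stop("u and v must be distinct (no self-loops)")
  if (u < 1L || v < 1L || u > g$n || v > g$n)
    stop("vertex labels must lie in 1..n")
  invisible(NULL)
}

#' Convert to an igraph object
#'
#' @param g An [aggregation_graph()].
#' @return An undirected [igraph::graph] on the same vertex set.
#' @export
as_igraph <- function(g) {
  stopifnot_graph(g)
  igraph::graph_from_data_frame(
    data.frame(from = g$edges[, 1L], to = g$edges[, 2L]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n)))
}

zero_based <- function(edges) {
  matrix(as.integer(edges) - 1L, ncol = 2L)
}

#' Sufficient statistics of the network Hamiltonian
#'
#' Computes the nine bonding-motif counts entering the network Hamiltonian:
#' edges (`e`), two-stars (`2s`), null shared-partner counts (`NSP1`, `NSP2`:
#' non-adjacent monomer pairs with exactly one or two common bonding
#' partners), edgewise shared-partner counts (`ESP0`, `ESP1`: bonded pairs
#' with zero or one common partner) and the numbers of simple cycles of
#' length five, six and seven (`C5`, `C6`, `C7`), each cycle subgraph counted
#' once.
#'
#' @param g An [aggregation_graph()].
#' @return Named numeric vector of length 9.
#' @export
sufficient_stats <- function(g) {
  stopifnot_graph(g)
  out <- cpp_sufficient_stats(g$n, zero_based(g$edges))
  names(out) <- STAT_NAMES
  out
}

#' Change statistics for a single-bond toggle
#'
#' Returns `t(g %+-% {u,v}) - t(g)`, the signed difference in the nine
#' sufficient statistics caused by toggling the bond \{u, v\}. This is the
#' standard ERGM change-statistic device: transition rates and acceptance
#' probabilities depend on the Hamiltonian only through this difference, so
#' it is computed locally (cycle terms by a bounded path search between `u`
#' and `v`) rather than from two full graph censuses.
#'
#' @inheritParams toggle_edge
#' @return Named numeric vector of length 9.
#' @export
change_stats <- function(g, u, v) {
  stopifnot_graph(g)
  u <- as.integer(u); v <- as.integer(v)
  check_dyad(g, u, v)
  out <- cpp_change_stats(g$n, zero_based(g$edges), u - 1L, v - 1L)
  names(out) <- STAT_NAMES
  out
}

#' Model parameters
#'
#' Bundles the nine Hamiltonian coefficients phi with the thermodynamic and
#' kinetic constants. Reduced units `k_B = 1`, `T = 1` are the default, and
#' time is measured in units of inverse collision rate (`A = 1`).
#'
#' @param phi Named numeric vector of the nine motif coefficients; names as
#'   in [sufficient_stats()] (`e`, `2s`, `NSP1`, `NSP2`, `ESP0`, `ESP1`,
#'   `C5`, `C6`, `C7`). Energy units.
#' @param T Temperature (> 0).
#' @param k_B Boltzmann constant; 1 in reduced units.
#' @param A Collision frequency in events per unit time (> 0); sets the
#'   kinetic time scale.
#' @param ref_measure Reference measure for the entropic weight `h(g)`;
#'   only `"counting"` (log h = 0) is currently supported.
#' @return An object of class `model_params`.
#' @details The effective edge coefficient of the Hamiltonian is
#'   `phi["e"] + k_B * T`; the equilibrium distribution is proportional to
#'   `exp(-H(g) / (k_B T))`. The natural-parameter vector on that scale is
#'   available via [theta()].
#' @export
model_params <- function(phi, T = 1, k_B = 1, A = 1, ref_measure = "counting") {
  phi <- unlist(phi)
  if (is.null(names(phi)) && length(phi) == 9L) names(phi) <- STAT_NAMES
  if (!setequal(names(phi), STAT_NAMES))
    stop("phi must be a named vector with components: ",
         paste(STAT_NAMES, collapse = ", "))
  phi <- as.numeric(phi[STAT_NAMES])
  names(phi) <- STAT_NAMES
  if (anyNA(phi)) stop("phi values must be numeric")
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  if (!is.numeric(k_B) || k_B <= 0) stop("k_B must be > 0")
  if (!is.numeric(A) || A <= 0) stop("A must be > 0")
  ref_measure <- match.arg(ref_measure, "counting")
  structure(list(phi = phi, T = as.numeric(T), k_B = as.numeric(k_B),
                 A = as.numeric(A), ref_measure = ref_measure),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  phi:", paste(sprintf("%s=%g", names(x$phi), x$phi), collapse = " "), "\n")
  cat(sprintf("  T = %g, k_B = %g, A = %g, reference measure = %s\n",
              x$T, x$k_B, x$A, x$ref_measure))
  invisible(x)
}

#' Hamiltonian coefficient vector
#'
#' The vector multiplying the sufficient statistics in the energy: the edge
#' component is `phi_e + k_B T`, all others are the bare phi values.
#'
#' @param p A [model_params()] object.
#' @return Named numeric vector of length 9.
#' @export
hamiltonian_coefficients <- function(p) {
  stopifnot(inherits(p, "model_params"))
  coef <- p$phi
  coef["e"] <- coef["e"] + p$k_B * p$T
  coef
}

#' Natural (ERGM) parameters
#'
#' theta is the natural-parameter vector of the equilibrium graph
#' distribution, `exp(theta . t(g))` being proportional to `exp(-beta H(g))`:
#' each Hamiltonian coefficient divided by `-k_B T` (so the edge entry
#' carries the `+ k_B T` offset of the edge coefficient).
#'
#' @param p A [model_params()] object.
#' @return Named numeric vector of length 9.
#' @export
theta <- function(p) {
  -hamiltonian_coefficients(p) / (p$k_B * p$T)
}

beta_of <- function(p) 1 / (p$k_B * p$T)

#' Network Hamiltonian
#'
#' Evaluates the coarse-grained energy of an aggregation state: the dot
#' product of the Hamiltonian coefficient vector (edge term
#' `phi_e + k_B T`, then the eight remaining phi) with the nine sufficient
#' statistics.
#'
#' @param g An [aggregation_graph()].
#' @param p A [model_params()] object.
#' @return Scalar energy.
#' @export
hamiltonian <- function(g, p) {
  stopifnot(inherits(p, "model_params"))
  sum(hamiltonian_coefficients(p) * sufficient_stats(g))
}
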