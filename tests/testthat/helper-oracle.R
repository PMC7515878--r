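# Independent brute-force oracle for the nine motif statistics, written
# against the definitions only (no shared code with the package kernels).

oracle_adj <- function(g) {
  A <- matrix(FALSE, g$n, g$n)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      A[g$edges[i, 1], g$edges[i, 2]] <- TRUE
      A[g$edges[i, 2], g$edges[i, 1]] <- TRUE
    }
  }
  A
}

# count of simple cycles with exactly k vertices, one per cycle subgraph:
# canonical traversals start at the smallest vertex and fix a direction
oracle_cycles <- function(A, k) {
  n <- nrow(A)
  if (n < k) return(0L)
  total <- 0L
  subsets <- utils::combn(n, k)
  for (ci in seq_len(ncol(subsets))) {
    vs <- subsets[, ci]
    first <- vs[1]
    rest <- vs[-1]
    perms <- all_perms(rest)
    for (pi in seq_len(nrow(perms))) {
      ord <- c(first, perms[pi, ])
      if (ord[2] > ord[k]) next   # fix direction: second < last
      ok <- TRUE
      for (j in seq_len(k)) {
        a <- ord[j]; b <- ord[if (j == k) 1 else j + 1]
        if (!A[a, b]) { ok <- FALSE; break }
      }
      if (ok) total <- total + 1L
    }
  }
  total
}

all_perms <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], all_perms(x[-i])))
  out
}

oracle_stats <- function(g) {
  A <- oracle_adj(g)
  n <- g$n
  e <- nrow(g$edges)
  two_star <- 0L
  if (n >= 3) {
    trip <- utils::combn(n, 3)
    for (ci in seq_len(ncol(trip))) {
      vs <- trip[, ci]
      # each of the three members as potential centre of a 2-path
      for (c0 in 1:3) {
        o <- vs[-c0]
        if (A[vs[c0], o[1]] && A[vs[c0], o[2]]) two_star <- two_star + 1L
      }
    }
  }
  nsp1 <- nsp2 <- esp0 <- esp1 <- 0L
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        cn <- 0L
        for (w in seq_len(n))
          if (w != a && w != b && A[a, w] && A[b, w]) cn <- cn + 1L
        if (A[a, b]) {
          if (cn == 0L) esp0 <- esp0 + 1L
          if (cn == 1L) esp1 <- esp1 + 1L
        } else {
          if (cn == 1L) nsp1 <- nsp1 + 1L
          if (cn == 2L) nsp2 <- nsp2 + 1L
        }
      }
    }
  }
  c(e = e, `2s` = two_star, NSP1 = nsp1, NSP2 = nsp2,
    ESP0 = esp0, ESP1 = esp1,
    C5 = oracle_cycles(A, 5), C6 = oracle_cycles(A, 6),
    C7 = oracle_cycles(A, 7))
}

random_graph <- function(n, p_edge = 0.4) {
  dy <- all_dyads(n)
  on <- stats::runif(nrow(dy)) < p_edge
  aggregation_graph(n, dy[on, , drop = FALSE])
}

# every labelled graph on n vertices (n small)
all_graphs <- function(n) {
  dy <- all_dyads(n)
  nd <- nrow(dy)
  lapply(seq_len(2^nd) - 1L, function(code) {
    on <- bitwAnd(code, bitwShiftL(1L, seq_len(nd) - 1L)) != 0L
    aggregation_graph(n, dy[on, , drop = FALSE])
  })
}

default_params <- function(phi = c(e = -2, `2s` = 0.7, NSP1 = -0.4,
                                   NSP2 = 0.3, ESP0 = -0.5, ESP1 = 1.1,
                                   C5 = 0.9, C6 = -0.2, C7 = 0.6), ...) {
  model_params(phi, ...)
}

dendrite_params <- function() {
  load_params(system.file("extdata",
                          "params_1ribbon_dendrite_consolidation_placeholder.yaml",
                          package = "fibrilnet"))
}
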