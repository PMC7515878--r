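ROLE_LEVELS <- c("end", "center", "defect", "free")

#' Monomer roles relative to fibrillar structure
#'
#' Assigns each monomer one of four roles: `end` (member of an induced
#' fibrillar component sitting in a terminal subunit of its segment),
#' `center` (any other fibrillar-component member), `defect` (a
#' non-fibrillar monomer whose aggregate contains fibrillar structure) or
#' `free` (a monomer in an aggregate with no fibrillar content, including
#' isolated monomers).
#'
#' @param g An [aggregation_graph()].
#' @param template Template object or class name.
#' @param components Optionally a precomputed
#'   [induced_fibrillar_components()] result for `g`.
#' @return Character vector of length `n` with the role of each monomer.
#' @export
vertex_roles <- function(g, template, components = NULL) {
  stopifnot_graph(g)
  t <- get_template(template)
  fc <- if (is.null(components)) induced_fibrillar_components(g, t) else components
  roles <- rep("free", g$n)
  for (cp in fc$components) roles[cp$vertices] <- cp$role
  comp <- igraph::components(as_igraph(g))
  fibv <- fibrillar_vertices(fc)
  fib_comps <- unique(comp$membership[fibv])
  nonfib <- roles == "free"
  roles[nonfib & comp$membership %in% fib_comps] <- "defect"
  roles
}

#' Census of non-fibril-internal bonding motifs
#'
#' Classifies every bond that is not internal to a single induced
#' fibrillar component by the roles of its endpoints (see
#' [vertex_roles()]): the closed set of unordered role pairs over
#' \{end, center, defect\} plus the free-monomer attachment categories.
#' A defect-free ideal fibril therefore has an all-zero census.
#'
#' @inheritParams vertex_roles
#' @return One-row data frame with counts `end_end`, `end_center`,
#'   `center_center`, `defect_end`, `defect_center`, `defect_defect`,
#'   `free_end`, `free_center`, `free_defect`, `free_free`, plus
#'   `n_external` (their sum).
#' @export
motif_census <- function(g, template, components = NULL) {
  stopifnot_graph(g)
  t <- get_template(template)
  fc <- if (is.null(components)) induced_fibrillar_components(g, t) else components
  roles <- vertex_roles(g, t, components = fc)
  comp_of <- integer(g$n)                     # fibrillar component index or 0
  for (i in seq_along(fc$components))
    comp_of[fc$components[[i]]$vertices] <- i
  cats <- c("end_end", "end_center", "center_center", "defect_end",
            "defect_center", "defect_defect", "free_end", "free_center",
            "free_defect", "free_free")
  counts <- stats::setNames(integer(length(cats)), cats)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      u <- g$edges[i, 1L]; v <- g$edges[i, 2L]
      if (comp_of[u] != 0L && comp_of[u] == comp_of[v]) next  # fibril-internal
      rr <- sort(factor(c(roles[u], roles[v]), levels = ROLE_LEVELS))
      key <- switch(paste(as.character(rr), collapse = "_"),
                    "end_end" = "end_end",
                    "end_center" = "end_center",
                    "center_center" = "center_center",
                    "end_defect" = "defect_end",
                    "center_defect" = "defect_center",
                    "defect_defect" = "defect_defect",
                    "end_free" = "free_end",
                    "center_free" = "free_center",
                    "defect_free" = "free_defect",
                    "free_free" = "free_free")
      counts[key] <- counts[key] + 1L
    }
  }
  out <- as.data.frame(as.list(counts))
  out$n_external <- sum(counts)
  out
}

#' Defect breakage events along a trajectory
#'
#' A defect breakage is a bond deletion that (1) is incident to at least
#' one defect monomer (role evaluated in the state just before the
#' deletion) and (2) disconnects the aggregate it belonged to (the
#' connected component count increases). Events are aggregated into fixed
#' event-count bins.
#'
#' @param traj A `fibril_trajectory`.
#' @param template Template object or class name.
#' @param bin Events per reporting bin (default 1000).
#' @return Data frame with one row per bin: `bin_start_event`,
#'   `bin_end_event`, `t_start`, `t_end`, `defect_breakage`.
#' @export
detect_breakage_events <- function(traj, template, bin = 1000L) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  t <- get_template(template)
  bin <- max(1L, as.integer(bin))
  nev <- nrow(traj$events)
  is_break <- logical(nev)
  g <- aggregation_graph(traj$n)
  for (i in seq_len(nev)) {
    u <- traj$events$u[i]; v <- traj$events$v[i]
    if (traj$events$action[i] == "del") {
      g2 <- toggle_edge(g, u, v)
      # deletion disconnects iff the bond was a bridge
      if (!igraph_connected_pair(g2, u, v)) {
        roles <- vertex_roles(g, t)
        if (roles[u] == "defect" || roles[v] == "defect")
          is_break[i] <- TRUE
      }
      g <- g2
    } else {
      g <- toggle_edge(g, u, v)
    }
  }
  if (nev == 0L)
    return(data.frame(bin_start_event = integer(0), bin_end_event = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      defect_breakage = integer(0)))
  starts <- seq(1L, nev, by = bin)
  out <- lapply(starts, function(s0) {
    s1 <- min(s0 + bin - 1L, nev)
    idx <- s0:s1
    data.frame(bin_start_event = s0, bin_end_event = s1,
               t_start = traj$events$time[s0], t_end = traj$events$time[s1],
               defect_breakage = sum(is_break[idx]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# is there still a path between u and v?
igraph_connected_pair <- function(g, u, v) {
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  comp$membership[u] == comp$membership[v]
}
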