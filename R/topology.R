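## Fibril topology templates and induced fibrillar component extraction.
##
## The five topology classes covering all amyloid fibril structures so far
## resolved in the PDB are expressed as declarative periodic templates: an
## edge pattern within the minimal repeating subunit, between consecutive
## subunits, and (for the "1,2" patterns) between next-nearest subunits.

.fibrilnet_cache <- new.env(parent = emptyenv())

#' Fibril topology template
#'
#' A declarative description of a periodic fibril topology: a minimal
#' repeating subunit of `subunit_size` monomers, bonded internally by
#' `intra_edges`, to the next subunit by `inter_edges`, and optionally to
#' the subunit after next by `next_inter_edges`. Position indices are
#' `1..subunit_size`; an inter-subunit pair `(i, j)` bonds position `i` of
#' subunit `k` to position `j` of subunit `k + 1` (or `k + 2`).
#'
#' @param class_id Label for the topology class.
#' @param subunit_size Monomers per minimal repeating subunit (>= 1).
#' @param intra_edges,inter_edges,next_inter_edges Two-column matrices (or
#'   `NULL`) of position pairs as described above.
#' @return An object of class `fibril_template`.
#' @seealso [fibril_classes()] for the five shipped templates.
#' @export
fibril_template <- function(class_id, subunit_size, intra_edges = NULL,
                            inter_edges = NULL, next_inter_edges = NULL) {
  s <- as.integer(subunit_size)
  if (s < 1L) stop("subunit_size must be >= 1")
  norm <- function(m, lab) {
    if (is.null(m) || NROW(m) == 0L) return(matrix(integer(0), ncol = 2L))
    m <- matrix(as.integer(as.matrix(m)), ncol = 2L)
    if (anyNA(m) || any(m < 1L) || any(m > s))
      stop(lab, " positions must lie in 1..subunit_size")
    m
  }
  intra <- norm(intra_edges, "intra_edges")
  if (any(intra[, 1L] == intra[, 2L]))
    stop("intra_edges may not contain self-pairs")
  tmpl <- structure(list(class_id = as.character(class_id),
                         subunit_size = s,
                         intra_edges = intra,
                         inter_edges = norm(inter_edges, "inter_edges"),
                         next_inter_edges = norm(next_inter_edges,
                                                 "next_inter_edges")),
                    class = "fibril_template")
  if (nrow(tmpl$inter_edges) == 0L && nrow(tmpl$next_inter_edges) == 0L)
    stop("a fibril template needs at least one inter-subunit bond")
  tmpl
}

#' @export
print.fibril_template <- function(x, ...) {
  cat(sprintf("<fibril_template> %s (subunit size %d; %d intra / %d inter / %d next-nearest bonds)\n",
              x$class_id, x$subunit_size, nrow(x$intra_edges),
              nrow(x$inter_edges), nrow(x$next_inter_edges)))
  invisible(x)
}

#' The five PDB fibril topology classes
#'
#' Returns the shipped templates: `1-ribbon` (a path of monomers),
#' `2-ribbon` (a ladder: a rung within each subunit, rails between),
#' `1,2 2-ribbon` (ladder plus bonds to the next-nearest subunit on both
#' strands), `double 1,2 2-ribbon` (two laterally bonded 1,2 2-ribbons) and
#' `3-prism` (stacked bonded triangles). The within/between-subunit bond
#' patterns are data, not code, so they can be amended without touching the
#' component-extraction machinery.
#'
#' @return Named list of [fibril_template()] objects.
#' @export
fibril_classes <- function() {
  list(
    "1-ribbon" = fibril_template("1-ribbon", 1L,
                                 inter_edges = cbind(1L, 1L)),
    "2-ribbon" = fibril_template("2-ribbon", 2L,
                                 intra_edges = cbind(1L, 2L),
                                 inter_edges = rbind(c(1L, 1L), c(2L, 2L))),
    "1,2 2-ribbon" = fibril_template("1,2 2-ribbon", 2L,
                                     intra_edges = cbind(1L, 2L),
                                     inter_edges = rbind(c(1L, 1L), c(2L, 2L)),
                                     next_inter_edges = rbind(c(1L, 1L), c(2L, 2L))),
    "double 1,2 2-ribbon" = fibril_template(
      "double 1,2 2-ribbon", 4L,
      intra_edges = rbind(c(1L, 2L), c(3L, 4L), c(2L, 3L)),
      inter_edges = rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(4L, 4L)),
      next_inter_edges = rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(4L, 4L))),
    "3-prism" = fibril_template("3-prism", 3L,
                                intra_edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                                inter_edges = rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L)))
  )
}

#' Resolve a template argument
#'
#' Accepts either a [fibril_template()] or the name of one of the five
#' shipped classes.
#'
#' @param template Template object or class name.
#' @return A `fibril_template`.
#' @export
get_template <- function(template) {
  if (inherits(template, "fibril_template")) return(template)
  cls <- fibril_classes()
  if (is.character(template) && template %in% names(cls))
    return(cls[[template]])
  stop("unknown fibril class: ", template, "; known classes: ",
       paste(names(cls), collapse = ", "))
}

template_key <- function(t) {
  paste(t$class_id, t$subunit_size,
        paste(t$intra_edges, collapse = ","),
        paste(t$inter_edges, collapse = ","),
        paste(t$next_inter_edges, collapse = ","), sep = "|")
}

#' Ideal fibril graph
#'
#' Builds the defect-free fibril of `L` repeating subunits for a topology
#' class. Vertices are labelled subunit-major: subunit `k` (1-based)
#' occupies labels `(k-1) * subunit_size + (1..subunit_size)`.
#'
#' @param template Template object or class name (see [get_template()]).
#' @param L Number of subunits (>= 1).
#' @return An [aggregation_graph()] with `subunit_size * L` vertices.
#' @examples
#' ideal_fibril("3-prism", 2)  # the triangular prism: 6 vertices, 9 edges
#' @export
ideal_fibril <- function(template, L) {
  t <- get_template(template)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  s <- t$subunit_size
  base <- (seq_len(L) - 1L) * s
  edges <- list()
  if (nrow(t$intra_edges) > 0L)
    edges <- c(edges, lapply(base, function(b) t$intra_edges + b))
  if (L >= 2L && nrow(t$inter_edges) > 0L)
    edges <- c(edges, lapply(base[-L], function(b)
      cbind(t$inter_edges[, 1L] + b, t$inter_edges[, 2L] + b + s)))
  if (L >= 3L && nrow(t$next_inter_edges) > 0L)
    edges <- c(edges, lapply(base[seq_len(L - 2L)], function(b)
      cbind(t$next_inter_edges[, 1L] + b, t$next_inter_edges[, 2L] + b + 2L * s)))
  em <- if (length(edges)) do.call(rbind, edges) else NULL
  aggregation_graph(s * L, em)
}

#' Nucleation size threshold
#'
#' The smallest monomer count for a subgraph to count as an induced
#' fibrillar component: two full minimal repeating subunits
#' (`2 * subunit_size`). For single-monomer subunits (the 1-ribbon) the
#' two-subunit rule would declare every bonded pair fibrillar, so the
#' threshold is raised to four monomers.
#'
#' @param template Template object or class name.
#' @return Integer monomer count.
#' @examples
#' nucleation_threshold("3-prism")  # 6
#' nucleation_threshold("1-ribbon") # 4
#' @export
nucleation_threshold <- function(template) {
  t <- get_template(template)
  if (t$subunit_size == 1L) 4L else 2L * t$subunit_size
}

## ---- local fibrillarity -------------------------------------------------

adjacency_matrix_of <- function(g) {
  A <- matrix(FALSE, g$n, g$n)
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  A
}

neighbour_list_of <- function(g) {
  nbr <- rep(list(integer(0)), g$n)
  if (nrow(g$edges)) {
    inc <- c(g$edges[, 1L], g$edges[, 2L])
    oth <- c(g$edges[, 2L], g$edges[, 1L])
    sp <- split(oth, inc)
    nbr[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  nbr
}

# Reference data for the strict neighbourhood test: a 7-subunit ideal fibril
# together with each reference vertex's neighbour set and local adjacency.
template_reference <- function(t) {
  key <- paste0("ref|", template_key(t))
  if (!is.null(.fibrilnet_cache[[key]])) return(.fibrilnet_cache[[key]])
  Lref <- max(7L, as.integer(ceiling(nucleation_threshold(t) / t$subunit_size)) + 4L)
  ref <- ideal_fibril(t, Lref)
  A <- adjacency_matrix_of(ref)
  nbr <- neighbour_list_of(ref)
  out <- list(graph = ref, A = A, nbr = nbr, deg = lengths(nbr),
              maxdeg = max(lengths(nbr)),
              is_path = t$subunit_size == 1L &&
                nrow(t$next_inter_edges) == 0L)
  .fibrilnet_cache[[key]] <- out
  out
}

# Anchored induced embedding: can the neighbours `nb` of a vertex (with
# graph adjacency matrix Ag) be injectively mapped into the neighbours of
# some reference position r, preserving both adjacency and non-adjacency
# among the mapped neighbours?
local_embeds <- function(Ag, nb, ref) {
  dv <- length(nb)
  if (dv == 0L || dv > ref$maxdeg) return(FALSE)
  if (ref$is_path) {
    # fast path for single-strand ribbons: at most two mutually non-bonded
    # neighbours
    if (dv > 2L) return(FALSE)
    if (dv == 2L && Ag[nb[1L], nb[2L]]) return(FALSE)
    return(TRUE)
  }
  sub <- Ag[nb, nb, drop = FALSE]
  for (r in seq_along(ref$deg)) {
    if (ref$deg[r] < dv) next
    cand <- ref$nbr[[r]]
    if (match_neighbours(sub, cand, ref$A)) return(TRUE)
  }
  FALSE
}

# Backtracking search for an injective map of neighbours (rows of `sub`)
# onto reference vertices `cand`, preserving the induced adjacency pattern.
match_neighbours <- function(sub, cand, Aref) {
  dv <- nrow(sub)
  assign_next <- function(i, used, img) {
    if (i > dv) return(TRUE)
    for (cidx in seq_along(cand)) {
      if (used[cidx]) next
      rc <- cand[cidx]
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          if (sub[i, j] != Aref[rc, img[j]]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      used[cidx] <- TRUE
      img[i] <- rc
      if (assign_next(i + 1L, used, img)) return(TRUE)
      used[cidx] <- FALSE
    }
    FALSE
  }
  assign_next(1L, logical(length(cand)), integer(dv))
}

#' Local fibrillarity test
#'
#' A monomer is locally fibrillar when it shares bonds with its immediate
#' neighbours in accordance with the fibrillar topology: its closed
#' 1-neighbourhood embeds (induced, anchored at the monomer) into the
#' neighbourhood of some position — interior or terminal — of the ideal
#' fibril. Extra bonds beyond the template pattern disqualify a monomer
#' (e.g. a monomer with five partners can never be part of a 1-ribbon,
#' whose positions have at most two); free monomers are never fibrillar.
#'
#' @param g An [aggregation_graph()].
#' @param v Vertex label.
#' @param template Template object or class name.
#' @return Logical.
#' @export
is_locally_fibrillar <- function(g, v, template) {
  stopifnot_graph(g)
  v <- as.integer(v)
  if (v < 1L || v > g$n) stop("v must lie in 1..n")
  t <- get_template(template)
  ref <- template_reference(t)
  Ag <- adjacency_matrix_of(g)
  nbr <- neighbour_list_of(g)
  local_embeds(Ag, nbr[[v]], ref)
}

# Strict locally-fibrillar vertex set.
strict_fibrillar_set <- function(g, t) {
  ref <- template_reference(t)
  Ag <- adjacency_matrix_of(g)
  nbr <- neighbour_list_of(g)
  deg <- lengths(nbr)
  strict <- logical(g$n)
  for (v in which(deg >= 1L)) strict[v] <- local_embeds(Ag, nbr[[v]], ref)
  strict
}

## ---- segment isomorphism ------------------------------------------------

# Induced segment of the infinite ideal fibril: positions
# offset+1 .. offset+m of a sufficiently long ideal fibril.
segment_graph <- function(t, m, offset) {
  key <- sprintf("seg|%s|%d|%d", template_key(t), m, offset)
  if (!is.null(.fibrilnet_cache[[key]])) return(.fibrilnet_cache[[key]])
  s <- t$subunit_size
  L <- as.integer(ceiling((offset + m) / s)) + 1L
  big <- ideal_fibril(t, L)
  vs <- offset + seq_len(m)
  keep <- big$edges[big$edges[, 1L] %in% vs & big$edges[, 2L] %in% vs, ,
                    drop = FALSE]
  em <- cbind(match(keep[, 1L], vs), match(keep[, 2L], vs))
  seg <- aggregation_graph(m, em)
  ig <- as_igraph(seg)
  out <- list(graph = seg, igraph = ig, positions = vs,
              degseq = sort(igraph::degree(ig)), ecount = nrow(em))
  .fibrilnet_cache[[key]] <- out
  out
}

# Try to match a candidate component (igraph, with original labels as
# vertex names) against all offsets of the template segment of equal size.
# Returns NULL or list(offset, positions): positions[i] = ideal-fibril
# position of the component's i-th vertex.
segment_match <- function(comp_ig, t) {
  m <- igraph::vcount(comp_ig)
  ec <- igraph::ecount(comp_ig)
  dseq <- sort(igraph::degree(comp_ig))
  for (offset in 0:(t$subunit_size - 1L)) {
    seg <- segment_graph(t, m, offset)
    if (seg$ecount != ec || any(seg$degseq != dseq)) next
    maps <- igraph::isomorphisms(comp_ig, seg$igraph)
    if (length(maps) > 0L) {
      mp <- as.integer(maps[[1L]])
      return(list(offset = offset, positions = seg$positions[mp]))
    }
  }
  NULL
}

# Recursively extract template-consistent segments from a connected set of
# fibrillar vertices: accept whole components isomorphic to an ideal
# segment; otherwise split deterministically at the first bridge edge (a
# spurious single bond joining two fibrils is a bridge, while every bond of
# a multi-stranded fibril is cycle-protected) and recurse. Bridgeless
# non-matching structures (e.g. closed rings of locally fibrillar
# monomers) are rejected.
extract_segments <- function(sub_ig, t, threshold) {
  m <- igraph::vcount(sub_ig)
  if (m < threshold) return(list())
  mt <- segment_match(sub_ig, t)
  if (!is.null(mt)) {
    labels <- as.integer(igraph::V(sub_ig)$name)
    s <- t$subunit_size
    sub_of <- (mt$positions - 1L) %/% s
    terminal <- sub_of %in% range(sub_of)
    ord <- order(labels)
    return(list(list(vertices = labels[ord],
                     size = as.integer(m),
                     positions = mt$positions[ord],
                     role = ifelse(terminal, "end", "center")[ord],
                     offset = mt$offset)))
  }
  if (m <= 2L) return(list())
  br <- igraph::bridges(sub_ig)
  if (length(br) == 0L) return(list())
  ends <- igraph::ends(sub_ig, br)
  lab <- matrix(as.integer(ends), ncol = 2L)
  a <- pmin(lab[, 1L], lab[, 2L]); b <- pmax(lab[, 1L], lab[, 2L])
  pick <- order(a, b)[1L]
  cut <- igraph::delete_edges(sub_ig, br[pick])
  comp <- igraph::components(cut)
  out <- list()
  for (ci in seq_len(comp$no)) {
    part <- igraph::induced_subgraph(cut, which(comp$membership == ci))
    out <- c(out, extract_segments(part, t, threshold))
  }
  out
}

#' Induced fibrillar components
#'
#' Extracts the maximal sets of monomers that are (1) in a locally
#' fibrillar conformation and (2) joined to one another by non-covalent
#' bonds, keeping only sets containing at least two minimal repeating
#' subunits (see [nucleation_threshold()]). Each returned component's
#' induced subgraph is isomorphic to a possibly end-truncated segment of
#' the ideal fibril of its class; connected fibrillar sets that are not
#' (for example two fibrils attached by a single spurious bond) are split
#' at bridge bonds into their template-consistent parts.
#'
#' @param g An [aggregation_graph()].
#' @param template Template object or class name.
#' @return Object of class `fibrillar_components`: list with `class_id`,
#'   `threshold`, `n`, and `components`, a list whose entries carry
#'   `vertices`, `size`, `positions` (ideal-fibril positions), `role`
#'   (`"end"` for terminal-subunit vertices, `"center"` otherwise) and
#'   `offset`.
#' @export
induced_fibrillar_components <- function(g, template) {
  stopifnot_graph(g)
  t <- get_template(template)
  threshold <- nucleation_threshold(t)
  ig <- as_igraph(g)
  extract_all <- function(vset) {
    comps <- list()
    if (length(vset) < threshold) return(comps)
    sub <- igraph::induced_subgraph(ig, vset)
    cc <- igraph::components(sub)
    for (ci in seq_len(cc$no)) {
      if (cc$csize[ci] < threshold) next
      part <- igraph::induced_subgraph(sub, which(cc$membership == ci))
      comps <- c(comps, extract_segments(part, t, threshold))
    }
    comps
  }
  # pass 1: strict local test, component extraction
  strict <- strict_fibrillar_set(g, t)
  comps <- extract_all(which(strict))
  retained <- unlist(lapply(comps, function(cp) cp$vertices), use.names = FALSE)
  # pass 2 (rescue): a vertex outside every retained component is still
  # fibrillar if its bonds *to retained-component monomers* form a valid
  # template neighbourhood — its remaining bonds are defect bonds and do
  # not disqualify it. This keeps a fibril interior monomer fibrillar when
  # a defect attaches to it, without letting disordered aggregates (whose
  # strict pass retains nothing) count as fibrillar.
  if (length(retained)) {
    ref <- template_reference(t)
    Ag <- adjacency_matrix_of(g)
    nbr <- neighbour_list_of(g)
    in_ret <- logical(g$n)
    in_ret[retained] <- TRUE
    rescued <- integer(0)
    for (v in which(!in_ret & lengths(nbr) >= 1L)) {
      nb <- nbr[[v]][in_ret[nbr[[v]]]]
      if (length(nb) >= 1L && local_embeds(Ag, nb, ref))
        rescued <- c(rescued, v)
    }
    if (length(rescued))
      comps <- extract_all(sort(c(retained, rescued)))
  }
  ord <- order(vapply(comps, function(cp) min(cp$vertices), integer(1)))
  structure(list(class_id = t$class_id, threshold = threshold, n = g$n,
                 components = comps[ord]),
            class = "fibrillar_components")
}

#' @export
print.fibrillar_components <- function(x, ...) {
  sizes <- component_sizes(x)
  cat(sprintf("<fibrillar_components> %s: %d component(s)%s\n", x$class_id,
              length(sizes),
              if (length(sizes)) paste0(" of sizes ",
                                        paste(sizes, collapse = ", ")) else ""))
  invisible(x)
}

#' @rdname induced_fibrillar_components
#' @param x A `fibrillar_components` object.
#' @export
component_sizes <- function(x) {
  vapply(x$components, function(cp) cp$size, integer(1))
}

#' @rdname induced_fibrillar_components
#' @export
fibrillar_vertices <- function(x) {
  sort(unlist(lapply(x$components, function(cp) cp$vertices), use.names = FALSE))
}

#' Classify a graph against the five fibril topology classes
#'
#' Tests whether the graph as a whole is a single induced fibrillar
#' component of each of the five shipped templates. If no template matches
#' the whole graph, the largest induced fibrillar component under each
#' template is compared and the class(es) achieving the largest fibrillar
#' content are reported. Ties are reported explicitly as a multi-element
#' result with a warning, never silently broken.
#'
#' @param g An [aggregation_graph()].
#' @return Character vector of matching class labels, or `"non-fibrillar"`.
#' @export
classify_topology <- function(g) {
  stopifnot_graph(g)
  cls <- fibril_classes()
  whole <- character(0)
  best_size <- integer(length(cls))
  names(best_size) <- names(cls)
  for (nm in names(cls)) {
    fc <- induced_fibrillar_components(g, cls[[nm]])
    sizes <- component_sizes(fc)
    best_size[nm] <- if (length(sizes)) max(sizes) else 0L
    if (length(sizes) == 1L && sizes == g$n) whole <- c(whole, nm)
  }
  res <- if (length(whole)) {
    whole
  } else if (all(best_size == 0L)) {
    "non-fibrillar"
  } else {
    names(best_size)[best_size == max(best_size)]
  }
  if (length(res) > 1L)
    warning("ambiguous topology: ", paste(res, collapse = " / "))
  res
}
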