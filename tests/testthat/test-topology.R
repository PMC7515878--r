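test_that("ideal fibril generators produce the expected periodic graphs", {
  # 1-ribbon is a path
  r1 <- ideal_fibril("1-ribbon", 5)
  expect_equal(r1$n, 5L)
  expect_equal(nrow(r1$edges), 4L)
  expect_equal(unname(sort(igraph::degree(as_igraph(r1)))), c(1, 1, 2, 2, 2))
  # 3-prism at L = 2 is the triangular prism
  pr <- ideal_fibril("3-prism", 2)
  expect_equal(pr$n, 6L)
  expect_equal(nrow(pr$edges), 9L)
  prism <- igraph::make_graph(c(1,2, 1,3, 2,3, 4,5, 4,6, 5,6, 1,4, 2,5, 3,6),
                              directed = FALSE)
  expect_true(igraph::isomorphic(as_igraph(pr), prism))
  # 2-ribbon edge count: L rungs + 2(L-1) rails
  for (L in c(1, 4, 9)) {
    r2 <- ideal_fibril("2-ribbon", L)
    expect_equal(r2$n, 2L * L)
    expect_equal(nrow(r2$edges), L + 2L * (L - 1L))
  }
  expect_error(ideal_fibril("1-ribbon", 0), "L must be")
  # subunit periodicity: consecutive-subunit blocks are isomorphic
  t12 <- get_template("1,2 2-ribbon")
  big <- ideal_fibril(t12, 8)
  block <- function(k) {
    vs <- ((k - 1) * 2 + 1):((k + 1) * 2)
    igraph::induced_subgraph(as_igraph(big), vs)
  }
  for (k in 3:5) expect_true(igraph::isomorphic(block(k), block(4)))
})

test_that("nucleation thresholds implement the two-subunit rule with the 1-ribbon exception", {
  expect_equal(nucleation_threshold("3-prism"), 6L)
  expect_equal(nucleation_threshold("1-ribbon"), 4L)
  expect_equal(nucleation_threshold("2-ribbon"), 4L)
  expect_equal(nucleation_threshold("1,2 2-ribbon"), 4L)
  expect_equal(nucleation_threshold("double 1,2 2-ribbon"), 8L)
})

test_that("local fibrillarity accepts template positions and rejects foreign neighbourhoods", {
  r1 <- ideal_fibril("1-ribbon", 6)
  expect_true(is_locally_fibrillar(r1, 3, "1-ribbon"))   # interior
  expect_true(is_locally_fibrillar(r1, 1, "1-ribbon"))   # terminal
  iso <- aggregation_graph(3, rbind(c(1, 2)))
  expect_false(is_locally_fibrillar(iso, 3, "1-ribbon")) # isolated monomer
  star5 <- aggregation_graph(6, cbind(1L, 2:6))
  expect_false(is_locally_fibrillar(star5, 1, "1-ribbon")) # degree 5 > path max
  tri <- aggregation_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_false(is_locally_fibrillar(tri, 1, "1-ribbon"))   # triangle is not path-like
  expect_true(is_locally_fibrillar(ideal_fibril("3-prism", 3), 4, "3-prism"))
})

test_that("induced fibrillar components recover ideal fibrils whole", {
  for (nm in names(fibril_classes())) {
    g <- ideal_fibril(nm, 10)
    fc <- induced_fibrillar_components(g, nm)
    expect_equal(component_sizes(fc), g$n)
    expect_equal(fibrillar_vertices(fc), seq_len(g$n))
  }
})

test_that("joining two fibrils end to end merges 1-ribbon components (count 2 -> 1)", {
  two <- aggregation_graph(20, rbind(ideal_fibril("1-ribbon", 10)$edges,
                                     ideal_fibril("1-ribbon", 10)$edges + 10L))
  fc2 <- induced_fibrillar_components(two, "1-ribbon")
  expect_equal(component_sizes(fc2), c(10L, 10L))
  joined <- toggle_edge(two, 10, 11)
  fc1 <- induced_fibrillar_components(joined, "1-ribbon")
  expect_equal(component_sizes(fc1), 20L)
})

test_that("subthreshold fragments are not fibrillar components", {
  p3 <- aggregation_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_length(induced_fibrillar_components(p3, "1-ribbon")$components, 0L)
  dimer <- aggregation_graph(6, rbind(c(1, 2)))
  expect_length(induced_fibrillar_components(dimer, "1-ribbon")$components, 0L)
})

test_that("closed rings of locally fibrillar monomers are not fibrils", {
  ring <- aggregation_graph(12, cbind(1:12, c(2:12, 1)))
  expect_length(induced_fibrillar_components(ring, "1-ribbon")$components, 0L)
})

test_that("component extraction is invariant under vertex relabelling", {
  set.seed(55)
  base <- make_fixture("fibril_with_defect", "2-ribbon", L = 6)
  ref_sizes <- component_sizes(induced_fibrillar_components(base, "2-ribbon"))
  for (rep in 1:5) {
    perm <- sample(base$n)
    gp <- aggregation_graph(base$n, cbind(perm[base$edges[, 1]],
                                          perm[base$edges[, 2]]))
    expect_equal(component_sizes(induced_fibrillar_components(gp, "2-ribbon")),
                 ref_sizes)
  }
})

test_that("edge deletion never enlarges the biggest fibril; bridging never raises the count", {
  set.seed(66)
  g <- ideal_fibril("1-ribbon", 12)
  full <- induced_fibrillar_components(g, "1-ribbon")
  for (i in seq_len(nrow(g$edges))) {
    del <- toggle_edge(g, g$edges[i, 1], g$edges[i, 2])
    fc <- induced_fibrillar_components(del, "1-ribbon")
    ms <- if (length(fc$components)) max(component_sizes(fc)) else 0L
    expect_lte(ms, max(component_sizes(full)))
  }
  two <- aggregation_graph(24, rbind(ideal_fibril("1-ribbon", 12)$edges,
                                     ideal_fibril("1-ribbon", 12)$edges + 12L))
  n0 <- length(induced_fibrillar_components(two, "1-ribbon")$components)
  bridged <- toggle_edge(two, 12, 13)
  n1 <- length(induced_fibrillar_components(bridged, "1-ribbon")$components)
  expect_lte(n1, n0)
})

test_that("every returned component is isomorphic to a segment of its ideal fibril", {
  set.seed(77)
  p <- dendrite_params()
  tr <- simulate_fibrillization(25, p, max_events = 3000, seed = 19)
  g <- trajectory_graph(tr)
  fc <- induced_fibrillar_components(g, "1-ribbon")
  for (cp in fc$components) {
    em <- g$edges
    keep <- em[em[, 1] %in% cp$vertices & em[, 2] %in% cp$vertices, ,
               drop = FALSE]
    sub <- igraph::graph_from_data_frame(
      data.frame(from = match(keep[, 1], cp$vertices),
                 to = match(keep[, 2], cp$vertices)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(cp$vertices)))
    seg <- as_igraph(ideal_fibril("1-ribbon", cp$size))
    expect_true(igraph::isomorphic(sub, seg))
    expect_equal(sum(cp$role == "end"), 2L)
  }
})

test_that("the five ideal topologies classify to five distinct labels", {
  labels <- vapply(names(fibril_classes()),
                   function(nm) classify_topology(ideal_fibril(nm, 12)),
                   character(1))
  expect_equal(unname(labels), names(fibril_classes()))
  expect_equal(length(unique(labels)), 5L)
  expect_equal(classify_topology(aggregation_graph(4)), "non-fibrillar")
  k4 <- aggregation_graph(4, all_dyads(4))
  expect_equal(classify_topology(k4), "non-fibrillar")
})

test_that("custom templates round-trip through files and drive the same machinery", {
  t <- fibril_template("custom-ladder", 2L,
                       intra_edges = cbind(1L, 2L),
                       inter_edges = rbind(c(1L, 1L), c(2L, 2L)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_template(t, path)
  t2 <- read_template(path)
  expect_equal(t2$class_id, "custom-ladder")
  expect_equal(t2$subunit_size, 2L)
  g <- ideal_fibril(t2, 6)
  expect_equal(component_sizes(induced_fibrillar_components(g, t2)), 12L)
})
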