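test_that("single-frame metrics follow the component and fibril definitions", {
  # all monomers free: average component size one
  m0 <- graph_metrics(aggregation_graph(50), "1-ribbon")
  expect_equal(m0$avg_component_size, 1)
  expect_equal(m0$fibril_fraction, 0)
  expect_equal(m0$oligomer_count, 0)
  # pure fibril: fraction 1, one component of full size
  r <- ideal_fibril("1-ribbon", 10)
  m1 <- graph_metrics(r, "1-ribbon")
  expect_equal(m1$fibril_fraction, 1)
  expect_equal(m1$fibril_component_count, 1)
  expect_equal(m1$max_fibril_size, 10L)
  # oligomers: components of size in [2, 8)
  sizes <- c(3, 7, 8, 12)
  edges <- NULL; off <- 0L
  for (s in sizes) {
    edges <- rbind(edges, cbind(off + 1:(s - 1), off + 2:s))
    off <- off + s
  }
  g <- aggregation_graph(off, edges)
  expect_equal(graph_metrics(g, "1-ribbon")$oligomer_count, 2)
  # fibril fraction times n equals the summed fibrillar component sizes
  fc <- induced_fibrillar_components(g, "1-ribbon")
  expect_equal(graph_metrics(g, "1-ribbon")$fibril_fraction * g$n,
               sum(component_sizes(fc)))
})

test_that("metric series sample the event stream and match per-frame recomputation", {
  # frozen trajectory: constant series once its instantaneous setup window
  # (all bonds appear before t = end_time * 1e-12 * m) has passed
  g8 <- ideal_fibril("1-ribbon", 8)
  fr <- frozen_trajectory(g8, end_time = 5)
  s <- metric_series(fr, "1-ribbon", stride = 2)
  post <- s[s$event == nrow(fr$events), ]
  expect_equal(post$fibril_fraction, 1)
  full <- metric_series(fr, "1-ribbon", stride = nrow(fr$events))
  expect_equal(nrow(full), 2L)              # empty start + frozen state
  expect_equal(full$fibril_fraction, c(0, 1))
  expect_equal(full$max_fibril_size, c(0L, 8L))
  # sequential growth: fibril fraction is non-decreasing
  gt <- make_fixture("growth_trajectory", "1-ribbon", L = 12)
  sg <- metric_series(gt, "1-ribbon", stride = 1)
  expect_true(all(diff(sg$fibril_fraction) >= 0))
  expect_equal(sg$fibril_fraction[1], 0)
  expect_equal(sg$fibril_fraction[nrow(sg)], 1)
  # stride = 1 equals a naive full recomputation on a simulated stream
  p <- dendrite_params()
  tr <- simulate_fibrillization(12, p, max_events = 300, seed = 29)
  s1 <- metric_series(tr, "1-ribbon", stride = 1)
  for (i in c(2, 150, 301)) {
    g <- trajectory_graph(tr, s1$event[i])
    expect_equal(s1[i, names(graph_metrics(g, "1-ribbon"))],
                 graph_metrics(g, "1-ribbon"), ignore_attr = TRUE)
  }
  expect_true(all(diff(s1$time) > 0))
})

test_that("epoch boundaries land exactly on planted landmarks (unsmoothed)", {
  s <- make_fixture("metric_curve", frames = 100, peak_avg = 10,
                    cross_threshold = 25, peak_count = 40, converge_from = 70)
  seg <- segment_epochs(s, smooth_window = 1)
  expect_s3_class(seg, "epoch_segmentation")
  expect_equal(seg$label, c("Condensation", "Local Ordering", "Nucleation",
                            "Fibril Growth", "Maturation"))
  # frames are 1-based; time = frame - 1
  expect_equal(seg$t_start[1], s$time[1])
  expect_equal(seg$t_end[1], s$time[10])     # avg component size argmax
  expect_equal(seg$t_end[2], s$time[25])     # threshold crossing
  expect_equal(seg$t_end[3], s$time[40])     # component count argmax
  expect_equal(seg$t_end[4], s$time[70])     # convergence start
  expect_equal(seg$t_end[5], s$time[nrow(s)])
})

test_that("segmentations are contiguous and cover the whole time axis", {
  s <- make_fixture("metric_curve", frames = 120, peak_avg = 15,
                    cross_threshold = 30, peak_count = 55, converge_from = 90)
  for (w in c(1, 3)) {
    seg <- segment_epochs(s, smooth_window = w)
    expect_equal(seg$t_start[1], s$time[1])
    expect_equal(seg$t_end[nrow(seg)], s$time[nrow(s)])
    expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])
    expect_true(all(seg$t_end >= seg$t_start))
  }
})

test_that("epoch boundaries depend on frame order, not the absolute time scale", {
  s <- make_fixture("metric_curve")
  seg <- segment_epochs(s, smooth_window = 3)
  s2 <- s
  s2$time <- s$time * 1e4
  seg2 <- segment_epochs(s2, smooth_window = 3)
  expect_equal(seg2$t_start, seg$t_start * 1e4)
  expect_equal(seg2$t_end, seg$t_end * 1e4)
})

test_that("missing or out-of-order landmarks raise an informative condition", {
  s <- make_fixture("metric_curve")
  s$max_fibril_size[] <- 0   # nucleation threshold never reached
  err <- tryCatch(segment_epochs(s, smooth_window = 1), error = identity)
  expect_s3_class(err, "fibrilnet_epochs_undetectable")
  expect_match(conditionMessage(err), "not reached")
})

test_that("1-ribbon pathway schemes prepend a Dimerization epoch", {
  s <- make_fixture("metric_curve", frames = 100, peak_avg = 10,
                    cross_threshold = 25, peak_count = 40, converge_from = 70)
  for (nm in c("condensate-annealing", "dendrite-consolidation")) {
    seg <- segment_epochs(s, scheme = nm, smooth_window = 1)
    expect_equal(seg$label[1], "Dimerization")
    expect_equal(nrow(seg), 6L)
    # dimerization ends when average component size first reaches 2
    expect_equal(seg$t_end[1], s$time[which(s$avg_component_size >= 2)[1]])
  }
})

test_that("smoothing is a centered moving average with truncated ends", {
  x <- c(1, 2, 6, 2, 1, 1, 1)
  expect_equal(smooth_series(x, 1), x)
  sm <- smooth_series(x, 3)
  expect_equal(sm[1], mean(x[1:2]))
  expect_equal(sm[3], mean(x[2:4]))
  expect_equal(sm[7], mean(x[6:7]))
})
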