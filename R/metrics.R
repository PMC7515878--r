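#' Single-frame aggregation metrics
#'
#' Computes, for one aggregation state, the measures used to characterise
#' fibrillization mechanisms: the average component size (mean number of
#' monomers per aggregate, counting free monomers as singleton components),
#' the maximum induced fibril component size, the induced fibril component
#' count, the fibril fraction (fraction of all monomers bound within an
#' induced fibrillar component), and the oligomer count (connected
#' components of at least 2 but fewer than 8 monomers).
#'
#' @param g An [aggregation_graph()].
#' @param template Template object or class name.
#' @return One-row data frame with columns `avg_component_size`,
#'   `max_fibril_size`, `fibril_component_count`, `fibril_fraction`,
#'   `oligomer_count`.
#' @export
graph_metrics <- function(g, template) {
  stopifnot_graph(g)
  t <- get_template(template)
  comp <- igraph::components(as_igraph(g))
  fc <- induced_fibrillar_components(g, t)
  sizes <- component_sizes(fc)
  nfib <- sum(sizes)
  data.frame(
    avg_component_size = g$n / comp$no,
    max_fibril_size = if (length(sizes)) max(sizes) else 0L,
    fibril_component_count = length(sizes),
    fibril_fraction = nfib / g$n,
    oligomer_count = sum(comp$csize >= 2L & comp$csize < 8L))
}

#' Metric series along a trajectory
#'
#' Applies [graph_metrics()] at sampled frames of the event stream: after
#' every `stride` events, always including the initial empty state and the
#' final state.
#'
#' @param traj A `fibril_trajectory`.
#' @param template Template object or class name.
#' @param stride Events between sampled frames (defaults to the
#'   trajectory's `frame_interval`).
#' @return Object of class `metric_series`: a data frame with `time`,
#'   `event`, and the [graph_metrics()] columns; attributes carry `n`,
#'   the template class and its nucleation threshold.
#' @export
metric_series <- function(traj, template, stride = NULL) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  t <- get_template(template)
  if (is.null(stride)) stride <- traj$frame_interval
  stride <- max(1L, as.integer(stride))
  nev <- nrow(traj$events)
  at <- unique(c(0L, seq_len(nev)[seq_len(nev) %% stride == 0L], nev))
  # incremental replay: apply events between consecutive sampled frames
  g <- aggregation_graph(traj$n)
  rows <- vector("list", length(at))
  prev <- 0L
  for (i in seq_along(at)) {
    k <- at[i]
    if (k > prev) {
      ev <- traj$events[(prev + 1L):k, , drop = FALSE]
      for (j in seq_len(nrow(ev)))
        g <- toggle_edge(g, ev$u[j], ev$v[j])
      prev <- k
    }
    tm <- if (k == 0L) 0 else traj$events$time[k]
    rows[[i]] <- cbind(data.frame(time = tm, event = k), graph_metrics(g, t))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("metric_series", "data.frame"),
            n = traj$n, class_id = t$class_id,
            threshold = nucleation_threshold(t))
}

#' Centered moving average used for epoch boundary detection
#'
#' @param x Numeric vector.
#' @param window Window width in frames (>= 1); even widths are widened to
#'   the next odd number. Window ends are truncated at the series limits.
#' @return Smoothed vector of the same length.
#' @export
smooth_series <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Epoch labelling schemes
#'
#' The default `"standard"` scheme carries the five epochs shared by the
#' higher-order topologies: Condensation, Local Ordering, Nucleation,
#' Fibril Growth, Maturation. The two 1-ribbon pathway schemes
#' (`"condensate-annealing"`, `"dendrite-consolidation"`) share the same
#' boundary machinery but prepend a Dimerization epoch that ends when the
#' average component size first reaches 2; their later labels reflect the
#' narrative names of the two pathways.
#'
#' @param name Scheme name.
#' @return List with `name`, `labels` and `dimerization` flag.
#' @export
epoch_scheme <- function(name = c("standard", "condensate-annealing",
                                  "dendrite-consolidation")) {
  name <- match.arg(name)
  switch(name,
    "standard" = list(
      name = name, dimerization = FALSE,
      labels = c("Condensation", "Local Ordering", "Nucleation",
                 "Fibril Growth", "Maturation")),
    "condensate-annealing" = list(
      name = name, dimerization = TRUE,
      labels = c("Dimerization", "Condensation", "Local Ordering",
                 "Nucleation", "Defect Annealing", "Maturation")),
    "dendrite-consolidation" = list(
      name = name, dimerization = TRUE,
      labels = c("Dimerization", "Condensation", "Local Ordering",
                 "Nucleation", "Consolidation", "Maturation")))
}

#' Segment a metric series into epochs
#'
#' Boundaries are landmarks of the (smoothed) metric series:
#' \itemize{
#'   \item Condensation ends at the first maximum of the smoothed average
#'     component size.
#'   \item Local Ordering ends — and Nucleation starts — when the smoothed
#'     maximum induced fibril component size first reaches the nucleation
#'     threshold of the template.
#'   \item Nucleation ends — and Fibril Growth starts — at the first
#'     maximum of the smoothed induced fibril component count.
#'   \item Maturation starts at the earliest frame from which both the
#'     fibril fraction and the maximum fibril size stay within a relative
#'     fluctuation of `conv_tol` through the end of the series (candidate
#'     start no later than 90% of the frames, so convergence is always
#'     judged on a meaningful trailing window).
#' }
#' Dimerization (1-ribbon schemes) ends when the smoothed average component
#' size first reaches 2. Boundaries must occur in scheme order; otherwise
#' an error of class `fibrilnet_epochs_undetectable` reports which
#' boundaries were found.
#'
#' @param s A [metric_series()].
#' @param scheme Scheme name or [epoch_scheme()] object.
#' @param smooth_window Smoothing window in frames; default 1% of the
#'   frames, at least 3.
#' @param conv_tol Relative fluctuation tolerance for Maturation (default
#'   0.05).
#' @return Object of class `epoch_segmentation`: data frame with `label`,
#'   `t_start`, `t_end`; intervals are contiguous and cover the whole time
#'   axis.
#' @export
segment_epochs <- function(s, scheme = "standard", smooth_window = NULL,
                           conv_tol = 0.05) {
  stopifnot(inherits(s, "metric_series"))
  if (nrow(s) < 3L) stop("metric series too short to segment")
  if (is.character(scheme)) scheme <- epoch_scheme(scheme)
  nfr <- nrow(s)
  if (is.null(smooth_window)) smooth_window <- max(3L, ceiling(0.01 * nfr))
  thr <- attr(s, "threshold")
  sm_avg <- smooth_series(s$avg_component_size, smooth_window)
  sm_max <- smooth_series(s$max_fibril_size, smooth_window)
  sm_cnt <- smooth_series(s$fibril_component_count, smooth_window)
  sm_frac <- smooth_series(s$fibril_fraction, smooth_window)

  found <- list()
  idx_dim <- if (scheme$dimerization) {
    i <- which(sm_avg >= 2)[1L]
    found[["dimerization end"]] <- i
    i
  } else NA_integer_
  idx_cond <- which.max(sm_avg)                # first occurrence on ties
  found[["condensation end (avg size max)"]] <- idx_cond
  idx_nuc <- which(sm_max >= thr)[1L]
  found[["nucleation start (size threshold)"]] <- idx_nuc
  idx_growth <- which.max(sm_cnt)
  found[["growth start (component count max)"]] <- idx_growth

  rel_fluct <- function(x) {
    m <- mean(abs(x))
    if (m < .Machine$double.eps) 0 else (max(x) - min(x)) / m
  }
  idx_mat <- NA_integer_
  latest <- max(1L, floor(0.9 * nfr))
  from <- max(1L, if (is.na(idx_growth)) 1L else idx_growth)
  for (f in from:latest) {
    win <- f:nfr
    if (rel_fluct(sm_frac[win]) <= conv_tol &&
        rel_fluct(sm_max[win]) <= conv_tol) { idx_mat <- f; break }
  }
  found[["maturation start (convergence)"]] <- idx_mat

  bounds <- c(if (scheme$dimerization) idx_dim, idx_cond, idx_nuc,
              idx_growth, idx_mat)
  if (anyNA(bounds) || any(diff(bounds) < 0L)) {
    msg <- paste0(
      "epoch undetectable: boundaries must occur in order; found: ",
      paste(sprintf("%s = %s", names(found),
                    vapply(found, function(i)
                      if (is.na(i)) "not reached" else
                        sprintf("frame %d (t = %.4g)", i, s$time[i]),
                      character(1))),
            collapse = "; "))
    rlang::abort(msg, class = "fibrilnet_epochs_undetectable",
                 boundaries = found)
  }
  tb <- c(s$time[1L], s$time[bounds], s$time[nfr])
  seg <- data.frame(label = scheme$labels,
                    t_start = tb[-length(tb)],
                    t_end = tb[-1L],
                    stringsAsFactors = FALSE)
  structure(seg, class = c("epoch_segmentation", "data.frame"),
            boundaries = found, scheme = scheme$name,
            smooth_window = smooth_window, conv_tol = conv_tol)
}

#' @export
print.epoch_segmentation <- function(x, ...) {
  cat(sprintf("<epoch_segmentation> scheme %s\n", attr(x, "scheme")))
  print.data.frame(x)
  invisible(x)
}

#' Write / read metric series as CSV
#'
#' @param s A [metric_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metric_series <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_series
#' @param seg An [segment_epochs()] result.
#' @export
write_epochs <- function(seg, path) {
  utils::write.csv(as.data.frame(seg), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.metric_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$avg_component_size, type = "l",
                 xlab = "time (1/collision rate)", ylab = "avg component size")
  graphics::plot(x$time, x$max_fibril_size, type = "l",
                 xlab = "time (1/collision rate)", ylab = "max fibril size")
  graphics::plot(x$time, x$fibril_component_count, type = "l",
                 xlab = "time (1/collision rate)", ylab = "fibril components")
  graphics::plot(x$time, x$fibril_fraction, type = "l", ylim = c(0, 1),
                 xlab = "time (1/collision rate)", ylab = "fibril fraction")
  invisible(x)
}
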