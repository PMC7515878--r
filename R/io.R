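PARAM_KEYS <- c("phi_e", "phi_2s", "phi_NSP1", "phi_NSP2", "phi_ESP0",
                "phi_ESP1", "phi_C5", "phi_C6", "phi_C7")

#' Load model parameters from a YAML or JSON file
#'
#' The file must provide the nine motif coefficients (`phi_e`, `phi_2s`,
#' `phi_NSP1`, `phi_NSP2`, `phi_ESP0`, `phi_ESP1`, `phi_C5`, `phi_C6`,
#' `phi_C7`) and the temperature `T`; `k_B`, `A` and `ref_measure` default
#' to 1, 1 and `"counting"`.
#'
#' @param path File path; format chosen by extension (`.json` for JSON,
#'   anything else parsed as YAML).
#' @return A [model_params()] object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  missing <- setdiff(c(PARAM_KEYS, "T"), names(raw))
  if (length(missing))
    stop("parameter file ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "))
  vals <- raw[c(PARAM_KEYS, "T", intersect(c("k_B", "A"), names(raw)))]
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && !is.na(x), logical(1))]
  if (length(bad))
    stop("non-numeric parameter value(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  phi <- stats::setNames(as.numeric(raw[PARAM_KEYS]), STAT_NAMES)
  model_params(phi,
               T = raw$T,
               k_B = if (is.null(raw$k_B)) 1 else raw$k_B,
               A = if (is.null(raw$A)) 1 else raw$A,
               ref_measure = if (is.null(raw$ref_measure)) "counting"
                             else raw$ref_measure)
}

#' @rdname load_params
#' @param p A [model_params()] object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  out <- c(stats::setNames(as.list(unname(p$phi)), PARAM_KEYS),
           list(T = p$T, k_B = p$k_B, A = p$A, ref_measure = p$ref_measure))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path, precision = 17L)
  }
  invisible(path)
}

#' Provenance hash of a parameter set
#'
#' @param p A [model_params()] object.
#' @return Short hash string recorded in output file headers.
#' @export
params_hash <- function(p) {
  stopifnot(inherits(p, "model_params"))
  substr(rlang::hash(list(p$phi, p$T, p$k_B, p$A, p$ref_measure)), 1L, 12L)
}

## ---- graph serialization ------------------------------------------------

#' Write / read an aggregation graph as a TSV edge list
#'
#' One `u<TAB>v` pair per line, preceded by a `# n=<N>` header carrying the
#' vertex count (so isolated monomers survive the round trip).
#'
#' @param g An [aggregation_graph()].
#' @param path File path.
#' @return `write_graph_tsv` returns `path` invisibly; `read_graph_tsv`
#'   returns the graph.
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot_graph(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", g$n), con)
  if (nrow(g$edges))
    writeLines(sprintf("%d\t%d", g$edges[, 1L], g$edges[, 2L]), con)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# n=\\d+$", lines[1L]))
    stop("malformed graph file (line 1): expected '# n=<N>' header")
  n <- as.integer(sub("^# n=", "", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (!length(body)) return(aggregation_graph(n))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed graph file (line ", bad[1L] + 1L, "): expected 'u\\tv'")
  em <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(em))
    stop("malformed graph file: non-integer vertex label")
  aggregation_graph(n, em)
}

#' Export an aggregation graph as GraphML
#'
#' Interoperability export via igraph's GraphML writer.
#'
#' @inheritParams write_graph_tsv
#' @export
write_graphml <- function(g, path) {
  stopifnot_graph(g)
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

## ---- trajectory serialization -------------------------------------------

#' Write / read a kinetic trajectory as a TSV event stream
#'
#' The canonical trajectory format: a commented header (monomer count,
#' seed, parameter hash, frame interval, end time, package version)
#' followed by one record per bond-change event,
#' `event<TAB>time<TAB>u<TAB>v<TAB>add|del`. Times are written with full
#' (17 significant digit) precision so the round trip is bit-exact.
#'
#' @param traj A `fibril_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory (with `params = NULL`; parameters travel in
#'   their own file, referenced by hash).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fibrilnet_trajectory v1 package=%s",
            as.character(utils::packageVersion("fibrilnet"))),
    sprintf("# n=%d", traj$n),
    sprintf("# seed=%s", ifelse(is.na(traj$seed), "NA", traj$seed)),
    sprintf("# params_hash=%s",
            if (is.null(traj$params)) "NA" else params_hash(traj$params)),
    sprintf("# frame_interval=%d", traj$frame_interval),
    sprintf("# end_time=%.17g", traj$end_time),
    sprintf("# events=%d", nrow(traj$events))), con)
  if (nrow(traj$events))
    writeLines(sprintf("%d\t%.17g\t%d\t%d\t%s",
                       traj$events$event, traj$events$time,
                       traj$events$u, traj$events$v, traj$events$action), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  get_field <- function(name) {
    hit <- grep(sprintf("^# %s=", name), header, value = TRUE)
    if (!length(hit)) stop("trajectory file missing header field: ", name)
    sub(sprintf("^# %s=", name), "", hit[1L])
  }
  n <- as.integer(get_field("n"))
  seed <- suppressWarnings(as.integer(get_field("seed")))
  frame_interval <- as.integer(get_field("frame_interval"))
  end_time <- as.numeric(get_field("end_time"))
  nev <- as.integer(get_field("events"))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) != nev)
    stop("trajectory file truncated: header announces ", nev,
         " events but ", length(body), " records found")
  if (nev > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad))
      stop("malformed trajectory record at line ",
           which(!startsWith(lines, "#") & nzchar(lines))[bad[1L]])
    m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
    events <- data.frame(event = as.integer(m[, 1L]),
                         time = as.numeric(m[, 2L]),
                         u = as.integer(m[, 3L]),
                         v = as.integer(m[, 4L]),
                         action = m[, 5L],
                         stringsAsFactors = FALSE)
    if (anyNA(events$time) || anyNA(events$u) ||
        !all(events$action %in% c("add", "del")))
      stop("malformed trajectory record: bad field value")
  } else {
    events <- data.frame(event = integer(0), time = numeric(0),
                         u = integer(0), v = integer(0),
                         action = character(0), stringsAsFactors = FALSE)
  }
  new_trajectory(n, events, end_time = end_time, seed = seed,
                 frame_interval = frame_interval, params = NULL)
}

## ---- fixtures ------------------------------------------------------------

#' Deterministic fixtures for tests and examples
#'
#' Constructs small reference objects:
#' \describe{
#'   \item{`ideal_fibril`}{`make_fixture("ideal_fibril", template=, L=)`.}
#'   \item{`two_fibrils_joined`}{two disjoint ideal fibrils of `L` subunits
#'     joined by a single bond between terminal monomers.}
#'   \item{`fibril_with_defect`}{an ideal fibril with one extra monomer
#'     attached at `attach = "center"` or `"end"`.}
#'   \item{`growth_trajectory`}{a trajectory that assembles the ideal
#'     fibril bond by bond (times 1, 2, ...).}
#'   \item{`metric_curve`}{a synthetic [metric_series()] with planted epoch
#'     landmarks; see arguments below.}
#' }
#'
#' @param kind Fixture kind (above).
#' @param template Template object or class name (graph fixtures).
#' @param L Subunits (graph fixtures).
#' @param attach `"center"` or `"end"` for `fibril_with_defect`.
#' @param frames,peak_avg,cross_threshold,peak_count,converge_from Frame
#'   count and planted landmark frames for `metric_curve` (1-based frame
#'   indices: average component size peaks at `peak_avg`, the max fibril
#'   size first reaches the nucleation threshold at `cross_threshold`, the
#'   fibril component count peaks at `peak_count`, and both convergence
#'   series are constant from `converge_from` on).
#' @return An [aggregation_graph()], `fibril_trajectory` or
#'   [metric_series()] according to `kind`.
#' @export
make_fixture <- function(kind, template = "1-ribbon", L = 10L,
                         attach = c("center", "end"),
                         frames = 100L, peak_avg = 10L,
                         cross_threshold = 25L, peak_count = 40L,
                         converge_from = 70L) {
  kind <- match.arg(kind, c("ideal_fibril", "two_fibrils_joined",
                            "fibril_with_defect", "growth_trajectory",
                            "metric_curve"))
  t <- if (kind != "metric_curve") get_template(template) else NULL
  switch(kind,
    ideal_fibril = ideal_fibril(t, L),
    two_fibrils_joined = {
      f <- ideal_fibril(t, L)
      m <- f$n
      # two disjoint copies; one bond joining a terminal monomer of each
      edges <- rbind(f$edges, f$edges + m, c(m, m + 1L))
      aggregation_graph(2L * m, edges)
    },
    fibril_with_defect = {
      attach <- match.arg(attach)
      f <- ideal_fibril(t, L)
      site <- if (attach == "center") {
        mid_subunit <- ceiling(L / 2)
        (mid_subunit - 1L) * t$subunit_size + 1L
      } else {
        1L
      }
      aggregation_graph(f$n + 1L, rbind(f$edges, c(site, f$n + 1L)))
    },
    growth_trajectory = {
      f <- ideal_fibril(t, L)
      # bonds appear in canonical order, which is subunit-major, so the
      # assembled prefix is always a growing fibril segment
      m <- nrow(f$edges)
      ev <- data.frame(event = seq_len(m), time = as.numeric(seq_len(m)),
                       u = f$edges[, 1L], v = f$edges[, 2L],
                       action = rep("add", m), stringsAsFactors = FALSE)
      new_trajectory(f$n, ev, end_time = m + 1, seed = NA_integer_,
                     frame_interval = 1L, params = NULL)
    },
    metric_curve = {
      stopifnot(peak_avg < cross_threshold, cross_threshold < peak_count,
                peak_count < converge_from, converge_from < frames)
      thr <- nucleation_threshold(get_template(template))
      n_mono <- 100
      f <- as.integer(frames)
      idx <- seq_len(f)
      # symmetric tent around peak_avg so a short centered moving average
      # keeps the argmax in place
      avg <- 1 + 9 * pmax(0, 1 - abs(idx - peak_avg) / peak_avg)
      # flat below threshold, step to a converged plateau at cross_threshold
      maxs <- ifelse(idx < cross_threshold, thr * 0.5, thr * 3)
      maxs[idx >= converge_from] <- thr * 3
      cnt <- pmax(0, 4 - abs(idx - peak_count) / 5)
      frac <- pmin(0.8, pmax(0, (idx - cross_threshold) / (converge_from -
                                                            cross_threshold)) * 0.8)
      # visible fluctuation before the convergence point, constant after
      wig <- rep_len(c(-0.06, 0.06), f) * (idx < converge_from)
      frac <- pmax(0, pmin(1, frac + wig))
      maxs <- maxs * (1 + wig)
      maxs[idx >= converge_from] <- thr * 3
      frac[idx >= converge_from] <- 0.8
      out <- data.frame(time = as.numeric(idx - 1L), event = idx - 1L,
                        avg_component_size = avg,
                        max_fibril_size = maxs,
                        fibril_component_count = cnt,
                        fibril_fraction = frac,
                        oligomer_count = rep(0L, f))
      structure(out, class = c("metric_series", "data.frame"),
                n = n_mono, class_id = get_template(template)$class_id,
                threshold = thr)
    })
}

## ---- template serialization ----------------------------------------------

#' Read / write fibril templates as YAML or JSON
#'
#' A template file carries `class_id`, `subunit_size` and the
#' `intra_edges`, `inter_edges` and `next_inter_edges` position-pair lists
#' (each a list of two-element integer vectors).
#'
#' @param path File path; `.json` parsed as JSON, otherwise YAML.
#' @return `read_template` returns a [fibril_template()].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("class_id", "subunit_size")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("template file missing key(s): ", paste(missing, collapse = ", "))
  as_pairs <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, function(p) as.integer(p)))
  }
  fibril_template(raw$class_id, raw$subunit_size,
                  intra_edges = as_pairs(raw$intra_edges),
                  inter_edges = as_pairs(raw$inter_edges),
                  next_inter_edges = as_pairs(raw$next_inter_edges))
}

#' @rdname read_template
#' @param t A [fibril_template()].
#' @export
write_template <- function(t, path) {
  stopifnot(inherits(t, "fibril_template"))
  to_list <- function(m) {
    if (nrow(m) == 0L) return(list())
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  }
  out <- list(class_id = t$class_id, subunit_size = t$subunit_size,
              intra_edges = to_list(t$intra_edges),
              inter_edges = to_list(t$inter_edges),
              next_inter_edges = to_list(t$next_inter_edges))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
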