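#' Read a pulse-chase time course from TSV
#'
#' Expects a header row `species  time_h  replicate  concentration`
#' (tab-separated, UTF-8). Validation errors (duplicate measurements,
#' negative concentrations, malformed species labels) name the offending
#' row.
#'
#' @param path File path.
#' @param sep Species-label chain separator, see [parse_species()].
#' @return A [timecourse()].
#' @export
read_timecourse <- function(path, sep = "-") {
  df <- utils::read.delim(path, colClasses = c(species = "character"),
                          check.names = TRUE, fileEncoding = "UTF-8")
  timecourse(df, sep = sep)
}

#' Write a time course to TSV
#'
#' @param tc A [timecourse()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  utils::write.table(tc$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a remodeling network as an edge-list TSV
#'
#' Columns: `source`, `target`, `position`, `score`, `window_start_h`,
#' `window_end_h`. The on-disk window columns are in hours when `times`
#' is supplied, otherwise raw time indices are written and read back.
#'
#' @param net A `remodeling_network`.
#' @param path File path.
#' @param times Optional time grid (hours) translating window indices.
#' @return `read_network`: a `remodeling_network`; `write_network`:
#'   `path`, invisibly.
#' @export
write_network <- function(net, path, times = NULL) {
  stopifnot(inherits(net, "remodeling_network"))
  ed <- net$edges
  out <- data.frame(source = ed$source, target = ed$target,
                    position = ed$position, score = ed$score)
  if (!is.null(times)) {
    out$window_start_h <- times[ed$window_start]
    out$window_end_h <- times[ed$window_end]
  } else {
    out$window_start_h <- ed$window_start
    out$window_end_h <- ed$window_end
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_network
#' @param nodes Optional node set; defaults to the species appearing in
#'   the edge list.
#' @export
read_network <- function(path, nodes = NULL, times = NULL) {
  df <- utils::read.delim(path, colClasses = c(source = "character",
                                               target = "character"),
                          fileEncoding = "UTF-8")
  ws <- df$window_start_h
  we <- df$window_end_h
  if (!is.null(times)) {
    ws <- match(ws, times)
    we <- match(we, times)
  }
  ed <- data.frame(source = df$source, target = df$target,
                   position = df$position, score = df$score,
                   window_start = ws, window_end = we)
  remodeling_network(nodes %||% unique(c(df$source, df$target)), ed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a remodeling network to GraphML
#'
#' For inspection in graph viewers (Cytoscape, Gephi). Requires igraph.
#'
#' @param net A `remodeling_network`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a conversion-rate table from TSV
#'
#' Columns `position`, `initial_chain`, `new_chain`, `rate`, optionally
#' `experiment` (defaults to `"pooled"`). The packaged BHK21 PE table is
#' at `system.file("extdata", "pe_remodeling_rates_bhk21.tsv",
#' package = "lipidremodel")`.
#'
#' @param path File path.
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (is.null(df$experiment)) df$experiment <- "pooled"
  df$rate <- as.numeric(df$rate)
  rate_table(df)
}

#' Write a structured fit report
#'
#' JSON report carrying the fitted rate per edge (with position and
#' chains), the error trace, convergence metadata, the settings and seed
#' used, and the package version -- enough to re-run the fit exactly.
#'
#' @param fit A `remodel_fit`.
#' @param net The `remodeling_network` that was fitted.
#' @param path Output path.
#' @param config Optional list of run settings echoed into the report.
#' @param seed Optional seed echoed into the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, net, path, config = NULL, seed = NULL) {
  stopifnot(inherits(fit, "remodel_fit"))
  ed <- fit$sys$edges
  report <- list(
    rates = data.frame(source = ed$source, target = ed$target,
                       position = ed$position,
                       rate_per_h = unname(fit$theta)),
    errors = fit$errors,
    error_trace = fit$trace,
    iterations = fit$iterations,
    converged = fit$converged,
    lambda = fit$lambda,
    rank_deficient = fit$rank_deficient,
    negative_rates = fit$negative_rates,
    n_species = fit$sys$N,
    n_edges = nrow(net$edges),
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("lipidremodel")))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read back a fit report
#'
#' @param path Path written by [write_fit_report()].
#' @return The report as a list; `rates` is a data frame.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read / write a simulation specification as JSON
#'
#' The on-disk form carries the true network as an edge list (`source`,
#' `target` pairs), the per-edge rates, the initial concentrations, and
#' the design fields of [simulation_spec()]; the round trip through disk
#' is lossless.
#'
#' @param spec A [simulation_spec()].
#' @param path File path.
#' @return `read_simulation_spec`: a [simulation_spec()];
#'   `write_simulation_spec`: `path`, invisibly.
#' @export
write_simulation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  ed <- spec$true_network$edges
  jsonlite::write_json(list(
    nodes = spec$true_network$nodes,
    edges = data.frame(source = ed$source, target = ed$target),
    theta = spec$true_theta,
    x0 = as.list(spec$x0),
    times = spec$times, n_replicates = spec$n_replicates,
    noise_cv = spec$noise_cv, detection_floor = spec$detection_floor,
    seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_spec
#' @export
read_simulation_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ed <- as.data.frame(x$edges)
  ed$position <- mapply(differs_at_one_position, ed$source, ed$target)
  ed$score <- NA_real_
  ed$window_start <- NA_integer_
  ed$window_end <- NA_integer_
  simulation_spec(remodeling_network(x$nodes, ed), x$theta,
                  x0 = unlist(x$x0), times = x$times,
                  n_replicates = x$n_replicates, noise_cv = x$noise_cv,
                  detection_floor = x$detection_floor, seed = x$seed)
}

#' Run the full two-step pipeline
#'
#' Executes the complete procedure on one time-course file: infer the
#' correlation network, bidirectionalize it, fit the rates by collocation,
#' decompose them into relative deacylation/reacylation rates, and
#' optionally run the label-permutation control. Each stage logs a
#' message with its timing; a stage failure aborts with a stage-tagged
#' error.
#'
#' @param input Path to the time-course TSV ([read_timecourse()]).
#' @param out_dir Output directory (created if missing): writes
#'   `network.tsv`, `fit.json`, `relative_rates.json`, and optionally
#'   `permutation_control.json`.
#' @param inference An [inference_config()].
#' @param spline A [spline_model()].
#' @param lambda,max_iter,tol Fit settings, see [fit_dynamics()].
#' @param ref_deacyl,ref_reacyl Reference chains for the decomposition;
#'   `NULL` picks, per position, the chain with most table entries.
#' @param permutations Number of label permutations for the control;
#'   0 skips the control.
#' @param seed Seed for the control draws, echoed into every artifact.
#' @return Invisibly, a list with the in-memory artifacts (`tc`, `net`,
#'   `fit`, `rates`, `relative`, `control`).
#' @export
run_pipeline <- function(input, out_dir, inference = inference_config(),
                         spline = spline_model(), lambda = 1,
                         max_iter = 1000, tol = 1e-6,
                         ref_deacyl = NULL, ref_reacyl = NULL,
                         permutations = 0, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- list(alpha = inference$alpha,
                   corr_threshold = inference$corr_threshold,
                   min_window = inference$min_window,
                   second_order = inference$second_order,
                   lambda = lambda, max_iter = max_iter, tol = tol,
                   n_basis = spline$n_basis,
                   n_collocation = spline$n_collocation, seed = seed)

  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0))
    out
  }

  tc <- stage("read", read_timecourse(input))
  net <- stage("infer-network", bidirectionalize(infer_network(tc, inference)))
  if (!nrow(net$edges)) stop("[infer-network] empty network; nothing to fit",
                             call. = FALSE)
  write_network(net, file.path(out_dir, "network.tsv"), times = tc$times)

  fit <- stage("fit", fit_dynamics(tc, build_ode(net), spline = spline,
                                   lambda = lambda, max_iter = max_iter,
                                   tol = tol))
  write_fit_report(fit, net, file.path(out_dir, "fit.json"),
                   config = cfg_echo, seed = seed)

  rates <- stage("decompose", fit_to_rate_table(fit))
  relative <- list()
  for (pos in unique(rates$position)) {
    blk <- rates[rates$position == pos, , drop = FALSE]
    pick_ref <- function(chains) names(sort(table(chains), decreasing = TRUE))[1]
    rd <- ref_deacyl %||% pick_ref(blk$initial_chain)
    rr <- ref_reacyl %||% pick_ref(blk$new_chain)
    relative[[pos]] <- list(
      deacylation = as.data.frame(relative_deacylation(rates, pos, rd)),
      reacylation = as.data.frame(relative_reacylation(rates, pos, rr)),
      ref_deacyl = rd, ref_reacyl = rr)
  }
  jsonlite::write_json(c(relative, list(config = cfg_echo)),
                       file.path(out_dir, "relative_rates.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  control <- NULL
  if (permutations > 0) {
    control <- stage("permutation-control",
                     permutation_test(tc, net, n = permutations, seed = seed,
                                      spline = spline, lambda = lambda,
                                      max_iter = max_iter, tol = tol))
    jsonlite::write_json(c(unclass(control), list(config = cfg_echo)),
                         file.path(out_dir, "permutation_control.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tc = tc, net = net, fit = fit, rates = rates,
                 relative = relative, control = control))
}

#' Conversion-rate table of a fit
#'
#' Tabulates the fitted forward rates as a [rate_table()] (one row per
#' edge with a positive fitted rate, keyed by the chain exchanged at the
#' edge's sn position). Non-positive fitted rates are dropped: they carry
#' no flux and the decomposition requires positive entries.
#'
#' @param fit A `remodel_fit`.
#' @param experiment Experiment label stamped on the rows.
#' @return A [rate_table()].
#' @export
fit_to_rate_table <- function(fit, experiment = "fit") {
  stopifnot(inherits(fit, "remodel_fit"))
  ed <- fit$sys$edges
  chain_at <- function(label, pos) {
    s <- parse_species(label)
    format(if (pos == "sn1") s$sn1 else s$sn2)
  }
  df <- data.frame(position = ed$position, experiment = experiment,
                   initial_chain = mapply(chain_at, ed$source, ed$position),
                   new_chain = mapply(chain_at, ed$target, ed$position),
                   rate = unname(fit$theta))
  df <- df[df$rate > 0, , drop = FALSE]
  if (!nrow(df)) stop("no positive fitted rates to tabulate", call. = FALSE)
  # the same chain exchange can occur on several species backbones; the
  # table keeps the flux-weighted representative: the largest fitted rate
  df <- df[order(-df$rate), , drop = FALSE]
  df <- df[!duplicated(df[c("position", "initial_chain", "new_chain")]), ,
           drop = FALSE]
  rate_table(df)
}
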