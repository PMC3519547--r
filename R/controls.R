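#' Randomly permute species labels of a time course
#'
#' Negative-control transform: the species identities are shuffled
#' uniformly at random (the identity permutation is allowed) while the
#' time/replicate structure of every series is left untouched, so the
#' multiset of measured values is unchanged but the network structure is
#' scrambled.
#'
#' @param tc A [timecourse()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [timecourse()] with permuted species labels.
#' @export
permute_labels <- function(tc, seed = 1L) {
  stopifnot(inherits(tc, "timecourse"))
  if (length(tc$species) < 2) return(tc)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample(tc$species)
  map <- stats::setNames(perm, tc$species)
  d <- tc$data
  d$species <- unname(map[d$species])
  timecourse(d)
}

control_report <- function(real_error, null_errors, n_failed = 0L) {
  structure(list(real_error = real_error,
                 null_errors = as.numeric(null_errors),
                 mean = if (length(null_errors)) mean(null_errors) else NA_real_,
                 stddev = if (length(null_errors) > 1) stats::sd(null_errors) else NA_real_,
                 p_empirical = if (length(null_errors))
                   mean(null_errors <= real_error) else NA_real_,
                 n_failed = as.integer(n_failed)),
            class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat(sprintf("<control report> real error %.4g vs null mean %.4g (sd %.4g), empirical p = %.3g, %d null fits (%d failed)\n",
              x$real_error, x$mean, x$stddev, x$p_empirical,
              length(x$null_errors), x$n_failed))
  invisible(x)
}

#' Species-label permutation test of fit specificity
#'
#' Fits the model repeatedly to label-permuted copies of the data while
#' keeping the network inferred from the real data fixed, and compares
#' the converged error of the real fit to the null distribution.
#' A real fit far below the null mean shows the close fit is specific to
#' the true species-network correspondence, not an artifact of model
#' flexibility.
#'
#' @param tc A [timecourse()].
#' @param net A bidirectionalized `remodeling_network` inferred from the
#'   real (unpermuted) data.
#' @param n Number of permutations (default 100).
#' @param seed Base seed; permutation b uses `seed + b`.
#' @param error Which converged error to compare: `"E_obs"` (default,
#'   the misfit between prediction and observation, the quantity the
#'   procedure reports for a fitted experiment) or `"E_total"` (the full
#'   collocation objective).
#' @param ... Fit settings passed to [fit_dynamics()] (e.g. `lambda`,
#'   `max_iter`, `spline`).
#' @return A `control_report`: `real_error`, `null_errors`, `mean`,
#'   `stddev`, `p_empirical` (fraction of null errors <= real), and the
#'   count of failed null fits (failures are counted, never dropped
#'   silently).
#' @export
permutation_test <- function(tc, net, n = 100, seed = 1L,
                             error = c("E_obs", "E_total"), ...) {
  stopifnot(inherits(net, "remodeling_network"), n >= 0)
  error <- match.arg(error)
  sys <- build_ode(net)
  real <- fit_dynamics(tc, sys, ...)
  nulls <- numeric(0)
  failed <- 0L
  for (b in seq_len(n)) {
    ptc <- permute_labels(tc, seed = seed + b)
    e <- tryCatch(fit_dynamics(ptc, sys, ...)$errors[[error]],
                  error = function(err) NA_real_)
    if (is.na(e)) failed <- failed + 1L else nulls <- c(nulls, e)
  }
  control_report(real$errors[[error]], nulls, failed)
}

#' Major-parameter perturbation test of fit specificity
#'
#' Deletes the edges carrying the major inferred reactions, replaces them
#' with randomly drawn single-position edges among the observed species
#' (drawn uniformly from edges not already in the network), refits, and
#' compares the converged error to the unperturbed fit. A specific model
#' should fit clearly worse once its load-bearing reactions are replaced
#' by arbitrary ones.
#'
#' @param tc A [timecourse()].
#' @param net A bidirectionalized `remodeling_network`.
#' @param targeted_edges Data frame (or list) with columns/fields
#'   `source`, `target` naming the edges to remove; must be a subset of
#'   the network's edges. Empty set reproduces the plain fit.
#' @param n Number of random replacements drawn (default 20); each draw
#'   replaces every deleted edge by one random edge.
#' @param seed Base seed.
#' @param error Which converged error to compare, see [permutation_test()].
#' @param ... Fit settings passed to [fit_dynamics()].
#' @return A `control_report` comparing the unperturbed error (real) to
#'   the perturbed-refit errors (null).
#' @export
parameter_perturbation_test <- function(tc, net, targeted_edges, n = 20,
                                        seed = 1L,
                                        error = c("E_obs", "E_total"), ...) {
  stopifnot(inherits(net, "remodeling_network"))
  error <- match.arg(error)
  targeted_edges <- as.data.frame(targeted_edges)
  real <- fit_dynamics(tc, build_ode(net), ...)
  if (!nrow(targeted_edges)) return(control_report(real$errors[[error]],
                                                   real$errors[[error]]))

  key <- function(s, t) paste(s, t, sep = " -> ")
  net_keys <- key(net$edges$source, net$edges$target)
  tgt_keys <- key(targeted_edges$source, targeted_edges$target)
  if (!all(tgt_keys %in% net_keys)) {
    stop("targeted edges must be a subset of the network's edges", call. = FALSE)
  }
  kept <- net$edges[!(net_keys %in% tgt_keys), , drop = FALSE]

  # pool: all single-position directed edges among observed species that
  # are not already in the (kept) network
  nodes <- net$nodes
  pool <- list()
  for (s in nodes) for (v in nodes) {
    if (s == v || is.na(differs_at_one_position(s, v))) next
    if (key(s, v) %in% net_keys) next
    pool[[length(pool) + 1L]] <- c(s, v)
  }
  if (!length(pool)) stop("replacement edge pool is empty", call. = FALSE)

  nulls <- numeric(0)
  failed <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (b in seq_len(n)) {
    set.seed(seed + b)
    pick <- pool[sample.int(length(pool), min(nrow(targeted_edges), length(pool)))]
    repl <- data.frame(source = vapply(pick, `[`, "", 1),
                       target = vapply(pick, `[`, "", 2))
    repl$position <- mapply(differs_at_one_position, repl$source, repl$target)
    repl$score <- 0
    repl$window_start <- NA_integer_
    repl$window_end <- NA_integer_
    pnet <- remodeling_network(nodes, rbind(kept, repl))
    e <- tryCatch(fit_dynamics(tc, build_ode(pnet), ...)$errors[[error]],
                  error = function(err) NA_real_)
    if (is.na(e)) failed <- failed + 1L else nulls <- c(nulls, e)
  }
  control_report(real$errors[[error]], nulls, failed)
}
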