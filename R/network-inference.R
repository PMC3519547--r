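#' Configuration for remodeling-network inference
#'
#' @param alpha Significance level for the per-time-point source test.
#'   Either a single value (used at every time point) or a vector of
#'   length H - 1 giving a per-time-point schedule.
#' @param corr_threshold Minimal score an edge must exceed to be accepted.
#' @param min_window Minimal evidence-window length in time points; window
#'   shrinking never goes below this (a 2-point correlation is degenerate).
#' @param second_order Accept an edge source -> target also when the flux
#'   is masked because the target is itself remodeled onward to a
#'   neighbour: both links of the chain must clear `corr_threshold`.
#' @param decrease_margin Fractional mean decrease required by the
#'   fallback source rule used when a time point has fewer than 2
#'   replicates and no t-test is possible.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(alpha = 0.3, corr_threshold = 0.5,
                             min_window = 3, second_order = TRUE,
                             decrease_margin = 0.05) {
  stopifnot(all(alpha > 0), all(alpha < 1), min_window >= 2,
            corr_threshold >= -1, corr_threshold <= 1,
            decrease_margin >= 0)
  structure(list(alpha = alpha, corr_threshold = corr_threshold,
                 min_window = as.integer(min_window),
                 second_order = isTRUE(second_order),
                 decrease_margin = decrease_margin),
            class = "inference_config")
}

alpha_at <- function(cfg, h) {
  if (length(cfg$alpha) == 1L) cfg$alpha else cfg$alpha[h]
}

#' Detect remodeling sources at a time point
#'
#' A species is a candidate source at time index `h` if its concentration
#' is significantly decreasing from `t_h` to `t_{h+1}`: a one-sided
#' two-sample Welch test on the replicate values rejects "not decreasing"
#' at level `alpha`. When either time point carries fewer than 2
#' replicates the test is undefined and a fallback rule is used: the mean
#' must drop by at least `decrease_margin` (fractional), with a message.
#'
#' @param tc A [timecourse()].
#' @param h Time index, 1 <= h < H.
#' @param alpha Significance level.
#' @param decrease_margin Fallback fractional decrease, see
#'   [inference_config()].
#' @return Character vector of source species labels.
#' @export
detect_sources <- function(tc, h, alpha = 0.3, decrease_margin = 0.05) {
  stopifnot(inherits(tc, "timecourse"), h >= 1, h < length(tc$times))
  t0 <- tc$times[h]
  t1 <- tc$times[h + 1]
  out <- character(0)
  for (sp in tc$species) {
    x <- tc_replicates(tc, sp, t0)
    y <- tc_replicates(tc, sp, t1)
    if (length(x) >= 2 && length(y) >= 2 &&
        (stats::sd(x) > 0 || stats::sd(y) > 0)) {
      p <- stats::t.test(x, y, alternative = "greater")$p.value
      decreasing <- is.finite(p) && p < alpha
    } else {
      # degenerate replicate structure: fall back to a mean-decrease rule
      message(sprintf("detect_sources: < 2 replicates (or zero variance) for %s at h = %d; using mean-decrease rule",
                      sp, h))
      decreasing <- mean(y) < mean(x) * (1 - decrease_margin)
    }
    if (decreasing) out <- c(out, sp)
  }
  out
}

#' Single-position neighborhood of a species
#'
#' Observed species reachable from `s` by exchanging the chain at exactly
#' one sn position.
#'
#' @param s Species label (or `species_id`).
#' @param observed Character vector of observed species labels.
#' @return Character vector, a subset of `observed`.
#' @export
neighborhood <- function(s, observed) {
  s_lab <- if (inherits(s, "species_id")) render_species(s) else s
  stopifnot(s_lab %in% observed)
  keep <- vapply(observed, function(v) {
    v != s_lab && !is.na(differs_at_one_position(s_lab, v))
  }, logical(1))
  unname(observed[keep])
}

# Score the inverse co-variation of a source mean series against a target
# mean series over a window. sigma guard: if the target never increases
# anywhere in the window the score is forced non-positive.
score_series <- function(src, tgt) {
  if (length(src) != length(tgt) || length(src) < 2) {
    stop("score_series: series must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(src) == 0 || stats::sd(tgt) == 0) {
    message("edge_score: zero-variance series in window; score 0")
    return(0)
  }
  raw <- -stats::cor(src, tgt)
  if (all(diff(tgt) <= 0)) -abs(raw) else raw
}

#' Correlation score of a candidate remodeling edge
#'
#' Scores the evidence that `s` is converted into `v` over a time window:
#' the negated Pearson correlation of the replicate-mean series of the two
#' species, guarded by a sign function that forces a non-positive score
#' when the putative target never increases within the window. The score
#' lies in \[-1, 1\]; large positive values indicate that the source falls
#' while the target rises.
#'
#' @param s,v Source and target species labels.
#' @param tc A [timecourse()].
#' @param window Integer pair `(h_start, h_end)` of time indices.
#' @return Numeric score in \[-1, 1\]; zero-variance windows score 0.
#' @export
edge_score <- function(s, v, tc, window) {
  stopifnot(inherits(tc, "timecourse"), length(window) == 2,
            window[1] >= 1, window[2] <= length(tc$times),
            window[2] > window[1])
  idx <- seq.int(window[1], window[2])
  m <- tc_mean_matrix(tc)
  score_series(m[idx, s], m[idx, v])
}

#' Infer the reduced remodeling correlation network
#'
#' First stage of the two-step procedure. At each time point, species with
#' significantly decreasing concentration are flagged as candidate sources
#' ([detect_sources()]). For each source, single-position neighbours are
#' scanned over the window from that time point to the end of the course;
#' every target whose [edge_score()] clears `corr_threshold` is accepted
#' as an edge (a branched source can feed several targets; on degenerate
#' 2-point windows, where scores are all-or-nothing, only the single
#' best-scoring target is kept). A second-order rule additionally accepts a target
#' whose own signal is masked because it is remodeled onward: it is kept
#' when the source anti-correlates with the summed target + downstream
#' series and the target -> downstream link itself clears the threshold.
#' If no candidate passes, the window end is shrunk one point at a time
#' (later fluxes can mask earlier ones) down to `min_window` points --
#' or down to whatever points remain for a source that only starts to
#' decline near the end of the course. When a
#' source accumulates several targets, each edge score is recomputed
#' against the sum of the mean series of all its targets over the edge's
#' window. Ties between equal-scoring targets break lexicographically.
#'
#' @param tc A [timecourse()].
#' @param cfg An [inference_config()].
#' @return A `remodeling_network`: list with `nodes` (species labels) and
#'   `edges` (data frame: `source`, `target`, `position`, `score`,
#'   `window_start`, `window_end` as time indices).
#' @export
infer_network <- function(tc, cfg = inference_config()) {
  stopifnot(inherits(tc, "timecourse"), inherits(cfg, "inference_config"))
  H <- length(tc$times)
  m <- tc_mean_matrix(tc)
  edges <- list()

  # an edge keeps its first (earliest-h, hence longest-window) evidence;
  # re-detections at later, shorter windows do not overwrite it
  add_edge <- function(s, v, score, win) {
    key <- paste(s, v, sep = " -> ")
    if (is.null(edges[[key]])) {
      edges[[key]] <<- list(source = s, target = v,
                            position = differs_at_one_position(s, v),
                            score = score, window = win)
    }
    edges
  }

  any_source <- FALSE
  for (h in seq_len(H - 1L)) {
    # the shrink floor: never below min_window points, except when the
    # source appears so late that fewer points remain at all
    floor_len <- min(cfg$min_window, H - h + 1L)
    sources <- detect_sources(tc, h, alpha = alpha_at(cfg, h),
                              decrease_margin = cfg$decrease_margin)
    if (length(sources)) any_source <- TRUE
    for (s in sources) {
      nb <- sort(neighborhood(s, tc$species))
      if (!length(nb)) next
      h_end <- H
      repeat {
        idx <- seq.int(h, h_end)
        passing <- list()
        for (v in nb) {
          sc <- score_series(m[idx, s], m[idx, v])
          ok <- sc > cfg$corr_threshold
          if (!ok && cfg$second_order) {
            # target may be drained onward: test source against the summed
            # target + downstream series, and the downstream link itself
            for (w in setdiff(sort(neighborhood(v, tc$species)), s)) {
              sc_chain <- score_series(m[idx, s], m[idx, v] + m[idx, w])
              sc_link <- score_series(m[idx, v], m[idx, w])
              if (sc_chain > cfg$corr_threshold && sc_link > cfg$corr_threshold) {
                ok <- TRUE
                sc <- max(sc, min(sc_chain, sc_link))
                break
              }
            }
          }
          if (ok) passing[[v]] <- sc
        }
        if (length(passing)) {
          # degenerate 2-point windows are all-or-nothing (score +/-1);
          # keep only the lexicographically first of the ties there, the
          # full-length windows keep every passing target
          if (length(idx) == 2L && length(passing) > 1L) {
            top <- names(passing)[which.max(unlist(passing))]
            passing <- passing[top]
          }
          for (v in names(passing)) {
            edges <- add_edge(s, v, passing[[v]], c(h, h_end))
          }
          break
        }
        if (h_end - h + 1 <= floor_len || h_end <= h + 1) break
        h_end <- h_end - 1
      }
    }
  }

  if (!any_source) warning("no species passed source detection; returning empty network")

  ed <- edge_df(edges)
  # a source with several targets: final score against the sum of its
  # targets' mean series over each edge's own window
  if (nrow(ed)) {
    for (s in unique(ed$source)) {
      rows <- which(ed$source == s)
      if (length(rows) < 2) next
      tgts <- ed$target[rows]
      for (r in rows) {
        idx <- seq.int(ed$window_start[r], ed$window_end[r])
        ed$score[r] <- score_series(m[idx, s], rowSums(m[idx, tgts, drop = FALSE]))
      }
    }
  }
  remodeling_network(nodes = tc$species, edges = ed)
}

edge_df <- function(edges) {
  if (!length(edges)) {
    return(data.frame(source = character(0), target = character(0),
                      position = character(0), score = numeric(0),
                      window_start = integer(0), window_end = integer(0)))
  }
  do.call(rbind, lapply(unname(edges), function(e) {
    data.frame(source = e$source, target = e$target, position = e$position,
               score = e$score, window_start = e$window[1],
               window_end = e$window[2])
  }))
}

#' Construct a remodeling network
#'
#' @param nodes Character vector of species labels.
#' @param edges Data frame with columns `source`, `target`, `position`,
#'   `score`, `window_start`, `window_end`.
#' @return An object of class `remodeling_network`.
#' @export
remodeling_network <- function(nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  stopifnot(all(c("source", "target", "position", "score",
                  "window_start", "window_end") %in% names(edges)))
  edges <- as.data.frame(edges)
  rownames(edges) <- NULL
  if (nrow(edges)) {
    if (!all(edges$source %in% nodes) || !all(edges$target %in% nodes)) {
      stop("edge endpoint not among nodes", call. = FALSE)
    }
    if (any(edges$source == edges$target)) stop("self-edge not allowed", call. = FALSE)
    pos <- mapply(differs_at_one_position, edges$source, edges$target)
    if (anyNA(pos) || !all(pos == edges$position)) {
      stop("every edge must join species differing at exactly its stated sn position",
           call. = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "remodeling_network")
}

#' @export
print.remodeling_network <- function(x, ...) {
  cat(sprintf("<remodeling network> %d species, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Full single-position network over a species set
#'
#' All directed edges between observed species differing at exactly one
#' sn position -- the unreduced search space that the correlation step
#' prunes. Fitting against it is the "full" endpoint of the
#' threshold-robustness protocol.
#'
#' @param species Character vector of species labels.
#' @return A `remodeling_network` (already bidirectional by symmetry);
#'   edge scores 0, windows `NA`.
#' @export
full_network <- function(species) {
  species <- sort(unique(species))
  ed <- list()
  for (s in species) for (v in species) {
    if (s == v) next
    pos <- differs_at_one_position(s, v)
    if (is.na(pos)) next
    ed[[length(ed) + 1L]] <- data.frame(source = s, target = v, position = pos,
                                        score = 0, window_start = NA_integer_,
                                        window_end = NA_integer_)
  }
  if (!length(ed)) stop("no single-position pairs among the given species",
                        call. = FALSE)
  remodeling_network(species, do.call(rbind, ed))
}

#' Add reverse reactions to every inferred edge
#'
#' The dynamic fit uses bidirectional reactions: each inferred conversion
#' gets a reverse partner (score 0, same evidence window) unless one was
#' inferred already. Idempotent.
#'
#' @param net A `remodeling_network`.
#' @return A `remodeling_network` in which every edge has a reverse.
#' @export
bidirectionalize <- function(net) {
  stopifnot(inherits(net, "remodeling_network"))
  ed <- net$edges
  if (!nrow(ed)) return(net)
  key <- paste(ed$source, ed$target)
  add <- ed[!(paste(ed$target, ed$source) %in% key), , drop = FALSE]
  if (nrow(add)) {
    rev <- data.frame(source = add$target, target = add$source,
                      position = add$position, score = 0,
                      window_start = add$window_start,
                      window_end = add$window_end)
    ed <- rbind(ed, rev)
  }
  remodeling_network(net$nodes, ed)
}
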