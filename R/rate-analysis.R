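#' Conversion-rate table
#'
#' Tabulates fitted first-order conversion rates k (h^-1) by sn position,
#' experiment (pulse-chase precursor), initial chain and new chain. One
#' row per modeled reaction; reactions not modeled in an experiment
#' (missing species or low flux) are simply absent, which is different
#' from a rate of zero.
#'
#' @param df Data frame with columns `position` (`"sn1"`/`"sn2"`),
#'   `experiment` (precursor label, free text), `initial_chain`,
#'   `new_chain` (`"C:D"` tokens), `rate` (>= 0).
#' @return An object of class `rate_table` (a validated data frame).
#' @seealso [read_rate_table()] for the TSV reader, and the packaged
#'   BHK21 PE table `system.file("extdata", "pe_remodeling_rates_bhk21.tsv",
#'   package = "lipidremodel")`.
#' @export
rate_table <- function(df) {
  req <- c("position", "experiment", "initial_chain", "new_chain", "rate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("rate table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  df$rate <- as.numeric(df$rate)
  if (!nrow(df)) stop("rate table is empty", call. = FALSE)
  if (!all(df$position %in% c("sn1", "sn2"))) {
    stop("position must be 'sn1' or 'sn2'", call. = FALSE)
  }
  for (ch in unique(c(df$initial_chain, df$new_chain))) parse_chain(ch)
  if (any(df$initial_chain == df$new_chain)) {
    stop("initial and new chain must differ", call. = FALSE)
  }
  if (anyNA(df$rate) || any(df$rate < 0)) {
    stop("rates must be non-negative numbers", call. = FALSE)
  }
  structure(df, class = c("rate_table", "data.frame"))
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate table> %d reactions (%d sn1, %d sn2)\n", nrow(x),
              sum(x$position == "sn1"), sum(x$position == "sn2")))
  print(as.data.frame(x))
  invisible(x)
}

# Entries for one sn position: experiment-resolved rows.
rt_block <- function(table, position) {
  stopifnot(inherits(table, "rate_table"))
  b <- table[table$position == position, , drop = FALSE]
  if (!nrow(b)) stop("no entries at position ", position, call. = FALSE)
  b
}

# Rate for one (experiment-agnostic) cell, averaging duplicates across
# experiments; NA when absent.
rt_cell <- function(block, initial, new) {
  r <- block$rate[block$initial_chain == initial & block$new_chain == new]
  if (!length(r)) NA_real_ else mean(r)
}

#' Effective conversion rates implied by deacylation/reacylation rates
#'
#' Under the Lands-cycle steady-state treatment of the lyso intermediate
#' (deacylation of any chain feeds a common intermediate pool whose
#' concentration is quasi-stationary and small), the effective first-order
#' conversion rate from initial chain i to new chain j at one sn position
#' is rank-1:
#' \deqn{k_{i \to j} = d_i\, a_j / \textstyle\sum_l a_l,}
#' where `d_i` is the deacylation rate of chain i and `a_j` the
#' reacylation rate of chain j. Row ratios of the resulting table recover
#' d ratios and column ratios recover a ratios exactly.
#'
#' @param d Named positive vector of deacylation rates (names are chains).
#' @param a Named positive vector of reacylation rates.
#' @param position `"sn1"` or `"sn2"` to stamp on the result.
#' @return A [rate_table()] with one row per ordered chain pair i != j
#'   (experiment `"steady-state"`).
#' @export
steady_state_rate_table <- function(d, a, position = "sn1") {
  stopifnot(length(d) >= 1, length(a) >= 1,
            !is.null(names(d)), !is.null(names(a)),
            all(d > 0), all(a > 0))
  grid <- expand.grid(initial_chain = names(d), new_chain = names(a),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$initial_chain != grid$new_chain, , drop = FALSE]
  if (!nrow(grid)) stop("no off-diagonal chain pairs", call. = FALSE)
  grid$rate <- d[grid$initial_chain] * a[grid$new_chain] / sum(a)
  grid$position <- position
  grid$experiment <- "steady-state"
  rate_table(grid)
}

#' Ratio of two conversion rates out of the same initial chain
#'
#' `k(i -> j1) / k(i -> j2)` at one sn position. Because reacylation draws
#' on a shared acyl-donor pool, this ratio estimates the relative
#' reacylation rate of j1 vs j2 independent of how fast chain i is
#' removed. Duplicate entries (same cell measured in several experiments)
#' are averaged first.
#'
#' @param table A [rate_table()].
#' @param position `"sn1"` or `"sn2"`.
#' @param initial Initial chain.
#' @param new1,new2 New chains of numerator and denominator.
#' @param digits Optional rounding of the result (default none).
#' @return Numeric scalar.
#' @export
pairwise_rate_ratio <- function(table, position, initial, new1, new2,
                                digits = NULL) {
  b <- rt_block(table, position)
  k1 <- rt_cell(b, initial, new1)
  k2 <- rt_cell(b, initial, new2)
  if (is.na(k1) || is.na(k2)) {
    stop(sprintf("missing rate entry for %s -> %s at %s", initial,
                 if (is.na(k1)) new1 else new2, position), call. = FALSE)
  }
  r <- k1 / k2
  if (!is.null(digits)) r <- round(r, digits)
  r
}

ratio_mean <- function(ratios, method) {
  if (method == "geometric") exp(mean(log(ratios))) else mean(ratios)
}

#' Relative reacylation rates per chain
#'
#' For each new chain j, averages over table rows (experiment x initial
#' chain) the ratio `k(i -> j) / k(i -> ref)` wherever both entries
#' exist. Under the rank-1 steady-state structure every such ratio equals
#' `a_j / a_ref`, so averaging over rows pools independent experiments.
#'
#' @param table A [rate_table()]; subset it first (e.g. to one
#'   experiment) to restrict which rows enter the average.
#' @param position `"sn1"` or `"sn2"`.
#' @param ref Reference new chain (ratio 1 by construction).
#' @param method `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-row ratios.
#' @return Data frame with columns `chain`, `ratio`, `n_pairs`, sorted by
#'   decreasing ratio; chains never co-occurring with `ref` in any row are
#'   dropped with a warning. Class `relative_rates`, attribute
#'   `kind = "reacylation"`.
#' @export
relative_reacylation <- function(table, position, ref,
                                 method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  b <- rt_block(table, position)
  if (!ref %in% b$new_chain) {
    stop("reference new chain ", ref, " absent from every row", call. = FALSE)
  }
  rows <- split(b, paste(b$experiment, b$initial_chain))
  chains <- setdiff(unique(b$new_chain), ref)
  out <- lapply(chains, function(j) {
    ratios <- unlist(lapply(rows, function(r) {
      kj <- r$rate[r$new_chain == j]
      kr <- r$rate[r$new_chain == ref]
      if (length(kj) == 1 && length(kr) == 1) kj / kr else NULL
    }))
    if (is.null(ratios)) return(NULL)
    data.frame(chain = j, ratio = ratio_mean(ratios, method),
               n_pairs = length(ratios))
  })
  dropped <- chains[vapply(out, is.null, TRUE)]
  if (length(dropped)) {
    warning("chain(s) never co-occurring with reference in any row, dropped: ",
            paste(dropped, collapse = ", "))
  }
  res <- rbind(data.frame(chain = ref, ratio = 1,
                          n_pairs = sum(b$new_chain == ref)),
               do.call(rbind, out))
  res <- res[order(-res$ratio), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("relative_rates", "data.frame"),
            kind = "reacylation", ref = ref, position = position)
}

#' Relative deacylation rates per chain
#'
#' For each initial chain i, averages over table columns (new chains j)
#' the ratio `k(i -> j) / k(ref -> j)` wherever both the row of i and the
#' row of the reference chain carry an entry in column j. Under the
#' rank-1 steady-state structure every such ratio equals `d_i / d_ref`.
#' When an initial chain was measured in several experiments each of its
#' rows contributes its own ratios to the average; the reference row is
#' collapsed (per-column mean) first.
#'
#' @inheritParams relative_reacylation
#' @param ref Reference initial chain (ratio 1 by construction).
#' @return Data frame as in [relative_reacylation()], attribute
#'   `kind = "deacylation"`.
#' @export
relative_deacylation <- function(table, position, ref,
                                 method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  b <- rt_block(table, position)
  if (!ref %in% b$initial_chain) {
    stop("reference initial chain ", ref, " absent from every column",
         call. = FALSE)
  }
  ref_rows <- b[b$initial_chain == ref, , drop = FALSE]
  ref_cols <- tapply(ref_rows$rate, ref_rows$new_chain, mean)
  chains <- setdiff(unique(b$initial_chain), ref)
  out <- lapply(chains, function(i) {
    ri <- b[b$initial_chain == i, , drop = FALSE]
    shared <- ri$new_chain %in% names(ref_cols)
    if (!any(shared)) return(NULL)
    ratios <- ri$rate[shared] / as.numeric(ref_cols[ri$new_chain[shared]])
    data.frame(chain = i, ratio = ratio_mean(ratios, method),
               n_pairs = sum(shared))
  })
  dropped <- chains[vapply(out, is.null, TRUE)]
  if (length(dropped)) {
    warning("chain(s) sharing no column with reference, dropped: ",
            paste(dropped, collapse = ", "))
  }
  res <- rbind(data.frame(chain = ref, ratio = 1, n_pairs = length(ref_cols)),
               do.call(rbind, out))
  res <- res[order(-res$ratio), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("relative_rates", "data.frame"),
            kind = "deacylation", ref = ref, position = position)
}

#' @export
print.relative_rates <- function(x, ...) {
  cat(sprintf("<relative %s rates> %s, reference %s\n", attr(x, "kind"),
              attr(x, "position"), attr(x, "ref")))
  print(as.data.frame(x))
  invisible(x)
}

#' Flag conversion-rate orderings inconsistent with pooled reacylation
#'
#' The steady-state model predicts that within any row the ordering of
#' rates follows the common reacylation ranking. This diagnostic checks
#' each row against the ranking pooled from all *other* rows
#' (leave-one-out, so an anomalous row cannot mask itself) and lists the
#' (row, chain pair) combinations whose ordering contradicts it -- e.g.
#' an sn2 chain replaced by 20:4 faster than by 18:1 although every other
#' row ranks 18:1 first. Such conflicts may signal cooperativity between
#' the sn positions; they are reported, never corrected.
#'
#' @param table A [rate_table()].
#' @param position `"sn1"` or `"sn2"`.
#' @param ref Reference new chain for the pooled ranking.
#' @return Data frame of conflicts (possibly 0 rows): `experiment`,
#'   `initial_chain`, `faster_chain`, `slower_chain`, `row_ratio`,
#'   `pooled_ratio`.
#' @export
reacylation_consistency <- function(table, position, ref) {
  b <- rt_block(table, position)
  rows <- split(b, paste(b$experiment, b$initial_chain))
  conflicts <- list()
  for (nm in names(rows)) {
    r <- rows[[nm]]
    rest <- b[paste(b$experiment, b$initial_chain) != nm, , drop = FALSE]
    if (!nrow(rest) || !ref %in% rest$new_chain) next
    rel <- tryCatch(
      suppressWarnings(relative_reacylation(rate_table(rest), position, ref)),
      error = function(e) NULL)
    if (is.null(rel)) next
    rank_of <- stats::setNames(rel$ratio, rel$chain)
    cc <- r$new_chain[r$new_chain %in% names(rank_of)]
    if (length(cc) < 2) next
    for (p in utils::combn(cc, 2, simplify = FALSE)) {
      k1 <- r$rate[r$new_chain == p[1]]
      k2 <- r$rate[r$new_chain == p[2]]
      row_faster <- if (k1 >= k2) p[1] else p[2]
      pooled_faster <- if (rank_of[p[1]] >= rank_of[p[2]]) p[1] else p[2]
      if (row_faster != pooled_faster) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          experiment = r$experiment[1], initial_chain = r$initial_chain[1],
          faster_chain = row_faster,
          slower_chain = setdiff(p, row_faster),
          row_ratio = max(k1, k2) / min(k1, k2),
          pooled_ratio = max(rank_of[p]) / min(rank_of[p]))
      }
    }
  }
  if (!length(conflicts)) {
    return(data.frame(experiment = character(0), initial_chain = character(0),
                      faster_chain = character(0), slower_chain = character(0),
                      row_ratio = numeric(0), pooled_ratio = numeric(0)))
  }
  out <- do.call(rbind, conflicts)
  rownames(out) <- NULL
  out
}
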