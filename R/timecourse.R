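#' Pulse-chase time course
#'
#' Container for replicate concentration measurements of a set of lipid
#' species over an ordered set of chase times. Concentrations are in
#' arbitrary MS-intensity units; the method is scale-free (fit errors
#' scale quadratically with the unit).
#'
#' @param data Data frame with columns `species` (label, `"C:D-C:D"`),
#'   `time_h` (hours), `replicate` (index), `concentration` (>= 0).
#'   Replicate counts may differ by time point, but every species must be
#'   measured at every time point by at least one replicate.
#' @param sep Species-label separator passed to [parse_species()].
#' @return An object of class `timecourse`: list with `data` (validated
#'   data frame), `species` (character vector, sorted), `times` (strictly
#'   increasing numeric vector, length H >= 3).
#' @examples
#' df <- expand.grid(species = c("18:3-18:3", "18:1-18:3"),
#'                   time_h = c(0, 4, 24), replicate = 1:2)
#' df$concentration <- runif(nrow(df), 1, 10)
#' tc <- timecourse(df)
#' @export
timecourse <- function(data, sep = "-") {
  required <- c("species", "time_h", "replicate", "concentration")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("time course is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  data$species <- as.character(data$species)
  data$time_h <- as.numeric(data$time_h)
  data$replicate <- as.integer(data$replicate)
  data$concentration <- as.numeric(data$concentration)

  if (anyNA(data)) {
    stop("time course contains missing values (row ",
         which(!stats::complete.cases(data))[1], ")", call. = FALSE)
  }
  neg <- which(data$concentration < 0)
  if (length(neg)) {
    stop("negative concentration at row ", neg[1], call. = FALSE)
  }
  dup <- duplicated(data[c("species", "time_h", "replicate")])
  if (any(dup)) {
    stop("duplicate (species, time, replicate) measurement at row ", which(dup)[1],
         call. = FALSE)
  }
  # labels must parse; this also rejects ether-lipid prefixes
  for (sp in unique(data$species)) parse_species(sp, sep = sep)

  times <- sort(unique(data$time_h))
  if (length(times) < 3L) {
    stop("time course needs at least 3 time points, got ", length(times),
         call. = FALSE)
  }
  species <- sort(unique(data$species))
  have <- table(data$species, data$time_h) > 0
  if (!all(have)) {
    miss <- which(!have, arr.ind = TRUE)[1, ]
    stop(sprintf("species %s has no measurement at t = %s h",
                 rownames(have)[miss[1]], colnames(have)[miss[2]]), call. = FALSE)
  }
  structure(list(data = data, species = species, times = times),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d species x %d time points (%g-%g h), %d measurements\n",
              length(x$species), length(x$times), min(x$times), max(x$times),
              nrow(x$data)))
  invisible(x)
}

#' Replicate means and standard errors per species and time point
#'
#' @param tc A [timecourse()].
#' @return Data frame with columns `species`, `time_h`, `n`, `mean`, `sem`
#'   (`sem` is `NA` for a single replicate).
#' @export
tc_summary <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  agg <- stats::aggregate(concentration ~ species + time_h, data = tc$data,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(species = agg$species, time_h = agg$time_h,
                    n = agg$concentration[, "n"],
                    mean = agg$concentration[, "mean"])
  out$sem <- agg$concentration[, "sd"] / sqrt(out$n)
  out[order(out$species, out$time_h), , drop = FALSE]
}

# Species-by-time matrix of replicate means (rows = times, cols = species).
tc_mean_matrix <- function(tc) {
  s <- tc_summary(tc)
  m <- matrix(NA_real_, nrow = length(tc$times), ncol = length(tc$species),
              dimnames = list(NULL, tc$species))
  idx_t <- match(s$time_h, tc$times)
  idx_s <- match(s$species, tc$species)
  m[cbind(idx_t, idx_s)] <- s$mean
  m
}

# Replicate values for one species at one time point.
tc_replicates <- function(tc, species, time_h) {
  d <- tc$data
  d$concentration[d$species == species & d$time_h == time_h]
}
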