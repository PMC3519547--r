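# Shared fixtures, built in code.

# Remodeling network along a species path.
make_path_network <- function(path) {
  ed <- data.frame(source = head(path, -1), target = tail(path, -1))
  ed$position <- mapply(differs_at_one_position, ed$source, ed$target)
  ed$score <- NA_real_
  ed$window_start <- NA_integer_
  ed$window_end <- NA_integer_
  remodeling_network(path, ed)
}

# Canonical 3-species single-path cascade (sn1 then sn2 conversion).
chain3_spec <- function(noise_cv = 0, seed = 1, times = c(0, 1, 2, 4, 8, 24),
                        theta = c(0.25, 0.05)) {
  net <- make_path_network(c("18:3-18:3", "18:1-18:3", "18:1-18:1"))
  simulation_spec(net, theta, x0 = c("18:3-18:3" = 100), times = times,
                  noise_cv = noise_cv, seed = seed)
}

# 6-species cascade with rates inside the observed primary-rate range;
# every species is dynamically active within the 24 h chase.
cascade6_spec <- function(noise_cv = 0.10, seed = 1) {
  p6 <- c("14:0-14:0", "18:1-14:0", "18:1-18:1", "18:1-18:2",
          "16:0-18:2", "16:0-16:1")
  simulation_spec(make_path_network(p6), c(0.5, 0.25, 0.12, 0.06, 0.03),
                  x0 = c("14:0-14:0" = 100), noise_cv = noise_cv, seed = seed)
}

# Small timecourse data frame built from a matrix of means (rows = times),
# exact replicates.
tc_from_means <- function(means, times, n_rep = 2) {
  stopifnot(nrow(means) == length(times))
  rows <- expand.grid(replicate = seq_len(n_rep), time_h = times,
                      species = colnames(means), stringsAsFactors = FALSE)
  rows$concentration <- means[cbind(match(rows$time_h, times),
                                    match(rows$species, colnames(means)))]
  timecourse(rows[c("species", "time_h", "replicate", "concentration")])
}

bhk21_rates <- function() {
  read_rate_table(system.file("extdata", "pe_remodeling_rates_bhk21.tsv",
                              package = "lipidremodel"))
}
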