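#' All diacyl species over two chain panels
#'
#' Cartesian product of candidate sn1 and sn2 chains; the node set of the
#' full remodeling network. Each species has (|sn1| - 1) + (|sn2| - 1)
#' single-position neighbours, so the full directed network over an
#' n1 x n2 grid has n1 * n2 * ((n1 - 1) + (n2 - 1)) edges.
#'
#' @param sn1_chains,sn2_chains Character vectors of `"C:D"` tokens.
#' @return Character vector of species labels, sn1 varying slowest.
#' @examples
#' make_species_grid(c("18:3", "18:1"), c("18:3", "18:1"))
#' @export
make_species_grid <- function(sn1_chains, sn2_chains) {
  stopifnot(length(sn1_chains) >= 1, length(sn2_chains) >= 1)
  for (ch in c(sn1_chains, sn2_chains)) parse_chain(ch)
  as.vector(t(outer(sn1_chains, sn2_chains, paste, sep = "-")))
}

#' Rank-1 ground-truth network over a chain grid
#'
#' Builds the full single-position remodeling network over the species
#' grid of two chain panels, with every rate given by the Lands-cycle
#' steady-state structure `k = d_i a_j / sum(a)` applied per position
#' (see [steady_state_rate_table()]). This emulates a system in which a
#' common lyso-intermediate pool couples all conversions at a position.
#'
#' @param d_sn1,a_sn1 Named positive deacylation/reacylation rate vectors
#'   over the sn1 chain panel (equal names).
#' @param d_sn2,a_sn2 Same for the sn2 panel.
#' @return List with `network` (a `remodeling_network` over the full
#'   grid) and `theta` (rate per edge, h^-1).
#' @export
rank1_truth <- function(d_sn1, a_sn1, d_sn2, a_sn2) {
  stopifnot(identical(sort(names(d_sn1)), sort(names(a_sn1))),
            identical(sort(names(d_sn2)), sort(names(a_sn2))))
  nodes <- make_species_grid(names(d_sn1), names(d_sn2))
  k1 <- steady_state_rate_table(d_sn1, a_sn1, "sn1")
  k2 <- steady_state_rate_table(d_sn2, a_sn2, "sn2")
  rate_of <- function(tab, i, j) tab$rate[tab$initial_chain == i & tab$new_chain == j]
  ed <- list()
  for (s in nodes) {
    sp <- parse_species(s)
    for (v in setdiff(nodes, s)) {
      pos <- differs_at_one_position(s, v)
      if (is.na(pos)) next
      vp <- parse_species(v)
      r <- if (pos == "sn1") rate_of(k1, format(sp$sn1), format(vp$sn1))
           else rate_of(k2, format(sp$sn2), format(vp$sn2))
      ed[[length(ed) + 1L]] <- data.frame(source = s, target = v,
                                          position = pos, rate = r)
    }
  }
  ed <- do.call(rbind, ed)
  net <- remodeling_network(nodes, data.frame(
    source = ed$source, target = ed$target, position = ed$position,
    score = NA_real_, window_start = NA_integer_, window_end = NA_integer_))
  # remodeling_network() sorts nothing but edge order is preserved
  list(network = net, theta = ed$rate)
}

# Remodeling network along a species path (consecutive species must be
# single-position neighbours); used to define simple ground truths.
path_network <- function(species_path, nodes = species_path) {
  stopifnot(length(species_path) >= 2)
  ed <- data.frame(source = utils::head(species_path, -1),
                   target = utils::tail(species_path, -1))
  ed$position <- mapply(differs_at_one_position, ed$source, ed$target)
  if (anyNA(ed$position)) {
    stop("consecutive path species must differ at exactly one position",
         call. = FALSE)
  }
  ed$score <- NA_real_
  ed$window_start <- NA_integer_
  ed$window_end <- NA_integer_
  remodeling_network(unique(c(nodes, species_path)), ed)
}

#' Specification of a simulated pulse-chase experiment
#'
#' Declares the ground truth (network and rates), the design (sampling
#' times, replicates) and the noise model of a synthetic pulse-chase
#' experiment. Defaults mirror the design of the BHK21 experiments the
#' package targets: a precursor-loaded initial state chased over 24 h on
#' a 6-point grid with 3 replicates and 10% multiplicative noise.
#'
#' @param true_network A `remodeling_network` carrying the true reactions
#'   (need not be bidirectional: absent reverse reactions have rate 0).
#' @param true_theta Named or ordered non-negative rates (h^-1), one per
#'   edge of `true_network`.
#' @param x0 Initial concentrations named by species; species of the
#'   network missing from `x0` start at 0 (precursor-loaded start).
#' @param times Sampling grid in hours (default `c(0, 1, 2, 4, 8, 24)`).
#' @param n_replicates Replicates per (species, time), default 3.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise, default 0.10; 0 for noiseless data.
#' @param detection_floor Concentrations below this are censored to 0
#'   (default 0, no censoring).
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(true_network, true_theta, x0,
                            times = c(0, 1, 2, 4, 8, 24),
                            n_replicates = 3, noise_cv = 0.10,
                            detection_floor = 0, seed = 1L) {
  stopifnot(inherits(true_network, "remodeling_network"),
            length(true_theta) == nrow(true_network$edges),
            all(true_theta >= 0), all(diff(times) > 0), length(times) >= 3,
            n_replicates >= 1, noise_cv >= 0, detection_floor >= 0,
            !is.null(names(x0)), all(names(x0) %in% true_network$nodes),
            all(x0 >= 0))
  structure(list(true_network = true_network,
                 true_theta = as.numeric(true_theta), x0 = x0,
                 times = as.numeric(times),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a pulse-chase time course with known ground truth
#'
#' Integrates the true linear mass-action system from the precursor-loaded
#' initial state, then draws replicates with multiplicative lognormal
#' noise of the requested CV (mean-one noise, so replicate means converge
#' to the noiseless trajectory) and censors values below the detection
#' floor to 0.
#'
#' @param spec A [simulation_spec()].
#' @return List with `tc` (the noisy [timecourse()]), `truth` (list:
#'   `trajectory` noiseless matrix times x species, `network`, `theta`
#'   named per edge, `x0`, `times`, `seed`).
#' @export
simulate_pulse_chase <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  sys <- build_ode(spec$true_network)
  x0 <- stats::setNames(rep(0, sys$N), sys$species)
  x0[names(spec$x0)] <- spec$x0
  traj <- verify_by_integration(sys, spec$true_theta, x0, spec$times)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  rows <- withr_seed({
    expand <- expand.grid(replicate = seq_len(spec$n_replicates),
                          species = sys$species, time_h = spec$times,
                          stringsAsFactors = FALSE)
    expand$concentration <- traj[cbind(match(expand$time_h, spec$times),
                                       match(expand$species, sys$species))]
    if (spec$noise_cv > 0) {
      noise <- stats::rlnorm(nrow(expand), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      expand$concentration <- expand$concentration * noise
    }
    expand
  })
  rows$concentration[rows$concentration < spec$detection_floor] <- 0

  theta <- spec$true_theta
  names(theta) <- paste(sys$edges$source, sys$edges$target, sep = " -> ")
  list(tc = timecourse(rows[c("species", "time_h", "replicate", "concentration")]),
       truth = list(trajectory = traj, network = spec$true_network,
                    theta = theta, x0 = x0, times = spec$times,
                    seed = spec$seed))
}
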