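two_species_net <- function() {
  bidirectionalize(make_path_network(c("18:3-18:3", "18:1-18:3")))
}

test_that("the compiled vector field is production minus conversion", {
  sys <- build_ode(two_species_net())
  M <- rate_matrix(sys, c(0.3, 0.1))
  # x_A' = -th1 x_A + th2 x_B ; x_B' = th1 x_A - th2 x_B
  expect_equal(unname(M), matrix(c(-0.1, 0.1, 0.3, -0.3), 2, 2),
               ignore_attr = TRUE)

  # isolated species: zero row and column
  net <- remodeling_network(c("18:3-18:3", "18:1-18:3", "16:0-20:4"),
                            two_species_net()$edges)
  M3 <- rate_matrix(build_ode(net), c(0.3, 0.1))
  expect_equal(M3["16:0-20:4", ], setNames(c(0, 0, 0), colnames(M3)))

  # conservation by construction: column sums vanish for any theta
  set.seed(3)
  sysc <- build_ode(bidirectionalize(make_path_network(
    c("14:0-14:0", "18:1-14:0", "18:1-18:1", "18:1-18:2"))))
  for (i in 1:5) {
    expect_equal(colSums(rate_matrix(sysc, runif(sysc$P))),
                 setNames(rep(0, sysc$N), sysc$species), tolerance = 1e-14)
  }

  expect_error(build_ode(remodeling_network("18:3-18:3",
                                            make_path_network(c("18:3-18:3", "18:1-18:3"))$edges[0, ])),
               "empty")
})

test_that("error components match an independent term-by-term summation", {
  sim <- suppressMessages(simulate_pulse_chase(chain3_spec(noise_cv = 0.1, seed = 4)))
  net <- bidirectionalize(make_path_network(c("18:3-18:3", "18:1-18:3", "18:1-18:1")))
  sys <- build_ode(net)
  sp <- spline_model(n_basis = 8, n_collocation = 15)
  set.seed(8)
  theta <- runif(sys$P, 0, 0.5)
  beta <- matrix(rnorm(8 * sys$N, sd = 5), 8, sys$N)
  lambda <- 2.5

  got <- compute_errors(sim$tc, sys, sp, theta, beta, lambda)

  # oracle: explicit loops over species / times / collocation points
  rng <- range(sim$tc$times)
  tau <- seq(rng[1], rng[2], length.out = 15)
  knots <- lipidremodel:::spline_knots(rng, 8, 3)
  Bo <- splines::splineDesign(knots, sim$tc$times, ord = 4)
  Bc <- splines::splineDesign(knots, tau, ord = 4)
  Bd <- splines::splineDesign(knots, tau, ord = 4, derivs = rep(1, 15))
  Y <- lipidremodel:::tc_mean_matrix(sim$tc)[, sys$species]
  M <- rate_matrix(sys, theta)
  E_obs <- 0
  for (i in seq_len(sys$N)) for (h in seq_along(sim$tc$times)) {
    E_obs <- E_obs + (sum(Bo[h, ] * beta[, i]) - as.numeric(Y[h, i]))^2
  }
  E_ode <- 0
  for (c in 1:15) {
    x <- as.numeric(Bc[c, ] %*% beta)
    xd <- as.numeric(Bd[c, ] %*% beta)
    f <- as.numeric(M %*% x)
    E_ode <- E_ode + sum((xd - f)^2)
  }
  expect_equal(got$E_obs, E_obs, tolerance = 1e-10)
  expect_equal(got$E_ode, E_ode, tolerance = 1e-10)
  expect_equal(got$E_total, E_obs + lambda * E_ode, tolerance = 1e-10)

  # lambda = 0 reduces the objective to the observation error
  expect_equal(compute_errors(sim$tc, sys, sp, theta, beta, 0)$E_total,
               got$E_obs, tolerance = 1e-12)
})

test_that("constant data with zero rates is an exact fixed point", {
  m <- matrix(7, nrow = 6, ncol = 2,
              dimnames = list(NULL, c("18:3-18:3", "18:1-18:3")))
  tc <- tc_from_means(m, c(0, 1, 2, 4, 8, 24))
  fit <- fit_dynamics(tc, build_ode(two_species_net()), max_iter = 50)
  expect_equal(fit$errors$E_total, 0, tolerance = 1e-14)
  expect_equal(unname(fit$theta), c(0, 0), tolerance = 1e-8)
})

test_that("each linear subproblem attains the brute-force grid optimum", {
  # one-parameter system: irreversible A -> B
  net1 <- make_path_network(c("18:3-18:3", "18:1-18:3"))
  sim <- suppressMessages(simulate_pulse_chase(simulation_spec(
    net1, 0.3, x0 = c("18:3-18:3" = 100), noise_cv = 0, seed = 1)))
  sys <- build_ode(net1)
  sp <- spline_model()
  d <- lipidremodel:::fit_design(sim$tc, sys, sp)
  beta <- lipidremodel:::init_beta(d, sys, sp)

  th_hat <- lipidremodel:::solve_theta(d, sys, beta)$x
  grid <- seq(0, 1, by = 1e-4)
  E <- vapply(grid, function(th)
    lipidremodel:::errors_from_design(d, sys, th, beta, 1)$E_total, 0)
  th_grid <- grid[which.min(E)]
  expect_equal(signif(th_hat, 3), signif(th_grid, 3))

  # two-parameter system: A <-> B on noiseless equilibration data
  sys2 <- build_ode(two_species_net())
  sim2 <- suppressMessages(simulate_pulse_chase(simulation_spec(
    two_species_net(), c(0.4, 0.1), x0 = c("18:3-18:3" = 100),
    noise_cv = 0, seed = 1)))
  d2 <- lipidremodel:::fit_design(sim2$tc, sys2, sp)
  beta2 <- lipidremodel:::init_beta(d2, sys2, sp)
  th2 <- lipidremodel:::solve_theta(d2, sys2, beta2)$x
  g <- as.matrix(expand.grid(seq(-0.5, 1, by = 5e-3), seq(-0.5, 1, by = 5e-3)))
  E2 <- apply(g, 1, function(th)
    lipidremodel:::errors_from_design(d2, sys2, th, beta2, 1)$E_total)
  coarse <- g[which.min(E2), ]
  # refine around the coarse grid optimum to 3-figure resolution
  g2 <- as.matrix(expand.grid(seq(coarse[1] - 5e-3, coarse[1] + 5e-3, by = 1e-4),
                              seq(coarse[2] - 5e-3, coarse[2] + 5e-3, by = 1e-4)))
  E3 <- apply(g2, 1, function(th)
    lipidremodel:::errors_from_design(d2, sys2, th, beta2, 1)$E_total)
  fine <- g2[which.min(E3), ]
  g3 <- as.matrix(expand.grid(seq(fine[1] - 2e-4, fine[1] + 2e-4, by = 1e-5),
                              seq(fine[2] - 2e-4, fine[2] + 2e-4, by = 1e-5)))
  E4 <- apply(g3, 1, function(th)
    lipidremodel:::errors_from_design(d2, sys2, th, beta2, 1)$E_total)
  expect_equal(signif(th2, 3), signif(unname(g3[which.min(E4), ]), 3))
})

test_that("noiseless cascade rates are recovered within 10 percent", {
  sim <- suppressMessages(simulate_pulse_chase(chain3_spec(noise_cv = 0)))
  net <- suppressMessages(bidirectionalize(infer_network(sim$tc)))
  fit <- fit_dynamics(sim$tc, build_ode(net), max_iter = 800)
  expect_lt(abs(fit$theta[["18:3-18:3 -> 18:1-18:3"]] - 0.25) / 0.25, 0.10)
  expect_lt(abs(fit$theta[["18:1-18:3 -> 18:1-18:1"]] - 0.05) / 0.05, 0.10)
})

test_that("with 10 percent noise the dominant rates stay within 30 percent", {
  sim <- suppressMessages(simulate_pulse_chase(chain3_spec(noise_cv = 0.10, seed = 42)))
  net <- suppressMessages(bidirectionalize(infer_network(sim$tc)))
  fit <- fit_dynamics(sim$tc, build_ode(net), max_iter = 800)
  expect_lt(abs(fit$theta[["18:3-18:3 -> 18:1-18:3"]] - 0.25) / 0.25, 0.30)
  expect_lt(abs(fit$theta[["18:1-18:3 -> 18:1-18:1"]] - 0.05) / 0.05, 0.30)
})

test_that("integration verifies closed forms and conserves mass", {
  sys <- build_ode(two_species_net())
  # zero rates: trajectories constant at x0
  traj <- verify_by_integration(sys, c(0, 0), c("18:3-18:3" = 4, "18:1-18:3" = 6),
                                times = c(0, 5, 10))
  expect_equal(traj[, "18:3-18:3"], rep(4, 3), tolerance = 1e-10)

  # symmetric exchange equilibrates to the average
  traj <- verify_by_integration(sys, c(0.5, 0.5),
                                c("18:3-18:3" = 10, "18:1-18:3" = 0),
                                times = c(0, 50))
  expect_equal(unname(traj[2, ]), c(5, 5), tolerance = 1e-6)

  # irreversible conversion follows the analytic exponential
  net1 <- make_path_network(c("18:3-18:3", "18:1-18:3"))
  k <- 0.23
  tt <- c(0, 1, 2, 4, 8, 24)
  traj <- verify_by_integration(build_ode(net1), k,
                                c("18:3-18:3" = 100, "18:1-18:3" = 0), tt)
  expect_equal(traj[, "18:3-18:3"], 100 * exp(-k * tt), tolerance = 1e-6)

  # mass conservation along the trajectory
  sim <- suppressMessages(simulate_pulse_chase(cascade6_spec(noise_cv = 0)))
  totals <- rowSums(sim$truth$trajectory)
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-8)
})

test_that("the fitted spline agrees with independent integration of its rates", {
  sim <- suppressMessages(simulate_pulse_chase(chain3_spec(noise_cv = 0)))
  net <- suppressMessages(bidirectionalize(infer_network(sim$tc)))
  fit <- fit_dynamics(sim$tc, build_ode(net), max_iter = 800)
  spl <- fitted_trajectory(fit, sim$tc$times)
  x0 <- spl[1, ]
  ode <- verify_by_integration(fit$sys, fit$theta, pmax(x0, 0), sim$tc$times)
  expect_lt(max(abs(spl - ode)), 1.0)  # absolute units on a 100-unit scale
})

test_that("rate estimates are stable across lambda over two orders of magnitude", {
  sim <- suppressMessages(simulate_pulse_chase(cascade6_spec(seed = 1)))
  net <- suppressMessages(bidirectionalize(infer_network(sim$tc)))
  sys <- build_ode(net)
  k <- vapply(c(0.1, 1, 10), function(li)
    fit_dynamics(sim$tc, sys, lambda = li, max_iter = 600)$theta[["14:0-14:0 -> 18:1-14:0"]],
    0)
  expect_lt((max(k) - min(k)) / mean(k), 0.25)
})
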