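test_that("source detection flags significantly decreasing species", {
  reps <- function(sp, t0, t1, t2) {
    data.frame(species = sp, time_h = rep(c(0, 1, 2), each = 3),
               replicate = rep(1:3, 3), concentration = c(t0, t1, t2))
  }
  tc <- timecourse(rbind(
    reps("18:3-18:3", c(10, 10.2, 9.8), c(5, 5.1, 4.9), c(2, 2, 2)),
    reps("18:1-18:3", c(5, 5.1, 4.9), c(5, 5.2, 4.8), c(5, 5, 5))))
  expect_equal(detect_sources(tc, 1, alpha = 0.3), "18:3-18:3")
  # constant series is never a source
  expect_false("18:1-18:3" %in% detect_sources(tc, 1, alpha = 0.3))
})

test_that("source detection over many species matches per-species t-tests", {
  # brute-force oracle: apply stats::t.test to each species directly
  set.seed(5)
  chains <- c("14:0", "14:1", "18:0", "18:1", "18:3", "22:6")
  species <- paste("18:0", chains, sep = "-")
  times <- c(0, 2, 6)
  df <- expand.grid(species = species, time_h = times, replicate = 1:3,
                    stringsAsFactors = FALSE)
  base <- setNames(runif(6, 5, 20), species)
  slope <- setNames(runif(6, -2, 1), species)
  df$concentration <- pmax(0.1, base[df$species] + slope[df$species] * df$time_h +
                             rnorm(nrow(df), sd = 0.3))
  tc <- timecourse(df)
  got <- detect_sources(tc, 1, alpha = 0.3)
  want <- Filter(function(sp) {
    x <- df$concentration[df$species == sp & df$time_h == 0]
    y <- df$concentration[df$species == sp & df$time_h == 2]
    t.test(x, y, alternative = "greater")$p.value < 0.3
  }, species)
  expect_setequal(got, want)
})

test_that("degenerate replicate structure falls back to the mean-decrease rule", {
  df <- expand.grid(species = c("18:3-18:3", "18:1-18:3"),
                    time_h = c(0, 1, 2), replicate = 1L,
                    stringsAsFactors = FALSE)
  df$concentration <- c(10, 5, 8, 5, 2, 5)
  tc <- timecourse(df)
  expect_message(src <- detect_sources(tc, 1, alpha = 0.3),
                 "mean-decrease rule")
  expect_setequal(src, "18:3-18:3")
})

test_that("neighborhood returns exactly the single-position partners", {
  obs <- c("18:3-18:3", "18:1-18:3", "18:3-18:1", "18:1-18:1", "16:0-20:4")
  expect_setequal(neighborhood("18:3-18:3", obs), c("18:1-18:3", "18:3-18:1"))
  expect_length(neighborhood("16:0-20:4", obs), 0)
  # full 3x3 grid: each corner species has (3-1) + (3-1) = 4 neighbours
  grid <- make_species_grid(c("14:0", "16:0", "18:1"), c("18:1", "18:2", "22:6"))
  expect_length(grid, 9)
  for (corner in c("14:0-18:1", "18:1-22:6")) {
    expect_length(neighborhood(corner, grid), 4)
  }
})

test_that("edge scores capture inverse co-variation with the sign guard", {
  times <- c(0, 2, 4)
  m <- cbind("18:3-18:3" = c(10, 6, 2), "18:1-18:3" = c(0, 4, 8),
             "18:3-18:1" = c(8, 4, 0), "18:1-18:1" = c(3, 3, 3))
  tc <- tc_from_means(m, times)
  # source falls while target rises: perfect score
  expect_equal(edge_score("18:3-18:3", "18:1-18:3", tc, c(1, 3)), 1.0)
  # co-decreasing target never increases: guard forces score <= 0
  expect_lte(edge_score("18:3-18:3", "18:3-18:1", tc, c(1, 3)), 0)
  # flat target: zero variance scores 0, never NaN
  expect_equal(suppressMessages(edge_score("18:3-18:3", "18:1-18:1", tc, c(1, 3))), 0)
})

test_that("edge score equals the negated Pearson correlation oracle", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(5, 0, 10)
    b <- runif(5, 0, 10)
    m <- cbind("18:3-18:3" = a, "18:1-18:3" = b)
    tc <- tc_from_means(m, c(0, 1, 2, 4, 8))
    raw <- -cor(a, b)
    want <- if (all(diff(b) <= 0)) -abs(raw) else raw
    expect_equal(edge_score("18:3-18:3", "18:1-18:3", tc, c(1, 5)), want,
                 tolerance = 1e-12)
  }
})

test_that("a synthetic conversion chain is recovered exactly and cleanly", {
  sim <- suppressMessages(simulate_pulse_chase(chain3_spec(noise_cv = 0)))
  net <- suppressMessages(infer_network(sim$tc))
  got <- paste(net$edges$source, net$edges$target, sep = " -> ")
  expect_true("18:3-18:3 -> 18:1-18:3" %in% got)
  expect_true("18:1-18:3 -> 18:1-18:1" %in% got)
  # A and C differ at both positions: no edge can ever join them
  expect_false(any(grepl("18:3-18:3 -> 18:1-18:1", got)))
  expect_false(any(grepl("18:1-18:1 -> 18:3-18:3", got)))
  # no spurious reverse edges on noiseless monotone data
  expect_equal(nrow(net$edges), 2)
})

test_that("every inferred edge joins species differing at one position", {
  sim <- suppressMessages(simulate_pulse_chase(cascade6_spec(seed = 9)))
  net <- suppressMessages(infer_network(sim$tc))
  expect_gt(nrow(net$edges), 0)
  pos <- mapply(differs_at_one_position, net$edges$source, net$edges$target)
  expect_false(anyNA(pos))
  expect_identical(unname(pos), net$edges$position)
})

test_that("constant concentrations yield an empty network with a warning", {
  m <- matrix(5, nrow = 4, ncol = 2,
              dimnames = list(NULL, c("18:3-18:3", "18:1-18:3")))
  tc <- tc_from_means(m, c(0, 1, 2, 4))
  expect_warning(net <- suppressMessages(infer_network(tc)), "no species passed")
  expect_equal(nrow(net$edges), 0)
})

test_that("edge count is non-increasing as the correlation threshold rises", {
  sim <- suppressMessages(simulate_pulse_chase(cascade6_spec(seed = 2)))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(thr) {
    cfg <- inference_config(corr_threshold = thr)
    nrow(suppressMessages(suppressWarnings(infer_network(sim$tc, cfg)))$edges)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("bidirectionalization adds reverses, is idempotent, doubles a path", {
  net <- make_path_network(c("18:3-18:3", "18:1-18:3"))
  b <- bidirectionalize(net)
  expect_equal(nrow(b$edges), 2)
  expect_true(any(b$edges$source == "18:1-18:3" & b$edges$target == "18:3-18:3"))
  # reverse edges carry score 0 and the forward window
  rev <- b$edges[which(b$edges$score == 0), ]
  expect_equal(rev$window_start, net$edges$window_start)
  expect_identical(bidirectionalize(b)$edges, b$edges)

  # a 6-forward-edge network becomes 12 directed edges
  grid <- make_species_grid(c("18:3", "18:1"), c("18:3", "18:1"))
  p1 <- make_path_network(c("18:3-18:3", "18:1-18:3", "18:1-18:1"))
  p2 <- make_path_network(c("18:3-18:3", "18:3-18:1", "18:1-18:1"))
  p3 <- make_path_network(c("18:1-18:1", "18:0-18:1", "18:0-18:2"))
  net6 <- remodeling_network(c(grid, "18:0-18:1", "18:0-18:2"),
                             rbind(p1$edges, p2$edges, p3$edges))
  expect_equal(nrow(net6$edges), 6)
  expect_equal(nrow(bidirectionalize(net6)$edges), 12)
})

test_that("the full single-position network has the predicted edge count", {
  # n1 x n2 grid: each species has (n1 - 1) + (n2 - 1) single-position partners
  grid <- make_species_grid(c("14:0", "16:0", "18:1"),
                            c("18:1", "18:2", "20:4", "22:6"))
  fn <- full_network(grid)
  expect_equal(nrow(fn$edges), 12 * (2 + 3))
})
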