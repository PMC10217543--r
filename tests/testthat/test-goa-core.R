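test_that("social force has the analytic root, sign structure, and decay", {
  # closed form: f * exp(-r/l) = exp(-r) at r = 3 * log(2) for f = 0.5, l = 1.5
  root <- 3 * log(2)
  expect_lt(abs(social_force(root, f = 0.5, l = 1.5)), 1e-12)
  expect_equal(social_force(0, f = 0.5, l = 1.5), -0.5)

  # repulsion below the comfort distance, attraction above, decay to zero
  below <- seq(0.01, root - 0.01, length.out = 50)
  above <- seq(root + 0.01, 12, length.out = 50)
  expect_true(all(social_force(below) < 0))
  expect_true(all(social_force(above) > 0))
  expect_lt(abs(social_force(15)), 1e-3)

  expect_error(social_force(-0.1), "non-negative")
})

test_that("social force peaks where the dense-grid oracle says", {
  # independent oracle: evaluate the closed-form expression on a 1e-5 grid
  grid <- seq(1e-5, 10, by = 1e-5)
  oracle_vals <- 0.5 * exp(-grid / 1.5) - exp(-grid)
  oracle_argmax <- grid[which.max(oracle_vals)]
  # exact argmax is 3 * log(3), with maximum value 1/54
  expect_equal(oracle_argmax, 3 * log(3), tolerance = 1e-4)

  opt <- stats::optimize(function(r) social_force(r), c(0, 10), maximum = TRUE)
  expect_equal(opt$maximum, oracle_argmax, tolerance = 1e-4)
  expect_equal(opt$objective, 1 / 54, tolerance = 1e-10)
  expect_equal(social_force(3.2958), 1 / 54, tolerance = 1e-6)
})

test_that("comfort coefficient is the exact linear schedule", {
  cfg <- goa_config(lower = 0, upper = 1, dim = 3, n_iter = 80)
  expect_identical(comfort_coefficient(0, cfg), cfg$c_max)
  expect_identical(comfort_coefficient(80, cfg), cfg$c_min)
  expect_equal(comfort_coefficient(40, cfg), 0.500005)

  cs <- vapply(0:80, comfort_coefficient, numeric(1), cfg = cfg)
  expect_true(all(diff(cs) < 0))

  expect_error(comfort_coefficient(81, cfg), "\\[0, 80\\]")
  expect_error(comfort_coefficient(-1, cfg), "iteration")
})

test_that("distance mapping hits the range endpoints and the degenerate rule", {
  expect_equal(map_distance(0.3, 0.3, 2.1), 1)
  expect_equal(map_distance(2.1, 0.3, 2.1), 4)
  expect_equal(map_distance(1.2, 0.3, 2.1), 1 + 3 * (1.2 - 0.3) / 1.8)
  # all pairwise distances identical -> midpoint
  expect_equal(map_distance(0.7, 0.7, 0.7), 2.5)
  expect_equal(map_distance(c(1, 1), 1, 1 + 1e-15), c(2.5, 2.5))
})

test_that("a lone grasshopper is moved onto the target", {
  cfg <- goa_config(lower = -2, upper = 2, dim = 3, n_pop = 1, n_iter = 5)
  state <- list(positions = matrix(c(1, -1, 0.5), 1, 3),
                fitness = 3, target_position = c(0.2, 0.1, -0.3),
                target_fitness = 0.14, iteration = 0L)
  out <- update_positions(state, 0.5, cfg, function(x) sum(x^2))
  expect_equal(out$positions[1, ], state$target_position)
})

test_that("symmetric pair updates mirror about the target in 1-D", {
  cfg <- goa_config(lower = -5, upper = 5, dim = 1, n_pop = 2, n_iter = 10)
  t0 <- 0.7
  a <- 1.2
  state <- list(positions = matrix(c(t0 + a, t0 - a), 2, 1),
                fitness = c((a)^2, (a)^2),
                target_position = t0, target_fitness = 0,
                iteration = 0L)
  c_coef <- 0.3
  out <- update_positions(state, c_coef, cfg, function(x) (x - t0)^2)

  # hand evaluation: single pairwise distance -> degenerate map to 2.5,
  # s = 0.5 exp(-2.5/1.5) - exp(-2.5); each grasshopper lands at
  # target -/+ c^2 * (span/2) * s along its inward unit vector
  s <- 0.5 * exp(-2.5 / 1.5) - exp(-2.5)
  dev <- c_coef^2 * 5 * s
  expect_equal(out$positions[1, 1], t0 - dev)
  expect_equal(out$positions[2, 1], t0 + dev)
  expect_equal(out$positions[1, 1] - t0, -(out$positions[2, 1] - t0))
})

test_that("positions stay inside the box at every iteration", {
  cfg <- goa_config(lower = c(-1, 0), upper = c(1, 3), dim = 2,
                    n_pop = 12, n_iter = 15, seed = 4)
  set.seed(4)
  state <- goa_init(cfg, function(x) sum(abs(x)))
  for (it in seq_len(cfg$n_iter)) {
    state <- update_positions(state, comfort_coefficient(it, cfg), cfg,
                              function(x) sum(abs(x)))
    expect_true(all(state$positions[, 1] >= -1 & state$positions[, 1] <= 1))
    expect_true(all(state$positions[, 2] >= 0 & state$positions[, 2] <= 3))
  }
})

test_that("coincident grasshoppers are separated without division by zero", {
  cfg <- goa_config(lower = -1, upper = 1, dim = 2, n_pop = 3, n_iter = 5,
                    seed = 9)
  pos <- matrix(c(0.5, 0.5, 0.5, 0.5, -0.2, 0.1), 3, 2, byrow = TRUE)
  state <- list(positions = pos, fitness = rowSums(pos^2),
                target_position = c(-0.2, 0.1), target_fitness = 0.05,
                iteration = 0L)
  set.seed(9)
  out <- update_positions(state, 0.8, cfg, function(x) sum(x^2))
  expect_true(all(is.finite(out$positions)))
})

test_that("optimize keeps its trace, bookkeeping, and determinism contracts", {
  cfg <- goa_config(lower = -10, upper = 10, dim = 4, n_pop = 12,
                    n_iter = 25, seed = 7)
  sphere <- function(x) sum(x^2)
  res <- goa_optimize(sphere, cfg)
  expect_length(res$trace, cfg$n_iter + 1L)
  expect_true(all(diff(res$trace) <= 0))
  expect_equal(res$best_fitness, res$trace[length(res$trace)])
  expect_equal(sphere(res$best_position), res$best_fitness)

  # bitwise-identical repeat under the same seed
  res2 <- goa_optimize(sphere, cfg)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_position, res2$best_position)

  # a pathological constant objective keeps the best-so-far flat
  flat <- goa_optimize(function(x) 1, cfg)
  expect_true(all(flat$trace == 1))

  expect_error(
    goa_optimize(function(x) if (x[1] > -Inf) NaN else 0, cfg),
    "non-finite"
  )
})

test_that("config validation rejects inconsistent settings", {
  expect_error(goa_config(lower = 1, upper = 0, dim = 2), "strictly below")
  expect_error(goa_config(lower = 0, upper = 1, dim = 2, c_max = 0.1,
                          c_min = 0.2), "c_max")
  expect_error(goa_config(lower = 0, upper = 1, dim = 2, f = -1), "f")
  expect_error(goa_config(lower = 0, upper = 1, dim = 2,
                          distance_map_range = c(4, 1)), "increasing")
})
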