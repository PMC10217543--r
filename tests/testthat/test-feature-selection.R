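test_that("thresholding, ties, and the keep-argmax repair rule", {
  expect_identical(binarize(c(0.9, 0.1, 0.7)), c(1L, 0L, 1L))
  expect_identical(binarize(c(0.2, 0.4, 0.1)), c(0L, 1L, 0L))
  expect_identical(binarize(c(0.5, 0.5)), c(1L, 1L))  # boundary selects
  expect_error(binarize(c(0.2, NA)), "finite")
})

test_that("fitness combines error and feature fraction as a convex sum", {
  tab <- fixtures$separable
  d <- ncol(tab$values)
  spec <- fitness_spec(seed = 7)

  # zero cross-validated error with the full mask leaves only the
  # feature-fraction term: 0.99 * 0 + 0.01 * 1
  expect_equal(mask_fitness(rep(1L, d), tab, spec), 0.01)

  # affine in alpha: the slope of f(alpha) is (error - fraction), so the
  # error recovered from two alphas must predict a third exactly
  mask <- c(rep(1L, 5), rep(0L, d - 5))
  f <- function(a) mask_fitness(mask, tab, fitness_spec(alpha = a, seed = 7))
  frac <- sum(mask) / d
  err <- (f(0.8) - f(0.2)) / 0.6 + frac
  expect_equal(f(0.5), 0.5 * err + 0.5 * frac, tolerance = 1e-12)

  # limits: alpha -> 1 gives the CV error, alpha -> 0 the feature fraction
  expect_equal(mask_fitness(mask, tab, fitness_spec(alpha = 1 - 1e-9,
                                                    seed = 7)),
               err, tolerance = 1e-6)
  expect_equal(mask_fitness(mask, tab, fitness_spec(alpha = 1e-9, seed = 7)),
               frac, tolerance = 1e-6)

  # the recovered error matches the pooled evaluation route independently
  ev <- train_eval(tab, mask = mask, classifier = "svm", seed = 7)
  expect_equal(err, 1 - ev$metrics$accuracy / 100, tolerance = 1e-12)
})

test_that("fitness input contracts", {
  tab <- fixtures$tiny
  expect_error(mask_fitness(rep(0L, 6), tab), "zero features")
  expect_error(mask_fitness(rep(1L, 5), tab), "length")
  single <- feature_table(tab$values, rep("benign", nrow(tab$values)))
  expect_error(mask_fitness(rep(1L, 6), single), "single class")
  expect_error(fitness_spec(alpha = 1), "strictly between")
})

test_that("selection reaches the exhaustive optimum region on the tiny table", {
  tab <- fixtures$tiny
  spec <- fitness_spec(seed = 99)
  oracle <- enumerate_masks(tab, spec)
  for (s in 1:3) {
    res <- select_features(tab, goa = goa_config(0, 1, dim = 6, seed = s),
                           spec = spec)
    expect_lte(res$final_fitness, oracle$best_fitness * 1.05)
    expect_equal(res$final_fitness, mask_fitness(res$mask, tab, spec),
                 tolerance = 1e-12)
  }
})

test_that("selection result keeps its trace and determinism contracts", {
  tab <- fixtures$tiny
  g <- quick_goa(6, seed = 2)
  res <- select_features(tab, goa = g, spec = fitness_spec(seed = 2))
  expect_length(res$fitness_trace, g$n_iter + 1L)
  expect_true(all(diff(res$fitness_trace) <= 0))
  expect_identical(res$final_fitness,
                   res$fitness_trace[length(res$fitness_trace)])
  expect_gte(res$selected_count, 1L)

  res2 <- select_features(tab, goa = g, spec = fitness_spec(seed = 2))
  expect_identical(res$mask, res2$mask)
  expect_identical(res$fitness_trace, res2$fitness_trace)
})

test_that("a single perfectly separating column is found and kept minimal", {
  tab <- fixtures$single
  res <- select_features(tab, goa = goa_config(0, 1, dim = 10, seed = 3),
                         spec = fitness_spec(seed = 3))
  # perfect subset: fitness collapses to the feature-fraction floor
  expect_lte(res$final_fitness, 0.01 * (1 / 10) + 1e-9)
  expect_identical(res$mask, tab$informative)
})

test_that("informative-column recovery beats random masks of the same size", {
  tab <- fixtures$noisy
  truth <- tab$informative
  runs <- lapply(11:15, function(s) {
    select_features(tab, spec = fitness_spec(seed = s),
                    goa = goa_config(0, 1, dim = 20, n_pop = 20, n_iter = 40,
                                     seed = s))
  })
  sizes <- vapply(runs, function(r) sum(r$mask), integer(1))
  hits <- vapply(runs, function(r) sum(r$mask == 1L & truth == 1L), integer(1))
  expect_true(all(hits >= 3))

  # Monte-Carlo null: masks of the observed sizes drawn uniformly at random
  set.seed(1)
  null_total <- replicate(20000, sum(stats::rhyper(length(sizes), 5, 15,
                                                   sizes)))
  p <- mean(null_total >= sum(hits))
  expect_lt(p, 0.01)
})

test_that("selection results serialize to JSON with full provenance", {
  tab <- fixtures$tiny
  res <- select_features(tab, goa = quick_goa(6, seed = 5),
                         spec = fitness_spec(seed = 5))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_selection(res, path)
  doc <- jsonlite::read_json(path)
  expect_identical(doc$mask, paste(res$mask, collapse = ""))
  expect_equal(doc$final_fitness, res$final_fitness)
  expect_length(doc$fitness_trace, length(res$fitness_trace))
  expect_identical(doc$fitness$seed, 5L)
})
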