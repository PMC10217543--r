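# Grasshopper optimization algorithm: social force, comfort-coefficient
# schedule, swarm position update, and the outer optimization loop.

#' Configuration for the grasshopper optimizer
#'
#' Collects every tunable of the grasshopper optimization algorithm (GOA):
#' swarm size, iteration budget, the social-force shape parameters, the
#' comfort-coefficient schedule, and the search box.
#'
#' @param lower,upper Numeric vectors of per-dimension bounds. Scalars are
#'   recycled to a common length; the common length is the problem dimension.
#' @param n_pop Population size N (grasshoppers in the swarm). `n_pop = 1`
#'   degenerates to repeated target copying and is allowed.
#' @param n_iter Iteration budget L of the outer loop.
#' @param f Attraction intensity of the social force (default 0.5).
#' @param l Attractive length scale of the social force (default 1.5).
#' @param c_max,c_min Endpoints of the linearly decaying comfort coefficient;
#'   `c_max > c_min > 0`.
#' @param distance_map_range Interval onto which pairwise swarm distances are
#'   affinely mapped before entering the social force (default `c(1, 4)`),
#'   keeping the force out of its flat long-range tail.
#' @param epsilon_distance Distance below which two grasshoppers are treated
#'   as coincident; their interaction direction is then drawn as a seeded
#'   random unit vector instead of dividing by a vanishing norm.
#' @param seed Integer seed; all randomness in [goa_optimize()] flows from it.
#' @param gravity_g,wind_u Accepted for completeness with the full swarm
#'   model (gravity magnitude and wind drift); the production position update
#'   is the target-guided social-interaction dynamics, which does not use
#'   them. They are stored untouched.
#'
#' @return An object of class `goa_config`.
#' @seealso [goa_optimize()], [social_force()], [comfort_coefficient()]
#' @examples
#' cfg <- goa_config(lower = -10, upper = 10, dim = 5)
#' cfg$n_pop
#' @param dim Problem dimension, used to recycle scalar bounds.
#' @export
goa_config <- function(lower, upper, dim = max(length(lower), length(upper)),
                       n_pop = 25L, n_iter = 80L, f = 0.5, l = 1.5,
                       c_max = 1, c_min = 1e-5,
                       distance_map_range = c(1, 4),
                       epsilon_distance = 1e-12, seed = 1L,
                       gravity_g = NULL, wind_u = NULL) {
  assert_scalar_num(dim, "dim", lower = 1, strict = FALSE)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("each lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  assert_scalar_num(n_pop, "n_pop", lower = 1)
  assert_scalar_num(n_iter, "n_iter", lower = 1)
  assert_scalar_num(f, "f", lower = 0, strict = TRUE)
  assert_scalar_num(l, "l", lower = 0, strict = TRUE)
  assert_scalar_num(c_min, "c_min", lower = 0, strict = TRUE)
  assert_scalar_num(c_max, "c_max", lower = c_min, strict = TRUE)
  if (length(distance_map_range) != 2L ||
      distance_map_range[1] >= distance_map_range[2]) {
    stop("`distance_map_range` must be an increasing pair", call. = FALSE)
  }
  assert_scalar_num(epsilon_distance, "epsilon_distance", lower = 0,
                    strict = TRUE)
  structure(
    list(
      lower = lower, upper = upper, dim = as.integer(dim),
      n_pop = as.integer(n_pop), n_iter = as.integer(n_iter),
      f = f, l = l, c_max = c_max, c_min = c_min,
      distance_map_range = as.numeric(distance_map_range),
      epsilon_distance = epsilon_distance, seed = as.integer(seed),
      gravity_g = gravity_g, wind_u = wind_u
    ),
    class = "goa_config"
  )
}

#' @export
print.goa_config <- function(x, ...) {
  cat("Grasshopper optimizer configuration\n")
  cat(sprintf("  dimension: %d, population: %d, iterations: %d\n",
              x$dim, x$n_pop, x$n_iter))
  cat(sprintf("  social force: f = %g, l = %g\n", x$f, x$l))
  cat(sprintf("  comfort coefficient: %g -> %g (linear)\n", x$c_max, x$c_min))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Grasshopper social force
#'
#' Signed pairwise interaction strength
#' `S(r) = f * exp(-r / l) - exp(-r)`: repulsive (negative) at short range,
#' zero at the comfort distance, attractive at medium range, and vanishing as
#' `r` grows. With the default shape `f = 0.5, l = 1.5` the comfort distance
#' is `3 * log(2)`, about 2.079.
#'
#' @param r Non-negative distance(s).
#' @param f Attraction intensity (> 0).
#' @param l Attractive length scale (> 0).
#' @return Numeric vector of force values, same length as `r`.
#' @examples
#' social_force(3 * log(2))   # ~0: the comfort distance
#' social_force(0)            # f - 1 = -0.5: maximal repulsion
#' @export
social_force <- function(r, f = 0.5, l = 1.5) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("`r` must be non-negative and finite", call. = FALSE)
  }
  assert_scalar_num(f, "f", lower = 0, strict = TRUE)
  assert_scalar_num(l, "l", lower = 0, strict = TRUE)
  f * exp(-r / l) - exp(-r)
}

#' Comfort coefficient schedule
#'
#' Linearly decaying coefficient
#' `c = c_max - iteration * (c_max - c_min) / n_iter` that contracts the
#' swarm's comfort zone over the run, trading exploration for exploitation.
#' Both endpoints are exact: iteration 0 gives `c_max`, iteration `n_iter`
#' gives `c_min`.
#'
#' @param iteration Current iteration index, in `[0, n_iter]`.
#' @param cfg A [goa_config()].
#' @return The coefficient value, a single number.
#' @export
comfort_coefficient <- function(iteration, cfg) {
  assert_scalar_num(iteration, "iteration", lower = 0)
  if (iteration > cfg$n_iter) {
    stop(sprintf("`iteration` must lie in [0, %d]", cfg$n_iter), call. = FALSE)
  }
  # convex-combination form so both endpoints are exact in floating point
  t <- iteration / cfg$n_iter
  cfg$c_max * (1 - t) + cfg$c_min * t
}

#' Map pairwise distances into the social force's responsive range
#'
#' The social force saturates toward zero past distances of about 10, so raw
#' swarm distances are affinely rescaled each iteration onto a fixed interval
#' (default `[1, 4]`) where the force still discriminates. When every pairwise
#' distance is identical the map is undefined and the interval midpoint is
#' returned.
#'
#' @param d Distance(s) to map.
#' @param d_min,d_max The swarm's current minimum and maximum pairwise
#'   distances.
#' @param range Target interval, default `c(1, 4)`.
#' @return Mapped distance(s).
#' @export
map_distance <- function(d, d_min, d_max, range = c(1, 4)) {
  if (d_max < d_min) stop("`d_max` must be >= `d_min`", call. = FALSE)
  span <- d_max - d_min
  if (span <= 1e-12 * max(1, abs(d_max))) {
    return(rep(mean(range), length(d)))
  }
  range[1] + (range[2] - range[1]) * (d - d_min) / span
}

# One swarm update step: the c-scaled pairwise social sum plus the best-so-far
# target, clamped to the box. Consumes the caller's RNG stream only when two
# grasshoppers coincide (random interaction direction).
#' Advance the swarm one iteration
#'
#' Applies the target-guided social-interaction update: each grasshopper moves
#' to `c * sum_j c * (ub - lb) / 2 * S(mapped d_ij) * unit(x_j - x_i)` plus
#' the best-so-far target, clamped per dimension to the search box. Fitness is
#' re-evaluated and the target updated, so the target fitness never increases.
#'
#' @param state Swarm state as returned by [goa_init()] or a previous call:
#'   a list with `positions`, `fitness`, `target_position`, `target_fitness`,
#'   `iteration`.
#' @param c_coef Comfort coefficient for this iteration.
#' @param cfg A [goa_config()].
#' @param objective Function mapping a position vector to a finite scalar.
#' @return The updated swarm state.
#' @export
update_positions <- function(state, c_coef, cfg, objective) {
  X <- state$positions
  n <- nrow(X)
  d <- ncol(X)
  half_span <- (cfg$upper - cfg$lower) / 2
  new_x <- matrix(state$target_position, nrow = n, ncol = d, byrow = TRUE)

  if (n >= 2L) {
    dm <- as.matrix(stats::dist(X))
    off <- dm[upper.tri(dm)]
    d_min <- min(off)
    d_max <- max(off)
    for (i in seq_len(n)) {
      total <- numeric(d)
      for (j in seq_len(n)) {
        if (j == i) next
        dij <- dm[i, j]
        if (dij < cfg$epsilon_distance) {
          u <- stats::rnorm(d)
          u <- u / sqrt(sum(u^2))
        } else {
          u <- (X[j, ] - X[i, ]) / dij
        }
        s_val <- social_force(map_distance(dij, d_min, d_max,
                                           cfg$distance_map_range),
                              cfg$f, cfg$l)
        total <- total + c_coef * half_span * s_val * u
      }
      new_x[i, ] <- c_coef * total + state$target_position
    }
  }

  new_x <- pmin(pmax(new_x, matrix(cfg$lower, n, d, byrow = TRUE)),
                matrix(cfg$upper, n, d, byrow = TRUE))
  fit <- eval_swarm(new_x, objective)

  best <- which.min(fit)
  state$positions <- new_x
  state$fitness <- fit
  if (fit[best] < state$target_fitness) {
    state$target_fitness <- fit[best]
    state$target_position <- new_x[best, ]
  }
  state$iteration <- state$iteration + 1L
  state
}

# Evaluate the objective on every row, aborting with the offending position
# if a non-finite value comes back.
eval_swarm <- function(X, objective) {
  fit <- vapply(seq_len(nrow(X)), function(i) {
    v <- objective(X[i, ])
    if (!is.numeric(v) || length(v) != 1L) {
      stop("objective must return a single number", call. = FALSE)
    }
    v
  }, numeric(1))
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1]
    stop(sprintf(
      "objective returned a non-finite value (%s) at position [%s]",
      format(fit[bad]), paste(signif(X[bad, ], 6), collapse = ", ")
    ), call. = FALSE)
  }
  fit
}

#' Initialize a swarm uniformly in the search box
#'
#' @param cfg A [goa_config()].
#' @param objective Objective function.
#' @return A swarm state list. Consumes the caller's RNG stream.
#' @keywords internal
#' @export
goa_init <- function(cfg, objective) {
  X <- matrix(stats::runif(cfg$n_pop * cfg$dim), cfg$n_pop, cfg$dim)
  X <- sweep(sweep(X, 2, cfg$upper - cfg$lower, `*`), 2, cfg$lower, `+`)
  fit <- eval_swarm(X, objective)
  best <- which.min(fit)
  list(
    positions = X, fitness = fit,
    target_position = X[best, ], target_fitness = fit[best],
    iteration = 0L
  )
}

#' Run the grasshopper optimizer
#'
#' Initializes the swarm uniformly inside the search box, then iterates the
#' comfort-coefficient schedule and the social-interaction position update for
#' `n_iter` iterations, tracking the best-so-far target. The whole run is
#' driven by `cfg$seed`: the seed is consumed in a fixed order
#' (initialization first, then any coincident-pair direction draws in swarm
#' order), so identical seed and configuration reproduce the run exactly.
#'
#' @param objective Function mapping an in-box numeric vector to a finite
#'   scalar to be minimized.
#' @param cfg A [goa_config()].
#' @return An object of class `goa_result`: a list with `best_position`,
#'   `best_fitness`, `trace` (length `n_iter + 1`, the best fitness after
#'   initialization and after each iteration; non-increasing), and `config`.
#' @examples
#' cfg <- goa_config(lower = -10, upper = 10, dim = 2, n_pop = 10,
#'                   n_iter = 20, seed = 42)
#' res <- goa_optimize(function(x) sum(x^2), cfg)
#' res$best_fitness
#' @export
goa_optimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "goa_config"))
  with_seed(cfg$seed, {
    state <- goa_init(cfg, objective)
    trace <- numeric(cfg$n_iter + 1L)
    trace[1L] <- state$target_fitness
    for (it in seq_len(cfg$n_iter)) {
      c_coef <- comfort_coefficient(it, cfg)
      state <- update_positions(state, c_coef, cfg, objective)
      trace[it + 1L] <- state$target_fitness
    }
    structure(
      list(
        best_position = state$target_position,
        best_fitness = state$target_fitness,
        trace = trace,
        config = cfg
      ),
      class = "goa_result"
    )
  })
}

#' @export
print.goa_result <- function(x, ...) {
  cat("Grasshopper optimization result\n")
  cat(sprintf("  best fitness: %g after %d iterations\n",
              x$best_fitness, length(x$trace) - 1L))
  cat(sprintf("  initial best: %g\n", x$trace[1]))
  invisible(x)
}

#' Write a fitness trace as two-column delimited text
#'
#' @param trace Numeric vector of best fitness per iteration (a `goa_result`
#'   or `selection_result` `trace`/`fitness_trace`), or either result object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "goa_result")) trace <- trace$trace
  if (inherits(trace, "selection_result")) trace <- trace$fitness_trace
  dt <- data.table::data.table(iteration = seq_along(trace) - 1L,
                               best_fitness = trace)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
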