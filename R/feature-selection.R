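# Binary wrapper feature selection: binarize continuous swarm positions into
# feature masks, score masks by cross-validated error plus feature fraction,
# and drive the grasshopper optimizer to a selection result.

#' Fitness specification for wrapper selection
#'
#' @param alpha Weight of the classification-error term, strictly inside
#'   (0, 1); the feature-fraction term gets `1 - alpha`. Default 0.99, so the
#'   error dominates and the feature count breaks ties.
#' @param classifier `"svm"` or `"decision_tree"`; the classifier trained
#'   inside every fitness evaluation.
#' @param n_folds Stratified cross-validation folds inside the fitness
#'   (default 5). Folds are fixed per run (seeded once), which de-noises the
#'   fitness landscape the optimizer sees.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha = 0.99, classifier = c("svm", "decision_tree"),
                         n_folds = 5L, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  classifier <- match.arg(classifier)
  assert_scalar_num(n_folds, "n_folds", lower = 2)
  structure(
    list(alpha = alpha, classifier = classifier,
         n_folds = as.integer(n_folds), seed = as.integer(seed)),
    class = "fitness_spec"
  )
}

#' Binarize a continuous position into a feature mask
#'
#' Componentwise threshold on the unit box: bit d is 1 iff
#' `position[d] >= threshold` (the boundary counts as selected). An all-zero
#' mask is repaired by switching on the single largest-valued dimension, so
#' every mask selects at least one feature.
#'
#' @param position Finite numeric vector, one entry per feature.
#' @param threshold Cut point, default 0.5.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' binarize(c(0.9, 0.1, 0.7))
#' binarize(c(0.2, 0.4, 0.1))  # repair keeps the argmax
#' @export
binarize <- function(position, threshold = 0.5) {
  if (any(!is.finite(position))) {
    stop("`position` must be finite", call. = FALSE)
  }
  bits <- as.integer(position >= threshold)
  if (sum(bits) == 0L) bits[which.max(position)] <- 1L
  bits
}

#' Wrapper fitness of a feature mask
#'
#' `fitness = alpha * (cross-validated error on the masked columns) +
#' (1 - alpha) * selected / D`; lower is better, values lie in `[0, 1]`.
#' The error is the pooled misclassification rate of seeded stratified
#' k-fold cross-validation, so the value is deterministic given the spec.
#'
#' @param mask 0/1 integer vector with at least one selected feature.
#' @param table A [feature_table()] with both classes present.
#' @param spec A [fitness_spec()].
#' @param folds Optional precomputed fold ids (as from [make_folds()]);
#'   supplied internally so every mask in a run is scored on the same folds.
#' @return The fitness value.
#' @export
mask_fitness <- function(mask, table, spec = fitness_spec(), folds = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "fitness_spec"))
  d <- ncol(table$values)
  if (length(mask) != d) {
    stop("`mask` length must equal the number of features", call. = FALSE)
  }
  if (sum(mask) < 1L) {
    stop("`mask` selects zero features (repair should have prevented this)",
         call. = FALSE)
  }
  labels <- as.character(table$labels)
  if (length(unique(labels)) < 2L) {
    stop("feature table contains a single class", call. = FALSE)
  }
  if (is.null(folds)) folds <- make_folds(labels, spec$n_folds, spec$seed)
  values <- table$values[, mask == 1L, drop = FALSE]
  pred <- cv_predict(values, labels, spec$classifier, folds)
  err <- mean(pred != labels)
  spec$alpha * err + (1 - spec$alpha) * sum(mask) / d
}

#' Exhaustively score every non-empty feature mask
#'
#' Brute-force oracle for small feature counts: enumerates all `2^D - 1`
#' non-empty masks, scores each with [mask_fitness()] on shared folds, and
#' returns the optimum. Intended for validating the optimizer on toy tables.
#'
#' @param table A [feature_table()] with at most `max_features` columns.
#' @param spec A [fitness_spec()].
#' @param max_features Safety cap on D (default 12).
#' @return A list with `best_mask`, `best_fitness`, and `fitness` (the full
#'   vector over masks, indexed by the mask's binary encoding).
#' @export
enumerate_masks <- function(table, spec = fitness_spec(), max_features = 12L) {
  stopifnot(inherits(table, "feature_table"))
  d <- ncol(table$values)
  if (d > max_features) {
    stop(sprintf("exhaustive enumeration capped at %d features", max_features),
         call. = FALSE)
  }
  folds <- make_folds(as.character(table$labels), spec$n_folds, spec$seed)
  n_masks <- 2L^d - 1L
  fitness <- numeric(n_masks)
  best <- Inf
  best_mask <- NULL
  for (code in seq_len(n_masks)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, 0:(d - 1L)), 1L))
    fitness[code] <- mask_fitness(mask, table, spec, folds = folds)
    if (fitness[code] < best) {
      best <- fitness[code]
      best_mask <- mask
    }
  }
  list(best_mask = best_mask, best_fitness = best, fitness = fitness)
}

#' Grasshopper-optimized wrapper feature selection
#'
#' Runs the grasshopper optimizer over the unit box in D dimensions: each
#' grasshopper position encodes a candidate feature subset, scored by
#' cross-validated classification error plus selected-feature fraction
#' ([mask_fitness()]). Mask fitnesses are cached (the objective depends on
#' the position only through its mask), and the best mask ever evaluated is
#' returned with the full per-iteration fitness trace.
#'
#' Positions become masks through a transfer rule. The default,
#' `"stochastic"`, treats each unit-box coordinate as the selection
#' probability of its feature and draws the mask bits from seeded Bernoulli
#' trials — the transfer-function family standard in binary swarm
#' optimization. It keeps the mask space explored even late in the run, when
#' the swarm has contracted around the target; the deterministic
#' `"threshold"` rule ([binarize()] at 0.5) is available but freezes
#' exploration once the swarm collapses, since nearby positions then all map
#' to the target's own mask.
#'
#' @param table A [feature_table()] with at least two features.
#' @param goa A [goa_config()]; its bounds are forced to the unit box per
#'   feature. Defaults to the standard setting: population 25, 80 iterations.
#' @param spec A [fitness_spec()].
#' @param transfer `"stochastic"` (default) or `"threshold"`; see Details.
#' @param threshold Cut point of the `"threshold"` rule (default 0.5).
#' @return An object of class `selection_result`: a list with `mask` (0/1
#'   integer vector), `selected_count`, `final_fitness`, `fitness_trace`
#'   (length `n_iter + 1`, non-increasing), `n_masks_evaluated`, `goa`,
#'   `spec`, `transfer`, `threshold`, and `seed`.
#' @examples
#' tab <- generate_features(synthetic_spec(n_per_class = 30, n_features = 6,
#'                                         n_informative = 2, delta = 3))
#' res <- select_features(tab,
#'   goa = goa_config(0, 1, dim = 6, n_pop = 8, n_iter = 10),
#'   spec = fitness_spec(classifier = "decision_tree"))
#' res$mask
#' @export
select_features <- function(table, goa = NULL, spec = fitness_spec(),
                            transfer = c("stochastic", "threshold"),
                            threshold = 0.5) {
  transfer <- match.arg(transfer)
  stopifnot(inherits(table, "feature_table"), inherits(spec, "fitness_spec"))
  d <- ncol(table$values)
  if (d < 2L) stop("selection needs at least two features", call. = FALSE)
  if (is.null(goa)) {
    goa <- goa_config(lower = 0, upper = 1, dim = d)
  } else {
    stopifnot(inherits(goa, "goa_config"))
    goa$lower <- rep(0, d)
    goa$upper <- rep(1, d)
    goa$dim <- d
  }
  labels <- as.character(table$labels)
  folds <- make_folds(labels, spec$n_folds, spec$seed)

  cache <- new.env(parent = emptyenv())
  best_mask <- NULL
  best_fit <- Inf
  # Draws (stochastic transfer) ride on the optimizer's seeded stream, so a
  # run stays reproducible from goa$seed alone.
  to_mask <- if (transfer == "stochastic") {
    function(x) {
      bits <- as.integer(stats::runif(length(x)) < x)
      if (sum(bits) == 0L) bits[which.max(x)] <- 1L
      bits
    }
  } else {
    function(x) binarize(x, threshold)
  }
  objective <- function(x) {
    mask <- to_mask(x)
    key <- paste(mask, collapse = "")
    fit <- cache[[key]]
    if (is.null(fit)) {
      fit <- tryCatch(
        mask_fitness(mask, table, spec, folds = folds),
        error = function(e) {
          stop(sprintf("fitness evaluation failed for mask %s: %s",
                       key, conditionMessage(e)), call. = FALSE)
        }
      )
      cache[[key]] <- fit
    }
    if (fit < best_fit) {
      best_fit <<- fit
      best_mask <<- mask
    }
    fit
  }

  res <- goa_optimize(objective, goa)
  structure(
    list(
      mask = best_mask,
      selected_count = sum(best_mask),
      final_fitness = res$trace[length(res$trace)],
      fitness_trace = res$trace,
      n_masks_evaluated = length(ls(cache)),
      goa = goa, spec = spec, transfer = transfer, threshold = threshold,
      seed = goa$seed
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Wrapper feature-selection result\n")
  cat(sprintf("  selected %d of %d features; final fitness %.5f\n",
              x$selected_count, length(x$mask), x$final_fitness))
  cat(sprintf("  fitness trace: %.5f -> %.5f over %d iterations (%d masks scored)\n",
              x$fitness_trace[1], x$final_fitness,
              length(x$fitness_trace) - 1L, x$n_masks_evaluated))
  invisible(x)
}

#' Serialize a selection result as JSON
#'
#' Writes the mask (as a 0/1 string), the fitness trace, and the full
#' configuration snapshot, so a run can be audited and reproduced.
#'
#' @param result A `selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  doc <- list(
    schema = "goafs/selection/1",
    mask = paste(result$mask, collapse = ""),
    selected_count = result$selected_count,
    final_fitness = result$final_fitness,
    fitness_trace = result$fitness_trace,
    n_masks_evaluated = result$n_masks_evaluated,
    transfer = result$transfer,
    threshold = result$threshold,
    seed = result$seed,
    goa = result$goa[c("n_pop", "n_iter", "f", "l", "c_max", "c_min",
                       "distance_map_range", "seed")],
    fitness = unclass(result$spec)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
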