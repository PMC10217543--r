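# Seeded synthetic feature tables with planted informative columns,
# emulating the two-class deep-feature setting (benign vs tumor) so the
# whole selection/classification machinery is testable offline.

#' Specification of a synthetic two-class feature table
#'
#' @param n_per_class Samples per class (>= 2).
#' @param n_features Total number of feature columns D.
#' @param n_informative Number of planted informative columns k (<= D).
#' @param delta Class-mean separation of the informative columns, in units of
#'   `noise_sd` (>= 0). The default 2.0 makes single-feature classification
#'   noticeably imperfect (Bayes error about 16%), so selection has to find a
#'   subset rather than a single column.
#' @param noise_sd Standard deviation of every column (> 0, default 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 100L, n_features = 20L,
                           n_informative = 5L, delta = 2, noise_sd = 1,
                           seed = 1L) {
  assert_scalar_num(n_per_class, "n_per_class", lower = 2)
  assert_scalar_num(n_features, "n_features", lower = 1)
  assert_scalar_num(n_informative, "n_informative", lower = 0)
  if (n_informative > n_features) {
    stop("`n_informative` cannot exceed `n_features`", call. = FALSE)
  }
  assert_scalar_num(delta, "delta", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0, strict = TRUE)
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         delta = delta, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic feature table
#'
#' Draws class-conditional Gaussian features: the k planted informative
#' columns have class means at `-delta/2` and `+delta/2` (in `noise_sd`
#' units; benign low, tumor high), the remaining columns are class-independent
#' Gaussian noise. Rows are shuffled with the seed, and the returned table
#' carries the ground-truth informative mask. Identical spec and seed
#' reproduce the table exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A [feature_table()] whose `informative` field marks the planted
#'   columns and whose positive class is `"tumor"`.
#' @examples
#' tab <- generate_features(synthetic_spec(n_per_class = 50))
#' sum(tab$informative)
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- 2L * spec$n_per_class
  d <- spec$n_features
  k <- spec$n_informative
  with_seed(spec$seed, {
    labels <- rep(c("benign", "tumor"), each = spec$n_per_class)
    values <- matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
    if (k > 0L) {
      shift <- spec$delta * spec$noise_sd / 2
      sign <- ifelse(labels == "tumor", 1, -1)
      values[, seq_len(k)] <- values[, seq_len(k)] + sign * shift
    }
    # shuffle rows so class is not confounded with row order
    ord <- sample.int(n)
    values <- values[ord, , drop = FALSE]
    labels <- labels[ord]
    informative <- c(rep(1L, k), rep(0L, d - k))
    feature_table(values, factor(labels, levels = c("benign", "tumor")),
                  informative = informative, positive = "tumor")
  })
}

#' Deterministic catalogue of test fixtures
#'
#' Generates the named set of tables used across the test modules:
#' `tiny` (D = 6, small enough for the 63-mask exhaustive oracle),
#' `toy8` (D = 8, 255-mask oracle), `separable` (delta = 6, linearly
#' separable), `noisy` (the standard selection setting: D = 20, 5 informative
#' columns, delta = 2), and `single` (one strongly separating column among
#' pure noise). Sub-seeds are derived from `seed` by fixed offsets, so the
#' whole suite is reproducible from one integer.
#'
#' @param seed Integer seed.
#' @return Named list of [feature_table()] objects.
#' @export
make_fixture_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    tiny = generate_features(synthetic_spec(
      n_per_class = 40L, n_features = 6L, n_informative = 2L, delta = 2.5,
      seed = seed)),
    toy8 = generate_features(synthetic_spec(
      n_per_class = 40L, n_features = 8L, n_informative = 3L, delta = 1.5,
      seed = seed + 1L)),
    separable = generate_features(synthetic_spec(
      n_per_class = 100L, n_features = 10L, n_informative = 3L, delta = 6,
      seed = seed + 2L)),
    noisy = generate_features(synthetic_spec(
      n_per_class = 100L, n_features = 20L, n_informative = 5L, delta = 2,
      seed = seed + 3L)),
    single = generate_features(synthetic_spec(
      n_per_class = 60L, n_features = 10L, n_informative = 1L, delta = 8,
      seed = seed + 4L))
  )
}
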