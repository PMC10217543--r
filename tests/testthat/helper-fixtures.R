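# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code under fixed seeds; no files on disk.

fixtures <- make_fixture_suite(seed = 1L)

# Small optimizer settings for quick contract checks.
quick_goa <- function(dim, seed = 1L, n_pop = 10L, n_iter = 15L) {
  goa_config(lower = 0, upper = 1, dim = dim, n_pop = n_pop, n_iter = n_iter,
             seed = seed)
}

# One-sided linear-separability certificate: the perceptron converges to a
# zero-error hyperplane if and only if one exists; a found separator is a
# constructive proof of separability, independent of any classifier in the
# package.
perceptron_separable <- function(tab, max_epochs = 500L) {
  x <- cbind(1, tab$values)
  y <- ifelse(as.character(tab$labels) == as.character(tab$labels)[1], 1, -1)
  w <- numeric(ncol(x))
  for (e in seq_len(max_epochs)) {
    errors <- 0L
    for (i in seq_len(nrow(x))) {
      if (y[i] * sum(w * x[i, ]) <= 0) {
        w <- w + y[i] * x[i, ]
        errors <- errors + 1L
      }
    }
    if (errors == 0L) return(TRUE)
  }
  FALSE
}

# Random well-defined confusion matrices (every metric denominator positive),
# built by tallying label vectors so the counts go through the public API.
random_confusions <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tp <- sample(1:200, 1)
    tn <- sample(1:200, 1)
    fp <- sample(0:200, 1)
    fn <- sample(0:200, 1)
    confusion_matrix(
      truth = rep(c("pos", "pos", "neg", "neg"), c(tp, fn, tn, fp)),
      predicted = rep(c("pos", "neg", "neg", "pos"), c(tp, fn, tn, fp)),
      positive = "pos"
    )
  })
}
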