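# Small fixtures built in code; everything is deterministic given the
# seeds set inside each helper.

# n random images of the given shape plus cyclic labels.
tiny_dataset <- function(n = 8, shape = c(3, 2, 2), k = 3, seed = 42) {
  set.seed(seed)
  imgs <- replicate(n, array(rnorm(prod(shape)), shape), simplify = FALSE)
  mtr_data(imgs, rep(letters[seq_len(k)], length.out = n))
}

# Random parameters compatible with a dataset.
random_params <- function(data, rank = 1, seed = 1, intercepts = FALSE) {
  set.seed(seed)
  k <- nlevels(data$labels)
  cp <- replicate(k - 1, cp_tensor(lapply(data$shape, function(d)
    matrix(rnorm(d * rank), d, rank))), simplify = FALSE)
  mtr_params(cp, levels(data$labels),
             intercepts = if (intercepts) rnorm(k - 1))
}

# The shared default-scenario fit used by the acceptance-level checks;
# computed at most once per test run.
.fit_cache <- new.env(parent = emptyenv())
default_scenario_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    .fit_cache$sim <- mtr_simulate(mtr_scenario())
    .fit_cache$fit <- mtr_fit(.fit_cache$sim$data,
                              control = mtr_control(seed = 11))
  }
  list(sim = .fit_cache$sim, fit = .fit_cache$fit)
}
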