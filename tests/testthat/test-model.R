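test_that("linear_predictor matches the materialized-tensor oracle", {
  d <- tiny_dataset(n = 6)
  # zero params -> all-zero predictors
  zero <- mtr_params(replicate(2, cp_tensor(lapply(d$shape, numeric)),
                               simplify = FALSE), levels(d$labels))
  expect_equal(unname(linear_predictor(zero, d)), matrix(0, 6, 2))
  # rank-1 indicator at voxel (1,1,1) reads off that voxel
  ind <- mtr_params(list(cp_tensor(list(c(1, 0, 0), c(1, 0), c(1, 0))),
                         cp_tensor(lapply(d$shape, numeric))),
                    levels(d$labels))
  eta <- linear_predictor(ind, d)
  expect_equal(eta[, 1], d$x[, 1])
  # random params: agree with sum over materialized entries
  p <- random_params(d, rank = 2, seed = 9)
  eta <- linear_predictor(p, d)
  for (i in 1:6) for (k in 1:2)
    expect_equal(unname(eta[i, k]),
                 sum(materialize(p$cp[[k]]) * get_volume(d, i)),
                 tolerance = 1e-10)
  expect_error(linear_predictor(p, tiny_dataset(shape = c(2, 2, 2))),
               "shape")
})

test_that("class probabilities are a numerically safe softmax", {
  d <- tiny_dataset(n = 6)
  zero <- mtr_params(replicate(2, cp_tensor(lapply(d$shape, numeric)),
                               simplify = FALSE), levels(d$labels))
  mu <- class_probabilities(zero, d)
  expect_equal(unname(mu), matrix(1 / 3, 6, 3))
  # closed form: eta = (ln 2, 0) vs reference third class
  mu1 <- mtreg:::softmax_prob(matrix(c(log(2), 0), 1), 3, letters[1:3])
  expect_equal(as.numeric(mu1), c(0.5, 0.25, 0.25))
  # log-sum-exp safety: eta = 800 must not overflow
  mu2 <- mtreg:::softmax_prob(matrix(c(800, 0), 1), 3, letters[1:3])
  expect_true(all(is.finite(mu2)))
  expect_equal(unname(mu2[1, 1]), 1)
  expect_error(mtreg:::softmax_prob(matrix(c(NaN, 0), 1), 3, letters[1:3]),
               "non-finite")
})

test_that("probability rows sum to 1 on random parameter draws", {
  for (seed in 1:20) {
    d <- tiny_dataset(n = 5, seed = seed)
    p <- random_params(d, rank = (seed %% 2) + 1, seed = seed + 100)
    mu <- class_probabilities(p, d)
    expect_true(all(abs(rowSums(mu) - 1) < 1e-12))
    expect_true(all(mu > 0 & mu < 1))
  }
})

test_that("log-likelihood equals the naive per-subject summation", {
  d <- tiny_dataset(n = 6)
  zero <- mtr_params(replicate(2, cp_tensor(lapply(d$shape, numeric)),
                               simplify = FALSE), levels(d$labels))
  expect_equal(log_likelihood(zero, d), 6 * log(1 / 3))
  p <- random_params(d, seed = 3)
  mu <- class_probabilities(p, d)
  ref <- sum(vapply(1:6, function(i) log(mu[i, d$labels[i]]), 0))
  expect_equal(log_likelihood(p, d), ref, tolerance = 1e-12)
  expect_lte(log_likelihood(p, d), 0)
})

test_that("log-likelihood is invariant under CP rescaling", {
  d <- tiny_dataset(n = 6)
  p <- random_params(d, seed = 4)
  ll <- log_likelihood(p, d)
  p2 <- p
  f <- p2$cp[[1]]$factors
  f[[1]] <- f[[1]] * 7; f[[3]] <- f[[3]] / 7
  p2$cp[[1]] <- cp_tensor(f)
  expect_equal(log_likelihood(p2, d), ll, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  d <- tiny_dataset(n = 4, shape = c(3, 2, 2), seed = 8)
  p <- random_params(d, rank = 1, seed = 5, intercepts = TRUE)
  g <- log_likelihood_gradient(p, d)
  h <- 1e-6
  fd <- function(set) {
    (log_likelihood(set(h), d) - log_likelihood(set(-h), d)) / (2 * h)
  }
  for (k in 1:2) for (j in 1:3) {
    fmat <- p$cp[[k]]$factors[[j]]
    for (a in seq_len(nrow(fmat))) {
      num <- fd(function(delta) {
        p2 <- p
        f <- p2$cp[[k]]$factors
        f[[j]][a, 1] <- f[[j]][a, 1] + delta
        p2$cp[[k]] <- cp_tensor(f)
        p2
      })
      expect_equal(g$cp[[k]][[j]][a, 1], num, tolerance = 1e-5)
    }
  }
  for (k in 1:2) {
    num <- fd(function(delta) {
      p2 <- p; p2$intercepts[k] <- p2$intercepts[k] + delta; p2
    })
    expect_equal(unname(g$intercepts[k]), num, tolerance = 1e-5)
  }
  # no gradient entries exist for the reference class
  expect_length(g$cp, nlevels(d$labels) - 1)
})

test_that("gradient of intercepts vanishes at zero params with balanced labels", {
  d <- tiny_dataset(n = 6, k = 3)  # 2 subjects per class
  zero <- mtr_params(replicate(2, cp_tensor(lapply(d$shape, numeric)),
                               simplify = FALSE), levels(d$labels),
                     intercepts = c(0, 0))
  g <- log_likelihood_gradient(zero, d)
  expect_equal(unname(g$intercepts), c(0, 0), tolerance = 1e-12)
})

test_that("prediction breaks ties toward the lowest class index", {
  d <- tiny_dataset(n = 5)
  zero <- mtr_params(replicate(2, cp_tensor(lapply(d$shape, numeric)),
                               simplify = FALSE), levels(d$labels))
  expect_equal(as.character(predict(zero, d)), rep(levels(d$labels)[1], 5))
  mu <- matrix(c(0.1, 0.7, 0.2), 1)
  expect_equal(max.col(mu, ties.method = "first"), 2L)
})

test_that("K=2 reduces exactly to binary logistic regression", {
  set.seed(10)
  d <- tiny_dataset(n = 12, shape = c(3, 3, 2), k = 2, seed = 10)
  p <- random_params(d, seed = 11)
  mu <- class_probabilities(p, d)
  # scalar logistic oracle on the vectorized voxels with the materialized
  # coefficient tensor
  beta <- as.numeric(materialize(p$cp[[1]]))
  eta <- as.numeric(d$x %*% beta)
  expect_equal(unname(mu[, 1]), stats::plogis(eta), tolerance = 1e-12)
})
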