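test_that("separable planted data is fit to perfect training accuracy", {
  sim <- mtr_simulate(mtr_scenario(shape = c(10, 12, 10), n_per_class = 20,
                                   seed = 70))
  fit <- mtr_fit(sim$data, control = mtr_control(seed = 71))
  expect_true(fit$converged)
  expect_equal(fit$train_accuracy, 1)
  # convergence criterion: final log-likelihood step below epsilon
  tr <- fit$loglik_trace
  expect_lt(abs(diff(utils::tail(tr, 2))), fit$control$epsilon)
  # ascent property: no decrease beyond solver tolerance
  expect_true(all(diff(tr) > -1e-3))
})

test_that("identical seed and config reproduce the fit bit for bit", {
  sim <- mtr_simulate(mtr_scenario(shape = c(6, 5, 4), n_per_class = 10,
                                   seed = 72))
  ctl <- mtr_control(seed = 73, max_outer = 20)
  f1 <- mtr_fit(sim$data, control = ctl)
  f2 <- mtr_fit(sim$data, control = ctl)
  expect_identical(f1$params$cp, f2$params$cp)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("a diverging fit aborts with a diagnostic naming the block", {
  d <- tiny_dataset(n = 12, shape = c(4, 3, 3), seed = 74)
  expect_error(
    mtr_fit(d, control = mtr_control(seed = 1, solver = "gd",
                                     learning_rate = 1e10, max_outer = 5)),
    "diverged at outer sweep .*class.*mode")
  expect_error(mtr_fit(d[1:2], control = mtr_control(seed = 1)),
               "at least as many subjects")
})

test_that("label-independent data converges to the null-model optimum", {
  set.seed(60)
  imgs <- replicate(160, array(rnorm(36), c(4, 3, 3)), simplify = FALSE)
  d <- mtr_data(imgs, rep(c("a", "a", "b", "c"), 40))
  # with intercepts: analytic optimum of the intercept-only model is
  # n * sum(p_hat * log(p_hat)); the image term can only add a small
  # overfitting gain
  ft <- mtr_fit(d, intercepts = TRUE,
                control = mtr_control(seed = 61, max_outer = 150))
  phat <- c(0.5, 0.25, 0.25)
  null_opt <- 160 * sum(phat * log(phat))
  ll <- utils::tail(ft$loglik_trace, 1)
  expect_gte(ll, null_opt - 1e-6)
  expect_lt((ll - null_opt) / 160, 0.15)
  # without intercepts the zero model is nested, so the fit cannot do
  # worse than n * log(1/K)
  ft2 <- mtr_fit(d, control = mtr_control(seed = 61, max_outer = 50))
  expect_gte(utils::tail(ft2$loglik_trace, 1), 160 * log(1 / 3) - 0.1)
})

test_that("K=2 fit agrees with the vectorized logistic-regression oracle", {
  sim <- mtr_simulate(mtr_scenario(shape = c(3, 3, 2), n_per_class = 150,
                                   n_classes = 2, mechanism = "model",
                                   amplitude = 2, seed = 17))
  fit <- mtr_fit(sim$data, control = mtr_control(seed = 18, max_outer = 300,
                                                 epsilon = 1e-6))
  vb <- as.numeric(materialize(fit$params$cp[[1]]))
  y <- as.integer(sim$data$labels == levels(sim$data$labels)[1])
  oracle <- suppressWarnings(glm.fit(sim$data$x, y,
                                     family = stats::binomial()))
  expect_gt(stats::cor(vb, oracle$coefficients), 0.9)
})

test_that("the estimator recovers the generating direction when n >> p", {
  # well-posed regime: 12 voxels, 750 subjects, labels drawn from the
  # model itself -- the MLE direction must align with the truth
  sim <- mtr_simulate(mtr_scenario(shape = c(3, 2, 2), n_per_class = 250,
                                   mechanism = "model", amplitude = 2,
                                   seed = 81))
  fit <- mtr_fit(sim$data, control = mtr_control(seed = 82, max_outer = 200,
                                                 epsilon = 1e-6))
  rec <- parameter_recovery(sim$truth, fit)
  expect_gt(abs(rec$cosine[1]), 0.95)
  expect_gt(abs(rec$cosine[2]), 0.95)
})

test_that("joint mode reaches a comparable likelihood to block mode", {
  sim <- mtr_simulate(mtr_scenario(shape = c(5, 4, 3), n_per_class = 15,
                                   seed = 75))
  fb <- mtr_fit(sim$data, control = mtr_control(seed = 76, max_outer = 60))
  fj <- mtr_fit(sim$data, control = mtr_control(seed = 76, max_outer = 60,
                                                mode = "joint"))
  expect_equal(fb$train_accuracy, 1)
  expect_equal(fj$train_accuracy, 1)
})

test_that("learning-rate tuning picks the stable rate deterministically", {
  sim <- mtr_simulate(mtr_scenario(shape = c(5, 4, 3), n_per_class = 10,
                                   seed = 77))
  ctl <- mtr_control(seed = 78, max_outer = 15)
  # singleton grid returns that value
  expect_equal(as.numeric(tune_learning_rate(sim$data, 0.02, n_folds = 3,
                                             control = ctl)), 0.02)
  # a wildly large rate loses to a sane one
  best <- tune_learning_rate(sim$data, c(1e-3, 1e3), n_folds = 3,
                             control = ctl)
  expect_equal(as.numeric(best), 1e-3)
  scores <- attr(best, "scores")
  expect_gt(scores[1], scores[2])
  # determinism
  best2 <- tune_learning_rate(sim$data, c(1e-3, 1e3), n_folds = 3,
                              control = ctl)
  expect_identical(as.numeric(best), as.numeric(best2))
  # stratification needs every class twice
  expect_error(tune_learning_rate(tiny_dataset(n = 4, k = 3), 0.01,
                                  n_folds = 2, control = ctl),
               "cannot stratify")
})

test_that("free-parameter count follows (K-1) R (d1+d2+d3) plus extras", {
  expect_equal(param_count(c(5, 4, 3), n_classes = 4, rank = 2), 72)
  expect_equal(param_count(c(5, 4, 3), n_classes = 4, rank = 2,
                           intercepts = TRUE, n_covariates = 2), 81)
  d <- tiny_dataset(n = 6)
  p <- random_params(d, rank = 2, seed = 79, intercepts = TRUE)
  expect_equal(param_count(p), 2 * 2 * sum(d$shape) + 2)
})

test_that("recovery report is exact for identical and sign-flipped params", {
  d <- tiny_dataset(n = 4)
  p <- random_params(d, seed = 80)
  expect_equal(parameter_recovery(p, p)$cosine, c(1, 1), tolerance = 1e-12)
  flip <- p
  for (k in 1:2) {
    f <- flip$cp[[k]]$factors
    f[[1]] <- -f[[1]]
    flip$cp[[k]] <- cp_tensor(f)
  }
  r <- parameter_recovery(p, flip)
  expect_equal(abs(r$cosine), c(1, 1), tolerance = 1e-12)
  expect_equal(r$cosine, c(-1, -1), tolerance = 1e-12)
})
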