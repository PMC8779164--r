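# Smooth bump profile on 1:d with a contiguous active window: half-sine
# over the window, zero elsewhere, peak 1.  Window centers are staggered
# by class so different classes light up different regions.
bump_profile <- function(d, center_frac, window_frac) {
  w <- max(2L, round(window_frac * d))
  center <- round(center_frac * d)
  lo <- max(1L, min(d - w + 1L, center - w %/% 2L))
  v <- numeric(d)
  v[lo:(lo + w - 1L)] <- sin(pi * seq_len(w) / (w + 1))
  v
}

#' Define a synthetic-data scenario
#'
#' Describes a dataset with the exact statistical structure the
#' multinomial tensor model assumes: equally shaped 3D volumes of i.i.d.
#' Gaussian voxel noise, plus a planted rank-1 signal region (smooth
#' half-sine bump per mode, at a class-specific location) for each
#' non-reference class.  Two label mechanisms are available:
#' \describe{
#'   \item{`"planted"`}{labels are assigned first (`n_per_class` each) and
#'     class \eqn{k}'s mean signal, with peak voxel amplitude
#'     `amplitude * noise_sd`, is added to its subjects' volumes; the
#'     reference class is pure noise.  The Bayes log-odds of class
#'     \eqn{k} versus the reference are then
#'     \eqn{(\mathrm{amplitude}/\sigma)\, S_k} with intercept
#'     \eqn{-\mathrm{amplitude}^2 \|S_k\|^2/2}; the generator returns
#'     exactly these as the ground-truth parameters, and a large
#'     `amplitude` guarantees separability.}
#'   \item{`"model"`}{volumes are pure noise and labels are drawn from the
#'     model's own softmax probabilities at the true parameters, which
#'     are scaled so the linear predictors have standard deviation
#'     `amplitude`.}
#' }
#'
#' @param shape volume dimensions, default `c(20, 24, 20)` — a desk-scale
#'   stand-in that keeps the 3-way structure and unequal dimensions of
#'   spatially normalized brain volumes.
#' @param n_per_class subjects per class (total \eqn{n = K \cdot}
#'   `n_per_class`).
#' @param n_classes number of classes \eqn{K \ge 2}; the last class is the
#'   reference (signal-free) class.
#' @param amplitude peak signal amplitude in noise-sd units (planted) or
#'   linear-predictor standard deviation (model); `>= 0`.
#' @param noise_sd standard deviation of the i.i.d. voxel noise.
#' @param mechanism `"planted"` or `"model"` (see above).
#' @param window_frac fraction of each axis covered by the active window.
#' @param class_names optional class names (default `class1..classK`).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return an object of class `mtr_scenario`.
#' @export
mtr_scenario <- function(shape = c(20L, 24L, 20L), n_per_class = 100L,
                         n_classes = 3L, amplitude = 5, noise_sd = 1,
                         mechanism = c("planted", "model"),
                         window_frac = 0.4, class_names = NULL,
                         seed = 7L) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(shape) == 3L, all(shape >= 2L), n_per_class >= 1L,
            n_classes >= 2L, amplitude >= 0, noise_sd > 0,
            window_frac > 0, window_frac <= 1)
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(n_classes))
  stopifnot(length(class_names) == n_classes)
  structure(list(shape = as.integer(shape),
                 n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes), amplitude = amplitude,
                 noise_sd = noise_sd, mechanism = mechanism,
                 window_frac = window_frac, class_names = class_names,
                 seed = as.integer(seed)),
            class = "mtr_scenario")
}

# Unit-peak rank-1 signal tensor for non-reference class k, as a
# cp_tensor.  Centers are staggered along each axis so class regions are
# disjoint-ish but always in bounds.
signal_tensor <- function(scenario, k) {
  km1 <- scenario$n_classes - 1L
  frac <- (k - 0.5) / km1          # class centers spread along each axis
  cp_tensor(lapply(scenario$shape, function(d)
    bump_profile(d, frac, scenario$window_frac)))
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws the dataset described by an [mtr_scenario()] and returns it
#' together with the exact generating parameters, enabling
#' parameter-recovery studies with no external data.
#'
#' @param scenario an [mtr_scenario()].
#' @return an object of class `mtr_sim`: list with `data`
#'   ([mtr_data()]), `truth` ([mtr_params()]) and `scenario`.
#' @examples
#' sim <- mtr_simulate(mtr_scenario(shape = c(8, 6, 5), n_per_class = 10))
#' table(sim$data$labels)
#' @export
mtr_simulate <- function(scenario) {
  stopifnot(inherits(scenario, "mtr_scenario"))
  set.seed(scenario$seed)
  k <- scenario$n_classes
  km1 <- k - 1L
  n <- k * scenario$n_per_class
  v <- prod(scenario$shape)
  sigma <- scenario$noise_sd

  signals <- lapply(seq_len(km1), function(kk) signal_tensor(scenario, kk))
  x <- matrix(stats::rnorm(n * v, 0, sigma), n, v)

  if (scenario$mechanism == "planted") {
    labels <- factor(rep(scenario$class_names, each = scenario$n_per_class),
                     levels = scenario$class_names)
    for (kk in seq_len(km1)) {
      rows <- which(as.integer(labels) == kk)
      sv <- scenario$amplitude * sigma * cp_vec(signals[[kk]])
      x[rows, ] <- sweep(x[rows, , drop = FALSE], 2L, sv, "+")
    }
    # Bayes log-odds of class k vs the (signal-free) reference class:
    # (amplitude/sigma) S_k plus intercept -amplitude^2 ||S_k||^2 / 2
    truth_cp <- lapply(signals, function(s) {
      f <- s$factors
      f[[1L]] <- f[[1L]] * (scenario$amplitude / sigma)
      cp_tensor(f)
    })
    truth_alpha <- vapply(signals, function(s)
      -scenario$amplitude^2 * cp_cross(s, s) / 2, 0)
  } else {
    # model mechanism: scale so linear predictors have sd = amplitude
    truth_cp <- lapply(signals, function(s) {
      f <- s$factors
      norm_s <- sqrt(cp_cross(s, s))
      f[[1L]] <- f[[1L]] * (scenario$amplitude / (sigma * norm_s))
      cp_tensor(f)
    })
    eta <- x %*% vapply(truth_cp, cp_vec, numeric(v))
    mu <- softmax_prob(eta, k, scenario$class_names)
    draw <- function(p) sample.int(k, 1L, prob = p)
    labels <- factor(scenario$class_names[apply(mu, 1L, draw)],
                     levels = scenario$class_names)
    truth_alpha <- NULL
  }

  truth <- mtr_params(truth_cp, scenario$class_names, reference = k,
                      intercepts = truth_alpha)
  data <- structure(list(x = x, shape = scenario$shape, labels = labels,
                         covariates = NULL),
                    class = "mtr_data")
  structure(list(data = data, truth = truth, scenario = scenario),
            class = "mtr_sim")
}

#' @export
print.mtr_sim <- function(x, ...) {
  cat(sprintf("<mtr_sim> %s mechanism, amplitude %.2g, noise sd %.2g\n",
              x$scenario$mechanism, x$scenario$amplitude,
              x$scenario$noise_sd))
  print(x$data)
  invisible(x)
}

#' Stratified train/test split
#'
#' Partitions a dataset into training and testing sets while retaining the
#' class ratio in both: per-class test counts are `test_fraction` times
#' the class count, rounded by the largest-remainder method so that each
#' count differs from its exact quota by less than 1 and the total equals
#' `round(test_fraction * n)`.  Deterministic given `seed`.
#'
#' @param data an [mtr_data()]; every class needs at least 2 members.
#' @param test_fraction fraction of subjects held out (default 0.2).
#' @param seed optional RNG seed.
#' @return list with elements `train` and `test`, a partition of the
#'   input.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = NULL) {
  stopifnot(inherits(data, "mtr_data"), test_fraction > 0,
            test_fraction < 1)
  counts <- table(data$labels)
  if (any(counts < 2L))
    stop(sprintf("class(es) with fewer than 2 members: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")))
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects(data)
  total <- round(test_fraction * n)
  quota <- test_fraction * as.numeric(counts)
  take <- floor(quota)
  extra <- total - sum(take)
  if (extra > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
  }
  test_idx <- integer(0)
  for (ci in seq_along(counts)) {
    idx <- sample(which(as.integer(data$labels) == ci))
    test_idx <- c(test_idx, idx[seq_len(take[ci])])
  }
  test_idx <- sort(test_idx)
  list(train = data[-test_idx], test = data[test_idx])
}
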