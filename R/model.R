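#' Multinomial tensor regression parameters
#'
#' Parameters of a \eqn{K}-class softmax (multinomial logistic) model whose
#' image coefficients are CP tensors.  One class is the reference: its
#' linear predictor is fixed at 0 and it carries no parameters.  For each
#' non-reference class \eqn{k} the predictor for subject \eqn{i} is
#' \deqn{\eta_{ik} = \alpha_k + \langle\gamma_k, Z_i\rangle
#'                 + \langle B_k, X_i\rangle,}
#' with \eqn{B_k} a [cp_tensor()], and class probabilities are the softmax
#' of \eqn{(\eta_{i1},\dots,\eta_{i,K-1},0)} (log-odds of each class
#' against the reference).  Intercepts \eqn{\alpha_k} and covariate
#' coefficients \eqn{\gamma_k} are optional; the default model uses the
#' image term alone.
#'
#' @param cp list of \eqn{K-1} `cp_tensor`s of identical shape and rank,
#'   one per non-reference class, in class order with the reference class
#'   skipped.
#' @param class_names character vector of the \eqn{K} class names.
#' @param reference index (in `class_names`) of the reference class;
#'   default the last class.
#' @param intercepts optional numeric vector of \eqn{K-1} intercepts.
#' @param gamma optional \eqn{(K-1) \times p} matrix of covariate
#'   coefficients.
#' @param standardize optional `list(center, scale)` of scalar training
#'   statistics applied to every voxel before the inner product.
#' @return an object of class `mtr_params`.
#' @export
mtr_params <- function(cp, class_names, reference = length(class_names),
                       intercepts = NULL, gamma = NULL,
                       standardize = NULL) {
  k <- length(class_names)
  if (k < 2L) stop("need at least 2 classes")
  if (!reference %in% seq_len(k)) stop("invalid reference class index")
  if (length(cp) != k - 1L)
    stop(sprintf("expected %d CP tensors (K-1), got %d", k - 1L, length(cp)))
  shapes <- lapply(cp, function(b) b$shape)
  ranks <- vapply(cp, function(b) b$rank, 0L)
  if (length(unique(shapes)) != 1L || length(unique(ranks)) != 1L)
    stop("all CP tensors must share one shape and rank")
  if (!is.null(intercepts) && length(intercepts) != k - 1L)
    stop("need one intercept per non-reference class")
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != k - 1L)
      stop("gamma must have one row per non-reference class")
  }
  names(cp) <- class_names[-reference]
  structure(list(cp = cp, class_names = class_names, reference = reference,
                 shape = shapes[[1L]], rank = ranks[[1L]],
                 intercepts = intercepts, gamma = gamma,
                 standardize = standardize),
            class = "mtr_params")
}

#' @export
print.mtr_params <- function(x, ...) {
  cat(sprintf(
    "<mtr_params> %d classes (reference: %s), shape (%s), rank %d\n",
    length(x$class_names), x$class_names[x$reference],
    paste(x$shape, collapse = ", "), x$rank))
  cat(sprintf("free parameters: %d%s%s\n", param_count(x),
              if (is.null(x$intercepts)) "" else " (incl. intercepts)",
              if (is.null(x$gamma)) "" else " (incl. covariate coefs)"))
  invisible(x)
}

#' Free-parameter count of a multinomial tensor model
#'
#' For \eqn{K} classes, rank \eqn{R} and shape \eqn{(d_1,d_2,d_3)} the
#' image coefficients contribute \eqn{(K-1)\,R\,(d_1+d_2+d_3)} parameters
#' (the CP factors of the \eqn{K-1} non-reference classes), plus
#' \eqn{K-1} intercepts and \eqn{(K-1)p} covariate coefficients when
#' present.  Scale indeterminacy within rank-1 terms is ignored, matching
#' the usual accounting for CP models.
#'
#' @param x an [mtr_params()] object, or a shape vector `c(d1, d2, d3)`.
#' @param n_classes,rank,intercepts,n_covariates used only when `x` is a
#'   shape vector.
#' @return integer parameter count.
#' @examples
#' param_count(c(79, 95, 79), n_classes = 3)  # 506
#' @export
param_count <- function(x, n_classes = 3L, rank = 1L, intercepts = FALSE,
                        n_covariates = 0L) {
  if (inherits(x, "mtr_params")) {
    km1 <- length(x$class_names) - 1L
    return(km1 * x$rank * sum(x$shape) +
           (if (is.null(x$intercepts)) 0L else km1) +
           (if (is.null(x$gamma)) 0L else km1 * ncol(x$gamma)))
  }
  km1 <- n_classes - 1L
  km1 * rank * sum(x) + (if (intercepts) km1 else 0L) + km1 * n_covariates
}

# vec(B) for a cp_tensor: length prod(shape), R-native (mode-1-fastest)
# ordering.  One image-sized buffer; used for batch linear predictors.
cp_vec <- function(b) {
  kr <- khatri_rao(b$factors[[3L]], khatri_rao(b$factors[[2L]],
                                               b$factors[[1L]]))
  rowSums(kr)
}

# Standardized voxel matrix (identity unless params carry training stats).
std_x <- function(params, data) {
  if (is.null(params$standardize)) return(data$x)
  (data$x - params$standardize$center) / params$standardize$scale
}

#' Linear predictors for all subjects
#'
#' Returns the \eqn{n \times (K-1)} matrix of linear predictors
#' \eqn{\eta_{ik}} for the non-reference classes; the reference class
#' predictor is identically 0 and not returned.
#'
#' @param params an [mtr_params()].
#' @param data an [mtr_data()] with matching shape.
#' @return numeric matrix, columns named by non-reference class.
#' @export
linear_predictor <- function(params, data) {
  if (!all(data$shape == params$shape))
    stop(sprintf("data shape (%s) does not match model shape (%s)",
                 paste(data$shape, collapse = ", "),
                 paste(params$shape, collapse = ", ")))
  x <- std_x(params, data)
  eta <- x %*% vapply(params$cp, cp_vec, numeric(ncol(x)))
  if (!is.null(params$intercepts))
    eta <- sweep(eta, 2L, params$intercepts, "+")
  if (!is.null(params$gamma)) {
    if (is.null(data$covariates))
      stop("model has covariate coefficients but data has no covariates")
    eta <- eta + data$covariates %*% t(params$gamma)
  }
  colnames(eta) <- names(params$cp)
  eta
}

# Softmax over (eta_1, ..., eta_{K-1}, 0) with max-subtraction; `eta` is
# the n x (K-1) non-reference predictor matrix, `reference` the column
# position of the reference class in the full K-column output.
softmax_prob <- function(eta, reference, class_names) {
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor; the model has diverged")
  k <- ncol(eta) + 1L
  full <- matrix(0, nrow(eta), k)
  full[, -reference] <- eta
  m <- apply(full, 1L, max)
  e <- exp(full - m)
  p <- e / rowSums(e)
  colnames(p) <- class_names
  p
}

#' Class probabilities under the model
#'
#' Softmax of the linear predictors (with the reference class fixed at 0),
#' computed with max-subtraction so large predictors cannot overflow.
#' Every row sums to 1.
#'
#' @inheritParams linear_predictor
#' @return \eqn{n \times K} probability matrix with columns in class
#'   order.
#' @export
class_probabilities <- function(params, data) {
  softmax_prob(linear_predictor(params, data), params$reference,
               params$class_names)
}

#' Multinomial log-likelihood
#'
#' \eqn{\ell(\Theta) = \sum_i \sum_k y_{ik} \log \mu_{ik}}, always
#' \eqn{\le 0}; at zero parameters it equals \eqn{n \log(1/K)}.  Inside
#' the likelihood only, \eqn{\log \mu} is floored at the log of the
#' smallest positive normal double so that a saturated wrong prediction
#' yields a large finite penalty rather than `-Inf`.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  mu <- class_probabilities(params, data)
  y <- one_hot(data$labels)
  lp <- pmax(log(mu), log(.Machine$double.xmin))
  sum(y * lp)
}

# Index permutations mapping R-native vec order to the mode-2 / mode-3
# unfolding vec orders (mode 1 is the identity).
mode_perms <- function(shape) {
  idx <- array(seq_len(prod(shape)), shape)
  list(NULL,
       as.integer(aperm(idx, c(2L, 1L, 3L))),
       as.integer(aperm(idx, c(3L, 1L, 2L))))
}

# For mode j: n x (d_j * R) matrix whose row i is vec(X_i(j) %*% KR),
# i.e. the design matrix of the block subproblem for one class's mode-j
# factor.  `xu` is the n x V voxel matrix already permuted to the mode-j
# unfolding order.
block_design <- function(xu, dj, kr) {
  n <- nrow(xu)
  m <- ncol(xu) / dj
  cmat <- matrix(xu, n * dj, m) %*% kr           # (n*dj) x R
  dim(cmat) <- c(n, dj * ncol(kr))
  cmat
}

#' Analytic log-likelihood gradient
#'
#' Exact gradient of the log-likelihood with respect to every CP factor
#' matrix (and intercepts / covariate coefficients when present), via the
#' chain rule through the CP structure: the derivative of
#' \eqn{\eta_{ik}} in the mode-\eqn{j} factor of \eqn{B_k} is
#' \eqn{X_{i(j)}} times the Khatri-Rao product of the other two factors,
#' weighted by the softmax residual \eqn{y_{ik} - \mu_{ik}}.  Used by the
#' joint-optimization mode and by finite-difference verification; the
#' block-relaxation fitter computes the same per-block quantities
#' incrementally.
#'
#' @inheritParams linear_predictor
#' @return list with `cp` (per class, a list of 3 gradient matrices
#'   congruent to the factor matrices), and `intercepts` / `gamma` when
#'   the model has them.
#' @export
log_likelihood_gradient <- function(params, data) {
  x <- std_x(params, data)
  mu <- class_probabilities(params, data)
  y <- one_hot(data$labels)
  resid <- y - mu                               # n x K
  perms <- mode_perms(params$shape)
  knames <- names(params$cp)
  out <- list(cp = vector("list", length(params$cp)))
  names(out$cp) <- knames
  for (k in seq_along(params$cp)) {
    b <- params$cp[[k]]
    rk <- resid[, knames[k]]
    out$cp[[k]] <- vector("list", 3L)
    for (j in 1:3) {
      xu <- if (is.null(perms[[j]])) x else x[, perms[[j]], drop = FALSE]
      cmat <- block_design(xu, params$shape[j], kr_other(b, j))
      out$cp[[k]][[j]] <- matrix(crossprod(cmat, rk),
                                 params$shape[j], b$rank)
    }
  }
  if (!is.null(params$intercepts))
    out$intercepts <- colSums(resid[, knames, drop = FALSE])
  if (!is.null(params$gamma))
    out$gamma <- t(crossprod(data$covariates,
                             resid[, knames, drop = FALSE]))
  out
}

#' Predicted classes
#'
#' Argmax of the class probabilities per subject; ties are broken toward
#' the lowest class index, so the zero-parameter model predicts the first
#' class for everyone.
#'
#' @param object an [mtr_params()] or [mtr_fit()] result.
#' @param data an [mtr_data()].
#' @param type `"class"` (default), `"prob"`, or `"link"` for the raw
#'   non-reference linear predictors.
#' @param ... unused.
#' @return factor of predicted classes, or a numeric matrix for
#'   `type = "prob"` / `"link"`.
#' @export
predict.mtr_params <- function(object, data, type = c("class", "prob",
                                                      "link"), ...) {
  type <- match.arg(type)
  if (type == "link") return(linear_predictor(object, data))
  mu <- class_probabilities(object, data)
  if (type == "prob") return(mu)
  factor(object$class_names[max.col(mu, ties.method = "first")],
         levels = object$class_names)
}
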