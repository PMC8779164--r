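#' CP (CANDECOMP/PARAFAC) tensor in factored form
#'
#' A rank-\eqn{R} CP tensor over a 3-way array of shape
#' \eqn{(d_1, d_2, d_3)} is the sum of \eqn{R} outer products
#' \deqn{B = \sum_{r=1}^{R} \beta_r^1 \circ \beta_r^2 \circ \beta_r^3,}
#' stored as three factor matrices (\eqn{d_j \times R}), never materialized
#' at full size unless explicitly requested via [materialize()].  A
#' coefficient tensor in this form has \eqn{R(d_1+d_2+d_3)} free parameters
#' (ignoring the scale indeterminacy within each rank-1 term) instead of
#' \eqn{d_1 d_2 d_3}.
#'
#' @param factors list of exactly 3 numeric matrices (or vectors, taken as
#'   single columns); matrix \eqn{j} has dimensions \eqn{d_j \times R} and
#'   holds the mode-\eqn{j} component vectors, one column per rank-1 term.
#' @return an object of class `cp_tensor` with fields `factors`, `shape`
#'   and `rank`.
#' @examples
#' b <- cp_tensor(list(c(1, 2), c(3, 4), 5))
#' materialize(b)
#' @export
cp_tensor <- function(factors) {
  if (!is.list(factors) || length(factors) != 3L)
    stop("`factors` must be a list of 3 vectors or matrices (one per mode)")
  factors <- lapply(factors, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    if (any(!is.finite(f))) stop("CP factor entries must be finite")
    f
  })
  ranks <- vapply(factors, ncol, 0L)
  if (length(unique(ranks)) != 1L)
    stop("all factor matrices must have the same number of columns (rank)")
  structure(
    list(factors = factors,
         shape   = vapply(factors, nrow, 0L),
         rank    = ranks[[1L]]),
    class = "cp_tensor")
}

#' @export
print.cp_tensor <- function(x, ...) {
  cat(sprintf("<cp_tensor> shape (%s), rank %d, %d free parameters\n",
              paste(x$shape, collapse = ", "), x$rank,
              x$rank * sum(x$shape)))
  invisible(x)
}

#' Outer product of three vectors
#'
#' Returns the 3-way array with entries `u[a] * v[b] * w[c]`.
#'
#' @param u,v,w finite numeric vectors of lengths \eqn{d_1, d_2, d_3}.
#' @return numeric array of dimension `c(length(u), length(v), length(w))`.
#' @export
outer_product <- function(u, v, w) {
  for (x in list(u, v, w))
    if (!is.numeric(x) || any(!is.finite(x)))
      stop("outer_product() requires finite numeric vectors")
  outer(outer(as.numeric(u), as.numeric(v)), as.numeric(w))
}

#' Materialize a CP tensor as a dense array
#'
#' Sums the rank-1 outer products into a full \eqn{d_1 \times d_2 \times
#' d_3} array.  Intended for small shapes and for verification; all model
#' computations work on the factored form.
#'
#' @param b a [cp_tensor()].
#' @return numeric 3-way array.
#' @export
materialize <- function(b) {
  stopifnot(inherits(b, "cp_tensor"))
  out <- array(0, b$shape)
  for (r in seq_len(b$rank))
    out <- out + outer_product(b$factors[[1L]][, r],
                               b$factors[[2L]][, r],
                               b$factors[[3L]][, r])
  out
}

#' Inner product of a CP tensor with a dense 3-way array
#'
#' Computes \eqn{\langle B, X\rangle = \sum_{abc} B_{abc} X_{abc}} by
#' mode-wise contraction (X is contracted against the mode-3, then mode-2,
#' then mode-1 component of each rank-1 term), so the CP tensor is never
#' materialized.
#'
#' @param b a [cp_tensor()].
#' @param x numeric 3-way array with `dim(x)` equal to `b$shape`.
#' @return scalar.
#' @export
inner_product <- function(b, x) {
  stopifnot(inherits(b, "cp_tensor"))
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || !all(d == b$shape))
    stop(sprintf("shape mismatch: CP tensor is (%s) but array is (%s)",
                 paste(b$shape, collapse = ", "),
                 paste(if (is.null(d)) length(x) else d, collapse = ", ")))
  u <- b$factors[[1L]]; v <- b$factors[[2L]]; w <- b$factors[[3L]]
  total <- 0
  x2 <- matrix(x, d[1L] * d[2L], d[3L])
  for (r in seq_len(b$rank)) {
    m <- x2 %*% w[, r]                      # contract mode 3
    m <- matrix(m, d[1L], d[2L]) %*% v[, r] # contract mode 2
    total <- total + sum(u[, r] * m)        # contract mode 1
  }
  as.numeric(total)
}

#' Mode-j unfolding (matricization) of a 3-way array
#'
#' Rearranges `x` into a matrix whose rows are the mode-`mode` fibers.
#' The columns run over the two remaining modes with the *lower* remaining
#' mode varying fastest; this is the one place the unfolding convention is
#' encoded, and [khatri_rao()] uses the matching ordering so that for a
#' rank-1 tensor \eqn{u \circ v \circ w}
#' \deqn{\langle u\circ v\circ w,\, X\rangle
#'       = u^\top X_{(1)} (w \otimes v)
#'       = v^\top X_{(2)} (w \otimes u)
#'       = w^\top X_{(3)} (v \otimes u).}
#'
#' @param x numeric 3-way array.
#' @param mode 1, 2 or 3.
#' @return matrix of dimension `dim(x)[mode]` by `prod(dim(x)[-mode])`.
#' @export
mode_unfold <- function(x, mode) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("`x` must be a 3-way array")
  if (!mode %in% 1:3) stop("`mode` must be 1, 2 or 3")
  switch(mode,
         matrix(x, d[1L], d[2L] * d[3L]),
         matrix(aperm(x, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L]),
         matrix(aperm(x, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L]))
}

#' Khatri-Rao product
#'
#' Column-wise Kronecker product of two matrices with the same number of
#' columns; for vectors this is the plain Kronecker product.  The index of
#' the *second* argument varies fastest, matching the column ordering of
#' [mode_unfold()].
#'
#' @param a,b numeric vectors or matrices with equal column counts.
#' @return matrix with `nrow(a) * nrow(b)` rows.
#' @export
khatri_rao <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("khatri_rao() needs matrices with the same number of columns")
  out <- matrix(0, nrow(a) * nrow(b), ncol(a))
  for (r in seq_len(ncol(a)))
    out[, r] <- kronecker(a[, r], b[, r])
  out
}

# Khatri-Rao product of the two factor matrices of `b` other than `mode`,
# ordered to match mode_unfold(): higher remaining mode first.
kr_other <- function(b, mode) {
  f <- b$factors
  switch(mode,
         khatri_rao(f[[3L]], f[[2L]]),
         khatri_rao(f[[3L]], f[[1L]]),
         khatri_rao(f[[2L]], f[[1L]]))
}

# <A, B> for two CP tensors of the same shape, via factor Gram products:
# sum_{r,s} prod_j (a_r^j . b_s^j).  Never materializes either tensor.
cp_cross <- function(a, b) {
  g <- crossprod(a$factors[[1L]], b$factors[[1L]]) *
       crossprod(a$factors[[2L]], b$factors[[2L]]) *
       crossprod(a$factors[[3L]], b$factors[[3L]])
  sum(g)
}

#' Cosine similarity between two CP tensors
#'
#' \eqn{\langle A,B\rangle / (\|A\|\,\|B\|)} computed entirely in factored
#' form, so it is exact at any shape.  Invariant to the CP scale
#' indeterminacy; its absolute value is additionally invariant to an
#' overall sign flip.
#'
#' @param a,b [cp_tensor()] objects of equal shape.
#' @return scalar in \eqn{[-1, 1]}.
#' @export
cp_cosine <- function(a, b) {
  stopifnot(inherits(a, "cp_tensor"), inherits(b, "cp_tensor"),
            all(a$shape == b$shape))
  cp_cross(a, b) / sqrt(cp_cross(a, a) * cp_cross(b, b))
}
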