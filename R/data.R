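#' Assemble an image-classification dataset
#'
#' Bundles \eqn{n} equally shaped 3D volumes, one class label per volume,
#' and optionally a matrix of per-subject scalar covariates.  Volumes are
#' stored internally as an \eqn{n \times d_1 d_2 d_3} matrix of vectorized
#' images (first index varying fastest, R's native array order), which is
#' the layout all model computations use.
#'
#' @param images either a list of `n` numeric 3D arrays of identical shape,
#'   or a 4D array with the subject index last.
#' @param labels class labels, one per image; coerced to factor.  The
#'   factor level order defines the class order used everywhere else
#'   (e.g. when choosing the reference class).
#' @param covariates optional numeric matrix (`n` rows) of scalar
#'   covariates.
#' @param class_names optional character vector of levels, to fix a class
#'   order or include classes absent from `labels`.
#' @return an object of class `mtr_data` with fields `x` (the
#'   `n` by `prod(shape)` matrix), `shape`, `labels`, `covariates`.
#' @examples
#' imgs <- replicate(4, array(rnorm(8), c(2, 2, 2)), simplify = FALSE)
#' d <- mtr_data(imgs, c("a", "a", "b", "b"))
#' d
#' @export
mtr_data <- function(images, labels, covariates = NULL, class_names = NULL) {
  if (is.array(images) && length(dim(images)) == 4L) {
    shape <- dim(images)[1:3]
    n <- dim(images)[4L]
    x <- t(matrix(images, prod(shape), n))
  } else if (is.list(images)) {
    n <- length(images)
    if (n < 1L) stop("need at least one image")
    shape <- dim(images[[1L]])
    if (is.null(shape) || length(shape) != 3L)
      stop("images must be 3-way arrays")
    x <- matrix(0, n, prod(shape))
    for (i in seq_len(n)) {
      di <- dim(images[[i]])
      if (is.null(di) || !all(di == shape))
        stop(sprintf("image %d has shape (%s), expected (%s)", i,
                     paste(di, collapse = ", "),
                     paste(shape, collapse = ", ")))
      x[i, ] <- as.numeric(images[[i]])
    }
  } else stop("`images` must be a list of 3D arrays or a 4D array")
  if (any(!is.finite(x))) stop("images contain non-finite voxels")
  if (length(labels) != n)
    stop(sprintf("%d labels for %d images", length(labels), n))
  labels <- if (is.null(class_names)) factor(labels)
            else factor(labels, levels = class_names)
  if (anyNA(labels)) stop("labels contain values outside `class_names`")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per image")
    if (any(!is.finite(covariates))) stop("covariates must be finite")
  }
  structure(list(x = x, shape = as.integer(shape), labels = labels,
                 covariates = covariates),
            class = "mtr_data")
}

#' @export
print.mtr_data <- function(x, ...) {
  cat(sprintf("<mtr_data> %d volumes of shape (%s), %d voxels each\n",
              nrow(x$x), paste(x$shape, collapse = ", "), ncol(x$x)))
  print(table(x$labels))
  if (!is.null(x$covariates))
    cat(sprintf("%d scalar covariate(s)\n", ncol(x$covariates)))
  invisible(x)
}

#' Number of subjects in a dataset
#' @param data an [mtr_data()] object.
#' @export
n_subjects <- function(data) nrow(data$x)

#' Subset a dataset by subject index
#'
#' @param x an [mtr_data()] object.
#' @param i integer or logical subject index.
#' @param ... unused.
#' @return an `mtr_data` with the selected subjects, preserving the class
#'   level order (levels are never dropped).
#' @export
`[.mtr_data` <- function(x, i, ...) {
  structure(list(x = x$x[i, , drop = FALSE],
                 shape = x$shape,
                 labels = x$labels[i],
                 covariates = if (!is.null(x$covariates))
                   x$covariates[i, , drop = FALSE]),
            class = "mtr_data")
}

#' Retrieve one subject's volume as a 3D array
#' @param data an [mtr_data()] object.
#' @param i subject index.
#' @export
get_volume <- function(data, i) array(data$x[i, ], data$shape)

# n x K one-hot indicator matrix Y[i, k] of the labels.
one_hot <- function(labels) {
  k <- nlevels(labels)
  y <- matrix(0, length(labels), k,
              dimnames = list(NULL, levels(labels)))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}
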