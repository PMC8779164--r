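#' Prediction accuracy
#'
#' Fraction of correct classifications: number of matches divided by the
#' sample size.
#'
#' @param truth,predicted equal-length vectors of class labels.
#' @return fraction in \eqn{[0, 1]}.
#' @export
prediction_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop(sprintf("length mismatch: %d true labels, %d predictions",
                 length(truth), length(predicted)))
  if (length(truth) < 1L) stop("need at least one observation")
  mean(as.character(truth) == as.character(predicted))
}

#' Rand index between two partitions
#'
#' The plain (unadjusted) Rand index: the fraction of the
#' \eqn{\binom{n}{2}} subject pairs on which the two partitions agree —
#' either together in both or apart in both.  Computed from the
#' contingency table, and invariant to relabeling classes in either
#' argument.
#'
#' @param a,b equal-length label vectors (\eqn{n \ge 2}).
#' @return fraction in \eqn{[0, 1]}; 1 iff the partitions are identical
#'   up to relabeling.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 observations")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  same_same <- sum(choose2(tab))
  pairs <- choose2(n)
  agree <- pairs + 2 * same_same - sum(choose2(rowSums(tab))) -
    sum(choose2(colSums(tab)))
  agree / pairs
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected variant of [rand_index()]; provided for
#' completeness (the plain index is what the evaluation report uses).
#'
#' @inheritParams rand_index
#' @return value \eqn{\le 1}; 0 expected under independent random
#'   partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 observations")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' One-directional pairwise AUC
#'
#' \eqn{\hat A(i\,|\,j)}: the probability that a randomly chosen class-i
#' subject scores higher than a randomly chosen class-j subject, plus half
#' the tie probability, computed from the Mann-Whitney rank statistic
#' (midranks implement the half-tie convention).
#'
#' @param scores_i scores of the class-i subjects.
#' @param scores_j scores of the class-j subjects, on the same scale.
#' @return fraction in \eqn{[0, 1]}.
#' @export
pairwise_auc <- function(scores_i, scores_j) {
  ni <- length(scores_i); nj <- length(scores_j)
  if (ni < 1L || nj < 1L) stop("both score groups must be non-empty")
  r <- rank(c(scores_i, scores_j))
  (sum(r[seq_len(ni)]) - ni * (ni + 1) / 2) / (ni * nj)
}

#' Multi-class AUC by pairwise averaging (Hand-Till M)
#'
#' For every unordered class pair \eqn{\{i, j\}} the separability is
#' \eqn{[\hat A(i|j) + \hat A(j|i)]/2}, where \eqn{\hat A(i|j)} ranks the
#' two groups by class i's probability column and \eqn{\hat A(j|i)} by
#' class j's; the multi-class AUC is the mean over all
#' \eqn{K(K-1)/2} pairs.  With \eqn{K = 2} this reduces exactly to the
#' standard two-class AUC.  Invariant to any strictly increasing
#' transform applied per score column.
#'
#' @param prob \eqn{n \times K} matrix of class scores (typically the
#'   probabilities from [class_probabilities()]), columns in class order.
#' @param truth length-\eqn{n} vector of true labels; every class must be
#'   present.
#' @return the multi-class AUC, with the per-pair table attached as
#'   attribute `"pairs"`.
#' @export
multiclass_auc <- function(prob, truth) {
  prob <- as.matrix(prob)
  k <- ncol(prob)
  if (k < 2L) stop("need at least 2 classes")
  classes <- colnames(prob)
  if (is.null(classes)) classes <- as.character(seq_len(k))
  truth <- as.character(truth)
  missing <- setdiff(classes, unique(truth))
  if (length(missing) > 0L)
    stop(sprintf("class(es) absent from true labels: %s",
                 paste(missing, collapse = ", ")))
  pairs <- utils::combn(k, 2L)
  vals <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    in_i <- truth == classes[i]; in_j <- truth == classes[j]
    a_ij <- pairwise_auc(prob[in_i, i], prob[in_j, i])
    a_ji <- pairwise_auc(prob[in_j, j], prob[in_i, j])
    (a_ij + a_ji) / 2
  })
  tab <- data.frame(class_i = classes[pairs[1L, ]],
                    class_j = classes[pairs[2L, ]], auc = vals)
  structure(mean(vals), pairs = tab)
}

#' Evaluate a fitted model on a dataset
#'
#' Computes the three evaluation metrics — prediction accuracy (PA), Rand
#' index (RI) between the true and predicted partitions, and the
#' Hand-Till multi-class AUC (MAUC) — plus the confusion matrix.
#'
#' @param object an `mtr_fit` or [mtr_params()].
#' @param data an [mtr_data()] to evaluate on.
#' @return an object of class `mtr_report`: list with `pa`, `ri`, `mauc`,
#'   `pair_auc` (per-pair AUC table), `confusion` and `n`.
#' @export
mtr_evaluate <- function(object, data) {
  if (inherits(object, "mtr_fit")) object <- object$params
  mu <- class_probabilities(object, data)
  pred <- predict(object, data)
  mauc <- multiclass_auc(mu, data$labels)
  structure(list(pa = prediction_accuracy(data$labels, pred),
                 ri = rand_index(data$labels, pred),
                 mauc = as.numeric(mauc),
                 pair_auc = attr(mauc, "pairs"),
                 confusion = table(truth = data$labels, predicted = pred),
                 n = n_subjects(data)),
            class = "mtr_report")
}

#' @export
print.mtr_report <- function(x, ...) {
  cat(sprintf("<mtr_report> n = %d\n", x$n))
  cat(sprintf("  PA   %.4f\n  RI   %.4f\n  MAUC %.4f\n", x$pa, x$ri,
              x$mauc))
  cat("pairwise AUC:\n")
  print(x$pair_auc, row.names = FALSE)
  cat("confusion:\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as a tab-separated table
#'
#' One row per metric, followed by the per-pair AUC rows
#' (`auc:<class_i>|<class_j>`).
#'
#' @param report an `mtr_report` from [mtr_evaluate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mtr_report"))
  rows <- data.frame(
    metric = c("pa", "ri", "mauc", "n",
               sprintf("auc:%s|%s", report$pair_auc$class_i,
                       report$pair_auc$class_j)),
    value = c(report$pa, report$ri, report$mauc, report$n,
              report$pair_auc$auc))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
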