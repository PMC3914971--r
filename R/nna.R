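#' Cosine nearness between two sample vectors
#'
#' The dissimilarity used by the nearest-neighbour classifier:
#' \deqn{d(x, y) = 1 - \frac{x \cdot y}{\|x\| \, \|y\|}}
#' ranging over \[0, 2\]; smaller means more similar. Scale-invariant in each
#' argument (for positive scalars), which suits copy-number profiles measured
#' on an arbitrary per-array scale.
#'
#' @param x,y Numeric vectors of equal length with nonzero modulus.
#' @return Nearness value in \[0, 2\].
#' @examples
#' nearness(c(1, 2, 3), c(1, 2, 3))  # 0
#' nearness(c(1, 0), c(0, 1))        # 1
#' @export
nearness <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("zero-modulus vector: cosine nearness undefined")
  1 - sum(x * y) / (nx * ny)
}

# Full pairwise nearness matrix for the rows of X; errors on zero rows.
nearness_matrix <- function(X) {
  g <- tcrossprod(X)
  nrm <- sqrt(diag(g))
  if (any(nrm == 0))
    stop("zero-modulus sample vector(s): ",
         paste(rownames(X)[nrm == 0], collapse = ", "))
  1 - g / outer(nrm, nrm)
}

#' Predict the class of a query sample by the nearest training sample
#'
#' Returns the label of the training sample with minimal cosine [nearness] to
#' the query; ties are broken by training-sample order (first wins).
#'
#' @param train A [cna_matrix] (optionally restricted to a probe subset).
#' @param query Numeric vector, one value per probe of `train`.
#' @param probe_subset Optional character vector of probe ids (or integer
#'   indices) restricting the feature space; `query` must then match the
#'   subset length and order.
#' @return The predicted class label (character).
#' @export
nna_predict <- function(train, query, probe_subset = NULL) {
  validate_cna_matrix(train)
  X <- restrict_probes(train, probe_subset)
  if (length(query) != ncol(X))
    stop("query length ", length(query), " != probe count ", ncol(X))
  nq <- sqrt(sum(query^2))
  if (nq == 0) stop("zero-modulus query vector")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("zero-modulus training sample(s): ",
         paste(rownames(X)[nrm == 0], collapse = ", "))
  d <- 1 - as.vector(X %*% query) / (nrm * nq)
  train$labels[which.min(d)]
}

restrict_probes <- function(x, probe_subset) {
  if (is.null(probe_subset)) return(x$values)
  if (is.character(probe_subset)) {
    missing <- setdiff(probe_subset, colnames(x$values))
    if (length(missing))
      stop("probe(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  x$values[, probe_subset, drop = FALSE]
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integers: true positives, true negatives,
#'   false positives, false negatives.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion: TP=", x$tp, " TN=", x$tn, " FP=", x$fp, " FN=", x$fn,
      " (n=", x$tp + x$tn + x$fp + x$fn, ")\n", sep = "")
  invisible(x)
}

#' Leave-one-out (jackknife) cross-validation of the nearest-neighbour classifier
#'
#' Every sample is predicted by the classifier trained on all other samples;
#' predictions are tallied against the positive/negative convention of the
#' matrix (positive = ACA by default). Counts always sum to the number of
#' samples.
#'
#' @param x A [cna_matrix].
#' @param probe_subset Optional probe ids or indices restricting the feature
#'   space.
#' @return A [confusion_counts] object.
#' @export
loocv_confusion <- function(x, probe_subset = NULL) {
  validate_cna_matrix(x)
  pos <- is_positive(x)
  if (!any(pos) || all(pos))
    stop("both classes must be present for LOOCV")
  if (min(sum(pos), sum(!pos)) < 2L)
    warning("a class has fewer than 2 samples; ",
            "its members cannot have a same-class neighbour")
  X <- restrict_probes(x, probe_subset)
  d <- nearness_matrix(X)
  diag(d) <- Inf                      # the held-out sample never trains itself
  nn <- vapply(seq_len(nrow(d)), function(i) which.min(d[i, ]), 0L)
  pred_pos <- pos[nn]
  confusion_counts(tp = sum(pred_pos & pos),  tn = sum(!pred_pos & !pos),
                   fp = sum(pred_pos & !pos), fn = sum(!pred_pos & pos))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP), \quad
#'       Acc = (TP+TN)/n}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' If any factor of the MCC denominator is zero, MCC is defined as 0
#' (standard convention). Values are returned at full precision; the
#' print method displays 4 decimals.
#'
#' @param counts A [confusion_counts] object.
#' @return A `performance_metrics` object: list with `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' classification_metrics(confusion_counts(tp = 199, tn = 60, fp = 33, fn = 9))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  structure(list(sn = tp / (tp + fn), sp = tn / (tn + fp),
                 acc = (tp + tn) / total, mcc = mcc),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f\n",
              x$sn, x$sp, x$acc, x$mcc))
  invisible(x)
}
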