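#' Area under the ROC curve
#'
#' Exact AUROC via the Mann-Whitney rank identity: the probability that a
#' random positive scores above a random negative, with ties counted
#' one-half (midranks).  Equivalent to trapezoidal integration of the
#' empirical ROC curve, with no interpolation.
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise precision envelope: scores sorted decreasing, tied scores
#' grouped, AUPRC = sum over threshold steps of
#' (recall step) x (precision at that threshold).  At recall 0 the curve
#' starts from the first threshold's precision (no extrapolated point is
#' added), the convention under which a perfect ranker scores 1.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == length(labels))
    stop("AUPRC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  # cumulative counts at each distinct-score threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]
  n_pred <- seq_along(y)[keep]
  prec <- tp / n_pred
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Threshold-free and thresholded evaluation metrics
#'
#' One pass over scores and labels yielding AUROC, AUPRC, accuracy, F1,
#' Matthews correlation coefficient, Brier score loss and the 2x2
#' confusion matrix at the given threshold.  Scores equal to the
#' threshold classify as positive.  MCC is defined as 0 when any
#' marginal of the confusion matrix is empty.
#'
#' @inheritParams auroc
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @return object of class `metric_report`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(threshold > 0, threshold < 1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  n <- length(labels)
  acc <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  structure(list(
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    accuracy = acc, f1 = f1, mcc = mcc,
    brier = mean((scores - labels)^2),
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(predicted = c("1", "0"),
                                       actual = c("1", "0"))),
    threshold = threshold, n = n
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("<metric_report> n =", x$n, " threshold =", x$threshold, "\n")
  v <- unlist(x[c("auroc", "auprc", "accuracy", "f1", "mcc", "brier")])
  print(round(v, digits))
  cat("confusion (rows predicted, cols actual):\n")
  print(x$confusion)
  invisible(x)
}

#' Shapley-style feature attribution by permutation sampling
#'
#' Model-agnostic Shapley value estimates at whole-feature granularity: a
#' categorical feature's value is toggled as one unit (never individual
#' one-hot indicators).  For each record and each sampled feature
#' permutation, features are switched one at a time from a background
#' record's values to the record's own, and the score changes are
#' accumulated as marginal contributions.  Each permutation telescopes
#' exactly, so summed contributions plus the background base value equal
#' the record's score (local accuracy holds by construction, up to
#' background sampling in the base value).
#'
#' @param score_fun function taking a data frame of records and returning
#'   a numeric score per row (e.g. a [predict_efcn()] closure).
#' @param records data frame of records to explain.
#' @param background data frame of background records to sample reference
#'   values from.
#' @param features character vector of feature columns to attribute over.
#' @param n_perm permutations sampled per record.
#' @param seed RNG seed; estimates are deterministic given it.
#' @param threshold records are grouped by predicted class at this
#'   threshold for the per-class mean attribution summary.
#' @return object of class `attribution_report`: `per_record` matrix
#'   (records x features), per-record `base_value` (mean score of the
#'   sampled backgrounds, so `base_value + rowSums(per_record) = scores`
#'   exactly), `scores`, and `per_class_mean` (features x predicted class).
#' @export
attribution <- function(score_fun, records, background, features,
                        n_perm = 32L, seed = 1L, threshold = 0.5) {
  stopifnot(nrow(background) >= 1, n_perm >= 1)
  n <- nrow(records)
  k <- length(features)
  phi <- matrix(0, n, k, dimnames = list(NULL, features))
  base_acc <- numeric(n)
  withr_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample.int(k)
      b_idx <- sample.int(nrow(background), n, replace = TRUE)
      cur <- records
      for (f in features) cur[[f]] <- background[[f]][b_idx]
      prev <- score_fun(cur)
      base_acc <- base_acc + prev / n_perm
      for (j in perm) {
        f <- features[j]
        cur[[f]] <- records[[f]]
        s <- score_fun(cur)
        phi[, j] <- phi[, j] + (s - prev) / n_perm
        prev <- s
      }
    }
  })
  scores <- score_fun(records)
  cls <- factor(as.integer(scores >= threshold), levels = c(0, 1))
  per_class <- sapply(levels(cls), function(l) {
    idx <- cls == l
    if (!any(idx)) rep(NA_real_, k) else colMeans(phi[idx, , drop = FALSE])
  })
  rownames(per_class) <- features
  structure(list(per_record = phi, base_value = base_acc, scores = scores,
                 per_class_mean = per_class, n_perm = n_perm, seed = seed),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, digits = 4, ...) {
  cat("<attribution_report>", nrow(x$per_record), "records,",
      ncol(x$per_record), "features,", x$n_perm, "permutations\n")
  cat("mean |attribution| by feature (top 10):\n")
  m <- sort(colMeans(abs(x$per_record)), decreasing = TRUE)
  print(round(utils::head(m, 10), digits))
  invisible(x)
}
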