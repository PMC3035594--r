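#' Top-scoring-pair (TSP) ranking of feature pairs
#'
#' Scores every unordered feature pair (i, j), i < j lexicographically, by
#' the between-class difference in the empirical probability of the strict
#' event `X_i < X_j`:
#' `delta = |P(X_i < X_j | class 1) - P(X_i < X_j | class 2)|`.
#' Ties (`X_i == X_j`) count as event-false, so the score is well defined on
#' discretized data. Because only the within-sample ordering of the two
#' features enters, delta is invariant under any strictly monotone
#' per-sample transformation. A secondary score `gamma`, the between-class
#' difference in mean within-pair rank gap, breaks ties among delta-equal
#' pairs; remaining ties resolve lexicographically, making the ranking
#' total.
#'
#' @param m Numeric matrix, features x samples.
#' @param labels Class label per column; exactly two distinct values, each
#'   with >= 1 sample.
#' @return Data frame sorted by `delta` desc, `gamma` desc, then pair id:
#'   `feature_i`, `feature_j`, `delta`, `gamma`, `p1`, `p2` (per-class event
#'   probabilities; class 1 is the lexicographically smaller label),
#'   `class_if_less` (predicted class when `X_i < X_j`), `class_other`, and
#'   `tie_class` (prediction when `X_i == X_j`: the class with the higher
#'   training prevalence of the false event).
#' @export
tsp_scores <- function(m, labels) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) stop("TSP requires exactly two classes")
  if (nrow(m) < 2L) stop("need >= 2 features")
  m <- m[order(rownames(m)), , drop = FALSE]
  i1 <- which(labels == classes[1L]); i2 <- which(labels == classes[2L])
  p <- nrow(m); ids <- rownames(m)
  R <- apply(m, 2L, rank)
  a <- rowMeans(R[, i1, drop = FALSE]); b <- rowMeans(R[, i2, drop = FALSE])
  res <- vector("list", p - 1L)
  for (i in seq_len(p - 1L)) {
    jj <- (i + 1L):p
    ev <- sweep(m[jj, , drop = FALSE], 2L, m[i, ], FUN = ">")  # X_i < X_j
    p1 <- rowMeans(ev[, i1, drop = FALSE])
    p2 <- rowMeans(ev[, i2, drop = FALSE])
    gamma <- abs((a[i] - a[jj]) - (b[i] - b[jj]))
    res[[i]] <- data.frame(
      feature_i = ids[i], feature_j = ids[jj],
      delta = abs(p1 - p2), gamma = gamma, p1 = p1, p2 = p2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$class_if_less <- ifelse(out$p1 > out$p2, classes[1L],
                              ifelse(out$p2 > out$p1, classes[2L], classes[1L]))
  out$class_other <- ifelse(out$class_if_less == classes[1L],
                            classes[2L], classes[1L])
  out$tie_class <- ifelse(out$p1 < out$p2, classes[1L],
                          ifelse(out$p2 < out$p1, classes[2L], classes[1L]))
  out <- out[order(-out$delta, -out$gamma, out$feature_i, out$feature_j), ]
  rownames(out) <- NULL
  out
}

#' Classify a sample with a scored feature pair
#'
#' Applies a pair's orientation rule: predict `class_if_less` when the
#' sample has `X_i < X_j`, the other class when `X_i > X_j`, and the pair's
#' recorded `tie_class` on equality.
#'
#' @param pair One row of a [tsp_scores()] result.
#' @param x Named numeric vector of feature values for one sample.
#' @return The predicted class label.
#' @export
tsp_classify <- function(pair, x) {
  fi <- pair$feature_i[1L]; fj <- pair$feature_j[1L]
  if (!all(c(fi, fj) %in% names(x)))
    stop("sample vector is missing feature(s): ",
         paste(setdiff(c(fi, fj), names(x)), collapse = ", "))
  if (x[[fi]] < x[[fj]]) pair$class_if_less[1L]
  else if (x[[fi]] > x[[fj]]) pair$class_other[1L]
  else pair$tie_class[1L]
}

#' Leave-one-out cross-validation of the top-scoring pair
#'
#' In each fold the full pair ranking is recomputed on the training samples
#' and the held-out sample is classified by the fold's top pair. The
#' procedure contains no randomness.
#'
#' @param m Numeric matrix, features x samples.
#' @param labels Class label per column; >= 2 samples per class.
#' @return List: `accuracy` (fraction of held-out samples correctly
#'   labeled) and `folds` (data frame: sample, truth, predicted, and the
#'   fold's chosen pair).
#' @export
tsp_cv <- function(m, labels) {
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) stop("LOOCV needs >= 2 samples per class")
  n <- ncol(m)
  folds <- vector("list", n)
  for (s in seq_len(n)) {
    tr_labels <- labels[-s]
    if (length(unique(tr_labels)) < 2L)
      stop("a class is absent from the training fold")
    sc <- tsp_scores(m[, -s, drop = FALSE], tr_labels)
    top <- sc[1L, ]
    pred <- tsp_classify(top, m[, s])
    folds[[s]] <- data.frame(sample = colnames(m)[s] %||% as.character(s),
                             truth = labels[s], predicted = pred,
                             feature_i = top$feature_i,
                             feature_j = top$feature_j,
                             delta = top$delta,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  list(accuracy = mean(folds$predicted == folds$truth), folds = folds)
}
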