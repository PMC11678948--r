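#' k-nearest-neighbour prediction
#'
#' Euclidean k-NN with majority vote. Voting ties are broken
#' deterministically by the class of the nearest neighbour among the tied
#' classes, and equal distances rank by training-row order, so predictions
#' are reproducible. If the training set has fewer rows than `k`, `k` is
#' reduced to `nrow(x_train) - 1` (floor 1) with a warning.
#'
#' @param x_train numeric training matrix (rows = samples).
#' @param y_train factor (or coercible) of training labels.
#' @param x_test numeric matrix of query samples.
#' @param k number of neighbours (default 5).
#' @return Factor of predicted labels with the levels of `y_train`.
#' @export
knn_predict <- function(x_train, y_train, x_test, k = 5) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- as.factor(y_train)
  n_train <- nrow(x_train)
  if (ncol(x_train) != ncol(x_test))
    stop("'x_train' and 'x_test' must have the same number of columns")
  if (n_train < k) {
    k <- max(1L, n_train - 1L)
    warning("fewer training samples than neighbours; using k = ", k)
  }

  d2 <- outer(rowSums(x_test^2), rep(1, n_train)) +
    outer(rep(1, nrow(x_test)), rowSums(x_train^2)) -
    2 * tcrossprod(x_test, x_train)

  lv <- levels(y_train)
  pred <- vapply(seq_len(nrow(x_test)), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]
    classes <- y_train[ord]
    counts <- tabulate(classes, nbins = length(lv))
    top <- which(counts == max(counts))
    if (length(top) == 1L) return(lv[top])
    # tie: class of the nearest neighbour belonging to a tied class
    lv[as.integer(classes[match(TRUE, as.integer(classes) %in% top)])]
  }, character(1))
  factor(pred, levels = lv)
}

# Min-max scaling using training statistics only; constant columns map to 0.
scale_minmax <- function(train, test = NULL) {
  train <- as.matrix(train)
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  sc <- function(x) sweep(sweep(as.matrix(x), 2L, lo), 2L, rng, "/")
  list(train = sc(train), test = if (!is.null(test)) sc(test))
}
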