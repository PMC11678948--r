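# Minimal binary soft-margin SVM trained by sequential minimal optimization.
# Exists because no SVM package ships with the runtime; the deterministic
# working-pair heuristic (second index chosen by maximum |E_i - E_j|) keeps
# fits reproducible without consuming the RNG stream.

rbf_kernel <- function(a, b, gamma) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Train an RBF-kernel support vector machine
#'
#' Binary soft-margin SVM solved in the dual by a simplified sequential
#' minimal optimization loop. The second class level is treated as the
#' positive class. Intended for the fall-detection demonstration, where the
#' classifier inside the wrapper fitness is an SVM; inputs are expected
#' pre-scaled (the cross-validation driver min-max scales per training fold).
#'
#' @param x numeric matrix, samples by features.
#' @param y two-level factor (or coercible).
#' @param cost box constraint `C` (default 1).
#' @param gamma RBF width; default `1/ncol(x)`.
#' @param tol KKT violation tolerance (default 1e-3).
#' @param max_passes maximum full passes without progress before stopping.
#' @return Object of class `"spiral_svm"`.
#' @export
svm_train <- function(x, y, cost = 1, gamma = NULL, tol = 1e-3,
                      max_passes = 200) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("'y' must have exactly two classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  yy <- ifelse(y == levels(y)[2L], 1, -1)
  n <- nrow(x)

  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n)
  b <- 0
  f <- numeric(n)  # decision values sum(alpha*y*K) + b, b tracked separately

  passes <- 0L
  sweeps <- 0L
  while (passes < max_passes && sweeps < 500L) {
    sweeps <- sweeps + 1L
    changed <- 0L
    E <- f + b - yy
    for (i in seq_len(n)) {
      Ei <- f[i] + b - yy[i]
      if ((yy[i] * Ei < -tol && alpha[i] < cost) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        E <- f + b - yy
        # try partners in decreasing |Ei - Ej| order until one admits progress
        cand <- setdiff(order(-abs(Ei - E)), i)
        for (j in cand) {
          Ej <- E[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (yy[i] != yy[j]) {
            L <- max(0, aj_old - ai_old); H <- min(cost, cost + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - cost); H <- min(cost, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - yy[j] * (Ei - Ej) / eta
          aj <- min(max(aj, L), H)
          if (abs(aj - aj_old) < 1e-7) next
          ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
          alpha[i] <- ai; alpha[j] <- aj
          f <- f + (ai - ai_old) * yy[i] * K[, i] +
            (aj - aj_old) * yy[j] * K[, j]
          b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
            yy[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
            yy[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < cost) b1
               else if (aj > 0 && aj < cost) b2
               else (b1 + b2) / 2
          changed <- changed + 1L
          break
        }
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    if (changed == 0L) break
  }

  sv <- alpha > 1e-8
  structure(list(x = x[sv, , drop = FALSE], coef = (alpha * yy)[sv], b = b,
                 gamma = gamma, levels = levels(y)),
            class = "spiral_svm")
}

#' Predict with a trained SVM
#'
#' @param object a `"spiral_svm"` from [svm_train()].
#' @param newdata numeric matrix of query samples.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.spiral_svm <- function(object, newdata, ...) {
  if (nrow(object$x) == 0L)
    return(factor(rep(object$levels[1L], nrow(as.matrix(newdata))),
                  levels = object$levels))
  dec <- rbf_kernel(as.matrix(newdata), object$x, object$gamma) %*%
    object$coef + object$b
  factor(ifelse(dec >= 0, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}
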