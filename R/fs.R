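#' Fitness specification for wrapper feature selection
#'
#' Bundles the evaluation settings of the subset-scoring function: the
#' error-rate weight `alpha` (subset-size weight is `1 - alpha`), the
#' binarization threshold applied to continuous positions, the neighbour
#' count of the k-NN evaluator, the number of stratified cross-validation
#' folds, and the classifier used inside the fitness (`"knn"` for the
#' benchmark protocol, `"svm"` for the fall-detection demo).
#'
#' @param alpha error-rate weight in `[0, 1]` (default 0.99, so classification
#'   error dominates and the subset-size term breaks ties).
#' @param threshold binarization cut on position components (default 0.5).
#' @param k_neighbors neighbours of the k-NN evaluator (default 5).
#' @param folds cross-validation folds (default 5).
#' @param classifier `"knn"` or `"svm"`.
#' @return An object of class `"fitness_spec"`.
#' @export
fitness_spec <- function(alpha = 0.99, threshold = 0.5, k_neighbors = 5,
                         folds = 5, classifier = c("knn", "svm")) {
  classifier <- match.arg(classifier)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (folds < 2) stop("'folds' must be at least 2")
  if (k_neighbors < 1) stop("'k_neighbors' must be at least 1")
  structure(list(alpha = alpha, beta = 1 - alpha, threshold = threshold,
                 k_neighbors = k_neighbors, folds = folds,
                 classifier = classifier),
            class = "fitness_spec")
}

#' Binarize a continuous position into a feature mask
#'
#' A feature is selected when its position component strictly exceeds the
#' threshold; a component exactly at the threshold is not selected.
#'
#' @param position numeric vector in the unit box.
#' @param threshold cut point (default 0.5).
#' @return Logical mask of the same length.
#' @export
binarize <- function(position, threshold = 0.5) {
  if (any(!is.finite(position))) stop("position components must be finite")
  position > threshold
}

#' Subset fitness: weighted error rate plus size penalty
#'
#' `fitness = alpha * error_rate + (1 - alpha) * n_selected / n_total`,
#' minimized. The empty subset is assigned the worst attainable value, 1,
#' so the optimizer is driven away from all-zero masks without biasing
#' positions.
#'
#' @param error_rate cross-validated misclassification rate in `[0, 1]`.
#' @param n_selected number of selected features.
#' @param n_total total number of features.
#' @param spec a [fitness_spec()].
#' @return Scalar fitness in `[0, 1]`.
#' @examples
#' fs_fitness(0, 50, 50)          # 0.01
#' fs_fitness(0.2, 5, 50)         # 0.199
#' @export
fs_fitness <- function(error_rate, n_selected, n_total,
                       spec = fitness_spec()) {
  if (n_total < 1) stop("'n_total' must be at least 1")
  if (n_selected < 0 || n_selected > n_total)
    stop("'n_selected' must lie in [0, n_total]")
  if (error_rate < 0 || error_rate > 1)
    stop("'error_rate' must lie in [0, 1]")
  if (n_selected == 0) return(1.0)
  spec$alpha * error_rate + spec$beta * n_selected / n_total
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds, keeping class proportions near-equal per fold.
make_cv_folds <- function(y, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  assignment <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Cross-validated error rate of a feature subset
#'
#' Mean misclassification rate over stratified cross-validation folds of the
#' classifier named in `spec`, restricted to the masked columns. Features are
#' min-max scaled to `[0, 1]` using each training fold's statistics only, so
#' no information leaks from the validation fold.
#'
#' @param x numeric matrix (rows = samples).
#' @param y labels (factor or coercible).
#' @param mask logical vector selecting columns; must select at least one.
#' @param spec a [fitness_spec()].
#' @param fold_id optional integer fold assignment per row; generated
#'   (stratified, from `seed` or the current RNG stream) when `NULL`.
#' @param seed optional seed for the fold assignment.
#' @return Mean fold error rate in `[0, 1]`.
#' @export
cv_error <- function(x, y, mask, spec = fitness_spec(), fold_id = NULL,
                     seed = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (length(mask) != ncol(x)) stop("'mask' length must equal ncol(x)")
  if (!any(mask)) stop("'mask' selects no features")
  if (is.null(fold_id)) fold_id <- make_cv_folds(y, spec$folds, seed)

  xs <- x[, mask, drop = FALSE]
  errs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    sc <- scale_minmax(xs[tr, , drop = FALSE], xs[!tr, , drop = FALSE])
    pred <- if (spec$classifier == "knn") {
      knn_predict(sc$train, y[tr], sc$test, k = spec$k_neighbors)
    } else {
      fit <- svm_train(sc$train, y[tr])
      predict(fit, sc$test)
    }
    mean(pred != y[!tr])
  }, numeric(1))
  mean(errs)
}

# Stratified train/test split; test fraction 0.2, at least one test sample
# per class. Consumes the current RNG stream.
stratified_split <- function(y, train_frac = 0.8) {
  y <- as.factor(y)
  test_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round((1 - train_frac) * length(idx)))
    test_idx <- c(test_idx, idx[sample.int(length(idx), n_test)])
  }
  list(train = setdiff(seq_along(y), test_idx), test = sort(test_idx))
}

#' Select features with a whale-optimization wrapper
#'
#' End-to-end protocol: the data are split into a stratified 80/20
#' train/test partition; the optimizer ([mswoa_run()] or [woa_run()])
#' minimizes the subset fitness (cross-validated error of the classifier on
#' the training partition plus size penalty, [fs_fitness()]) over continuous
#' positions in the unit box, thresholded by [binarize()]. Fold assignment is
#' fixed once per run, so the fitness is a deterministic function of the
#' mask, and evaluated masks are cached. The held-out 20% is touched exactly
#' once, to report test accuracy of the classifier refitted on the full
#' training partition with the selected features.
#'
#' @param x numeric matrix, samples by features.
#' @param y class labels (at least two classes, at least 10 samples).
#' @param algorithm `"mswoa"` (default) or `"woa"`.
#' @param spec a [fitness_spec()].
#' @param n_agents,max_iter optimizer budget (defaults 10 and 100).
#' @param seed integer seed controlling the split, the folds and the
#'   optimizer; identical seeds give identical results.
#' @param ... further arguments passed to the optimizer (e.g. `gamma`,
#'   `regroup_period`).
#' @return Object of class `"fs_result"`: `mask`, `selected` (indices),
#'   `n_selected`, `best_fitness`, `cv_error` (of the best mask), `history`,
#'   `test_accuracy` (percent), `train_idx`, `fold_id`, `n_evals`,
#'   `wall_time` (seconds), `seed`, `algorithm`.
#' @export
select_features <- function(x, y, algorithm = c("mswoa", "woa"),
                            spec = fitness_spec(), n_agents = 10,
                            max_iter = 100, seed = NULL, ...) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) < 10) stop("need at least 10 samples")
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  d <- ncol(x)
  t0 <- proc.time()[["elapsed"]]

  if (!is.null(seed)) set.seed(seed)
  split <- stratified_split(y, 0.8)
  x_tr <- x[split$train, , drop = FALSE]
  y_tr <- y[split$train]
  fold_id <- make_cv_folds(y_tr, spec$folds)
  opt_seed <- sample.int(.Machine$integer.max, 1L)

  cache <- new.env(parent = emptyenv())
  objective <- function(position) {
    mask <- binarize(position, spec$threshold)
    if (!any(mask)) return(1.0)
    key <- paste(which(mask), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fs_fitness(cv_error(x_tr, y_tr, mask, spec, fold_id = fold_id),
                      sum(mask), d, spec)
    cache[[key]] <- val
    val
  }

  run <- if (algorithm == "mswoa") {
    mswoa_run(objective, d, n_agents = n_agents, max_iter = max_iter,
              seed = opt_seed, ...)
  } else {
    woa_run(objective, d, n_agents = n_agents, max_iter = max_iter,
            seed = opt_seed, ...)
  }

  mask <- binarize(run$best_position, spec$threshold)
  test_acc <- NA_real_
  best_err <- NA_real_
  if (any(mask)) {
    best_err <- cv_error(x_tr, y_tr, mask, spec, fold_id = fold_id)
    sc <- scale_minmax(x_tr[, mask, drop = FALSE],
                       x[split$test, mask, drop = FALSE])
    pred <- if (spec$classifier == "knn") {
      knn_predict(sc$train, y_tr, sc$test, k = spec$k_neighbors)
    } else {
      predict(svm_train(sc$train, y_tr), sc$test)
    }
    test_acc <- 100 * mean(pred == y[split$test])
  } else {
    warning("optimizer returned an empty mask")
  }

  structure(
    list(mask = mask, selected = which(mask), n_selected = sum(mask),
         best_fitness = run$best_fitness, cv_error = best_err,
         history = run$history, test_accuracy = test_acc,
         train_idx = split$train, test_idx = split$test, fold_id = fold_id,
         n_evals = run$n_evals,
         wall_time = proc.time()[["elapsed"]] - t0,
         seed = seed, algorithm = algorithm),
    class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf(
    "<fs_result: %s> %d features selected, fitness = %.4f, test accuracy = %s\n",
    x$algorithm, x$n_selected, x$best_fitness,
    if (is.na(x$test_accuracy)) "NA" else sprintf("%.4f%%", x$test_accuracy)))
  invisible(x)
}

#' Read a delimited feature matrix with a label column
#'
#' Accepts CSV or TSV (delimiter sniffed from the header line when not
#' given). The label column is named via `label`, given as an index, or taken
#' as the last column by default; all remaining columns must be numeric.
#'
#' @param path file path.
#' @param label label column name or index (`NULL` = last column).
#' @param sep field delimiter; `NULL` to sniff tab vs comma.
#' @param header does the file have a header line (default `TRUE`).
#' @return List with `x` (numeric matrix) and `y` (factor).
#' @export
read_fs_dataset <- function(path, label = NULL, sep = NULL, header = TRUE) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  col <- if (is.null(label)) ncol(df)
         else if (is.character(label)) match(label, names(df))
         else as.integer(label)
  if (is.na(col) || col < 1 || col > ncol(df)) stop("label column not found")
  y <- as.factor(df[[col]])
  x <- as.matrix(df[, -col, drop = FALSE])
  if (!is.numeric(x)) stop("feature columns must be numeric")
  list(x = x, y = y)
}

#' Serialize a feature-selection result
#'
#' Writes the result record as JSON (mask stored as selected indices) and,
#' optionally, the convergence history as a two-column CSV
#' (`iteration`, `best_fitness`).
#'
#' @param result an `"fs_result"`.
#' @param path JSON output path.
#' @param history_csv optional CSV path for the convergence curve.
#' @return Invisibly, the JSON path.
#' @export
write_fs_result <- function(result, path, history_csv = NULL) {
  rec <- list(algorithm = result$algorithm, seed = result$seed,
              selected = result$selected, n_selected = result$n_selected,
              best_fitness = result$best_fitness, cv_error = result$cv_error,
              test_accuracy = result$test_accuracy,
              n_evals = result$n_evals, wall_time = result$wall_time)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(history_csv)) {
    utils::write.csv(
      data.frame(iteration = seq_along(result$history) - 1L,
                 best_fitness = result$history),
      history_csv, row.names = FALSE)
  }
  invisible(path)
}
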