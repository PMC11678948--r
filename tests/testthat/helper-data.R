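# Small fixtures built in code.

# Two well-separated Gaussian clouds; feature 1 carries the signal, the
# remaining columns are pure noise.
separable_clouds <- function(n_per_class = 20, n_noise = 2, gap = 10,
                             seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n_per_class))
  x1 <- c(rnorm(n_per_class, 0, 0.5), rnorm(n_per_class, gap, 0.5))
  x <- cbind(x1, matrix(rnorm(2 * n_per_class * n_noise), ncol = n_noise))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = y)
}

# Exhaustive oracle: best attainable subset fitness over all non-empty masks,
# using the same folds as a select_features() run.
enumerate_mask_fitness <- function(x, y, train_idx, fold_id, spec) {
  d <- ncol(x)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))[-1, ]
  apply(masks, 1L, function(mask) {
    fs_fitness(cv_error(x[train_idx, , drop = FALSE], y[train_idx],
                        as.logical(mask), spec, fold_id = fold_id),
               sum(mask), d, spec)
  })
}
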