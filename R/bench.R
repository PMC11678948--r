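#' Repeated-run feature-selection trials with paired seeds
#'
#' Runs each algorithm `n_runs` times on the same dataset; run `r` uses seed
#' `base_seed + r` for every algorithm, so competing algorithms see exactly
#' the same train/test split, fold assignment and initial-population draws,
#' enabling paired comparisons. Failed runs are dropped with a warning and
#' the per-algorithm run count adjusted.
#'
#' @param x,y feature matrix and labels (see [select_features()]).
#' @param algorithms character vector of algorithm ids (`"mswoa"`, `"woa"`).
#' @param n_runs repetitions (protocol default 30).
#' @param base_seed integer; run `r` is seeded `base_seed + r`.
#' @param spec a [fitness_spec()].
#' @param n_agents,max_iter optimizer budget per run.
#' @param dataset_id label used in the summary table.
#' @param out_dir optional directory; when given, the summary and the mean
#'   convergence curves are written as CSV.
#' @param ... passed on to [select_features()].
#' @return List with `summary` (one row per algorithm: mean/sd accuracy,
#'   mean selected features, mean/sd fitness, mean runtime, `n_runs`),
#'   `runs` (per-algorithm list of `"fs_result"` records) and `curves`
#'   (matrix of mean best-fitness per iteration, one column per algorithm).
#' @export
run_trials <- function(x, y, algorithms = c("mswoa", "woa"), n_runs = 30,
                       base_seed = 1, spec = fitness_spec(), n_agents = 10,
                       max_iter = 100, dataset_id = "dataset",
                       out_dir = NULL, ...) {
  runs <- stats::setNames(vector("list", length(algorithms)), algorithms)
  for (algo in algorithms) {
    runs[[algo]] <- lapply(seq_len(n_runs), function(r) {
      tryCatch(
        select_features(x, y, algorithm = algo, spec = spec,
                        n_agents = n_agents, max_iter = max_iter,
                        seed = base_seed + r, ...),
        error = function(e) {
          warning(sprintf("run %d of %s failed: %s", r, algo,
                          conditionMessage(e)))
          NULL
        })
    })
    runs[[algo]] <- Filter(Negate(is.null), runs[[algo]])
  }

  summary <- do.call(rbind, lapply(algorithms, function(algo) {
    rr <- runs[[algo]]
    acc <- vapply(rr, `[[`, numeric(1), "test_accuracy")
    fit <- vapply(rr, `[[`, numeric(1), "best_fitness")
    nf <- vapply(rr, `[[`, numeric(1), "n_selected")
    tm <- vapply(rr, `[[`, numeric(1), "wall_time")
    data.frame(dataset = dataset_id, algorithm = algo, n_runs = length(rr),
               mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
               mean_n_selected = mean(nf),
               mean_fitness = mean(fit), sd_fitness = stats::sd(fit),
               mean_time = mean(tm), stringsAsFactors = FALSE)
  }))

  curves <- vapply(algorithms, function(algo) {
    rowMeans(vapply(runs[[algo]], `[[`, numeric(max_iter), "history"))
  }, numeric(max_iter))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(
      cbind(data.frame(iteration = seq_len(max_iter) - 1L), curves),
      file.path(out_dir, "convergence.csv"), row.names = FALSE)
  }

  list(summary = summary, runs = runs, curves = curves)
}

#' Pairwise significance label
#'
#' Two-sided Wilcoxon rank-sum test on run-level metric samples of a proposed
#' method (`a`) against a competitor (`b`) at level `alpha`: `"+"` when the
#' difference is significant and `a`'s mean is better, `"-"` when significant
#' and worse, `"≈"` otherwise. Identical samples are `"≈"` by definition;
#' fewer than 3 values per side yields `"≈"` with a warning.
#'
#' @param a,b numeric metric samples (one value per run).
#' @param higher_better is a larger metric better (accuracy) or worse
#'   (fitness, subset size)?
#' @param alpha significance level (default 0.05).
#' @return One of `"+"`, `"-"`, `"≈"`.
#' @export
significance_label <- function(a, b, higher_better = TRUE, alpha = 0.05) {
  if (length(a) == length(b) && isTRUE(all(a == b))) return("≈")
  if (length(a) < 3 || length(b) < 3) {
    warning("fewer than 3 runs per sample; returning '≈'")
    return("≈")
  }
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  if (is.na(p) || p >= alpha) return("≈")
  a_better <- if (higher_better) mean(a) > mean(b) else mean(a) < mean(b)
  if (a_better) "+" else "-"
}

#' Export a benchmark table as CSV and Markdown
#'
#' Rows are datasets, columns algorithms. The Markdown rendering bolds the
#' best value per row and appends an `Ave` row (column means over datasets)
#' and a `Rank` row (rank of the averages, 1 = best).
#'
#' @param tab numeric `data.frame` or matrix, datasets x algorithms, with row
#'   names.
#' @param out_dir output directory (created if needed).
#' @param name file stem; writes `<name>.csv` and `<name>.md`.
#' @param higher_better direction of "best" (default `TRUE`).
#' @param digits decimals in the Markdown table (default 4).
#' @return Invisibly, the two file paths.
#' @export
export_tables <- function(tab, out_dir, name, higher_better = TRUE,
                          digits = 4) {
  tab <- as.data.frame(tab)
  if (is.null(rownames(tab))) rownames(tab) <- paste0("dataset", seq_len(nrow(tab)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ave <- colMeans(tab)
  rk <- if (higher_better) rank(-ave, ties.method = "min")
        else rank(ave, ties.method = "min")

  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  full <- rbind(tab, Ave = ave, Rank = rk)
  utils::write.csv(cbind(dataset = rownames(full), full), csv_path,
                   row.names = FALSE)

  fmt <- function(v) formatC(v, digits = digits, format = "f")
  md_rows <- vapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, ])
    best <- if (higher_better) v == max(v) else v == min(v)
    cells <- ifelse(best, paste0("**", fmt(v), "**"), fmt(v))
    paste0("| ", rownames(tab)[i], " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  md <- c(paste0("| Dataset | ", paste(colnames(tab), collapse = " | "), " |"),
          paste0("|", paste(rep("---", ncol(tab) + 1L), collapse = "|"), "|"),
          md_rows,
          paste0("| Ave | ", paste(fmt(ave), collapse = " | "), " |"),
          paste0("| Rank | ", paste(rk, collapse = " | "), " |"))
  md_path <- file.path(out_dir, paste0(name, ".md"))
  writeLines(md, md_path)
  invisible(c(csv = csv_path, md = md_path))
}
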