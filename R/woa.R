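#' Convergence scalar schedule
#'
#' The shrinking coefficient `a` decreases linearly from 2 to 0 over the run
#' and scales the coefficient vector `A`: early iterations allow long
#' exploratory moves, late iterations collapse the encircling step onto the
#' reference solution.
#'
#' @param t 0-based iteration index, `0 <= t <= max_iter`.
#' @param max_iter total iteration budget (positive integer).
#' @return Scalar `2 - 2 * t / max_iter`, in `[0, 2]`.
#' @examples
#' update_a(0, 100)   # 2
#' update_a(25, 100)  # 1.5
#' update_a(100, 100) # 0
#' @export
update_a <- function(t, max_iter) {
  if (length(max_iter) != 1L || !is.finite(max_iter) || max_iter <= 0)
    stop("'max_iter' must be a positive number")
  if (length(t) != 1L || !is.finite(t) || t < 0 || t > max_iter)
    stop("'t' must lie in [0, max_iter]")
  2 - 2 * t / max_iter
}

#' Shrinking-encirclement position update
#'
#' Moves an agent toward a reference position (the best solution found so
#' far, or a subpopulation leader): `X' = X_ref - A * |C * X_ref - X|`,
#' all operations element-wise. With `A = 0` the agent lands exactly on the
#' reference.
#'
#' @param x current position vector.
#' @param x_ref reference position vector (same length).
#' @param a_coef coefficient `A` (scalar or vector), drawn as `2*a*r - a`.
#' @param c_coef coefficient `C` (scalar or vector), drawn as `2*r`.
#' @return Updated position, not yet boundary-corrected.
#' @export
encircle <- function(x, x_ref, a_coef, c_coef) {
  if (length(x) != length(x_ref))
    stop("'x' and 'x_ref' must have the same length")
  x_ref - a_coef * abs(c_coef * x_ref - x)
}

#' Logarithmic-spiral (bubble-net) position update
#'
#' Moves an agent along a logarithmic spiral around a reference position:
#' `X' = |X_ref - X| * exp(b*l) * cos(2*pi*l) + X_ref`, where the spiral
#' factor is a single scalar applied to every component.
#'
#' @param x current position vector.
#' @param x_ref reference position vector.
#' @param l spiral parameter in `[-1, 1]`.
#' @param b spiral shape constant (default 1).
#' @return Updated position, not yet boundary-corrected.
#' @export
spiral_attack <- function(x, x_ref, l, b = 1) {
  if (length(x) != length(x_ref))
    stop("'x' and 'x_ref' must have the same length")
  if (abs(l) > 1) stop("'l' must lie in [-1, 1]")
  abs(x_ref - x) * (exp(b * l) * cos(2 * pi * l)) + x_ref
}

#' Random-search position update
#'
#' Exploration step toward a randomly chosen agent rather than the best:
#' `X' = X_rand - A * |C * X_rand - X|`. Selected when `|A| >= 1`.
#'
#' @param x current position vector.
#' @param x_rand position of a randomly selected other agent.
#' @inheritParams encircle
#' @return Updated position, not yet boundary-corrected.
#' @export
random_search <- function(x, x_rand, a_coef, c_coef) {
  if (length(x) != length(x_rand))
    stop("'x' and 'x_rand' must have the same length")
  x_rand - a_coef * abs(c_coef * x_rand - x)
}

#' Clamp a position into the search box
#'
#' @param x position vector.
#' @param lower,upper box bounds (`lower < upper`).
#' @return `x` with every component clamped into `[lower, upper]`.
#' @export
correct_bounds <- function(x, lower = 0, upper = 1) {
  if (!is.numeric(lower) || !is.numeric(upper) || any(lower >= upper))
    stop("'lower' must be strictly less than 'upper'")
  pmin(pmax(x, lower), upper)
}

## Shared helpers -----------------------------------------------------------

init_population <- function(n_agents, d, lower, upper) {
  matrix(stats::runif(n_agents * d, lower, upper), nrow = n_agents, ncol = d)
}

make_counted_objective <- function(objective) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  fn <- function(x) {
    env$n <- env$n + 1L
    val <- objective(x)
    if (length(val) != 1L || !is.finite(val))
      stop("objective must return a single finite value")
    val
  }
  list(fn = fn, env = env)
}

new_spiral_run <- function(algorithm, best_position, best_fitness, history,
                           n_evals, seed) {
  structure(
    list(algorithm = algorithm, best_position = best_position,
         best_fitness = best_fitness, history = history,
         n_evals = n_evals, seed = seed),
    class = "spiral_run")
}

#' @export
print.spiral_run <- function(x, ...) {
  cat(sprintf("<%s run> d = %d, best fitness = %.6g, evaluations = %d\n",
              toupper(x$algorithm), length(x$best_position),
              x$best_fitness, x$n_evals))
  invisible(x)
}

#' Baseline whale optimization algorithm
#'
#' Minimizes `objective` over a box in `d` dimensions. Each iteration every
#' agent takes exactly one of three moves, chosen by a branch draw `p` and the
#' coefficient magnitude `|A|`: encirclement of the best solution
#' (`p < 0.5`, `|A| < 1`), random search toward another agent
#' (`p < 0.5`, `|A| >= 1`), or a spiral move around the best (`p >= 0.5`).
#' `A` is drawn once per agent per iteration as a scalar so the branch test is
#' well defined; `C` is a per-dimension vector. The best solution found so far
#' is retained across iterations (elitism), so the reported history is
#' non-increasing.
#'
#' All randomness flows from one seeded stream in a fixed order (per agent:
#' `r_A`, `r_C` (d draws), `p`, `l`, then the random-partner index when the
#' exploration branch fires), making runs bit-reproducible.
#'
#' @param objective function mapping a length-`d` numeric vector to a single
#'   finite value (minimized).
#' @param d problem dimension.
#' @param n_agents population size (default 10).
#' @param max_iter iteration budget (default 100).
#' @param lower,upper search box (defaults `[0, 1]`, the feature-selection
#'   encoding).
#' @param b spiral shape constant (default 1).
#' @param seed optional integer seed.
#' @param callback optional `function(t, best_fitness)` invoked after each
#'   iteration.
#' @return An object of class `"spiral_run"`: best position, best fitness,
#'   per-iteration best-fitness history (length `max_iter`), evaluation count.
#' @seealso [mswoa_run()] for the multispiral variant.
#' @export
woa_run <- function(objective, d, n_agents = 10, max_iter = 100,
                    lower = 0, upper = 1, b = 1, seed = NULL,
                    callback = NULL) {
  stopifnot(d >= 1, n_agents >= 2, max_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  counted <- make_counted_objective(objective)
  obj <- counted$fn

  pos <- init_population(n_agents, d, lower, upper)
  fit <- apply(pos, 1L, obj)
  best_i <- which.min(fit)
  best_x <- pos[best_i, ]
  best_f <- fit[best_i]
  history <- numeric(max_iter)

  for (t in seq_len(max_iter) - 1L) {
    a <- update_a(t, max_iter)
    for (i in seq_len(n_agents)) {
      r_a <- stats::runif(1)
      r_c <- stats::runif(d)
      p <- stats::runif(1)
      l <- stats::runif(1, -1, 1)
      a_coef <- 2 * a * r_a - a
      c_coef <- 2 * r_c
      new_x <- if (p < 0.5) {
        if (abs(a_coef) < 1) {
          encircle(pos[i, ], best_x, a_coef, c_coef)
        } else {
          others <- setdiff(seq_len(n_agents), i)
          j <- others[sample.int(length(others), 1L)]
          random_search(pos[i, ], pos[j, ], a_coef, c_coef)
        }
      } else {
        spiral_attack(pos[i, ], best_x, l, b)
      }
      pos[i, ] <- correct_bounds(new_x, lower, upper)
      fit[i] <- obj(pos[i, ])
    }
    m <- which.min(fit)
    if (fit[m] < best_f) {
      best_f <- fit[m]
      best_x <- pos[m, ]
    }
    history[t + 1L] <- best_f
    if (!is.null(callback)) callback(t, best_f)
  }

  new_spiral_run("woa", best_x, best_f, history, counted$env$n, seed)
}
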