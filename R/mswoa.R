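#' Number of subpopulations under the adaptive merging schedule
#'
#' The population is split into `K` subpopulations that merge exponentially
#' from `floor(N/2 + gamma)` at the start of the run down to one at the end:
#' `K = floor(N/2 * exp(-ln(N/2) * t/max_iter) + gamma)`. Small early
#' subpopulations favour diversity; the single late population favours deep
#' exploitation.
#'
#' @param t 0-based iteration index.
#' @param n_agents population size `N` (at least 2).
#' @param max_iter iteration budget.
#' @param gamma merge offset in `[0, 1]`; 0.8 suits a population of 10.
#' @return Integer `K >= 1`, non-increasing in `t`.
#' @examples
#' subpop_count(0, 10, 100)    # 5
#' subpop_count(50, 10, 100)   # 3
#' subpop_count(100, 10, 100)  # 1
#' @export
subpop_count <- function(t, n_agents, max_iter, gamma = 0.8) {
  if (n_agents < 2) stop("'n_agents' must be at least 2")
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  if (t < 0 || t > max_iter) stop("'t' must lie in [0, max_iter]")
  half <- n_agents / 2
  as.integer(floor(half * exp(-log(half) * t / max_iter) + gamma))
}

#' Fitness-distance scores for subpopulation assignment
#'
#' Combines solution quality with distance from the incumbent best:
#' `FD = (1 - fit_norm) + dis_norm`, where `fit_norm` is the min-max
#' normalized fitness over the population and `dis_norm` the min-max
#' normalized Euclidean distance to the best agent. Degenerate
#' normalizations (max equal to min) are defined as 0, so a population of
#' identical agents scores FD = 1 throughout. High FD marks good and/or
#' remote agents, which seed the leading subpopulations.
#'
#' @param positions numeric matrix, one agent per row.
#' @param fitness numeric vector of evaluated fitness values.
#' @param best_index row index of the reference (best) agent; defaults to the
#'   minimum-fitness agent (ties to the lowest index).
#' @return `data.frame` with columns `fd`, `fit_norm`, `dis_norm`, in `[0,2]`,
#'   `[0,1]`, `[0,1]`.
#' @export
fd_scores <- function(positions, fitness, best_index = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 0L) stop("empty population")
  if (length(fitness) != n) stop("'fitness' length must match rows of 'positions'")
  if (anyNA(fitness)) stop("all fitness values must be evaluated")
  if (is.null(best_index)) best_index <- which.min(fitness)

  minmax <- function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  }
  fit_norm <- minmax(fitness)
  dis <- sqrt(rowSums((positions - matrix(positions[best_index, ], n,
                                          ncol(positions), byrow = TRUE))^2))
  dis_norm <- minmax(dis)
  data.frame(fd = (1 - fit_norm) + dis_norm,
             fit_norm = fit_norm, dis_norm = dis_norm)
}

#' Partition the population into subpopulations
#'
#' Implements the adaptive multipopulation merging step. Normally agents are
#' ranked by fitness-distance score (descending, ties to the lower index) and
#' assigned to `K` contiguous blocks of `M = floor(N/K)`; the `N - K*M`
#' remainder agents join the last subpopulation. Every `regroup_period`
#' iterations (for `t > 0`) membership is instead a uniformly random
#' permutation split into the same blocks, which shuffles information across
#' subpopulations. Consumes the current RNG stream when regrouping.
#'
#' @inheritParams subpop_count
#' @inheritParams fd_scores
#' @param regroup_period iterations between random regroupings (default 5, the
#'   customary epoch of dynamic multi-swarm regrouping).
#' @return List with `k`, `m`, `membership` (integer vector in `1..k`) and
#'   `leaders` (per-subpopulation index of the minimum-fitness member).
#' @export
partition_population <- function(positions, fitness, t, max_iter,
                                 gamma = 0.8, regroup_period = 5) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  k <- subpop_count(t, n, max_iter, gamma)
  m <- n %/% k

  ord <- if (t > 0 && t %% regroup_period == 0) {
    sample.int(n)
  } else {
    scores <- fd_scores(positions, fitness)
    order(-scores$fd, seq_len(n))
  }

  membership <- integer(n)
  membership[ord] <- pmin(((seq_len(n) - 1L) %/% m) + 1L, k)

  leaders <- vapply(seq_len(k), function(g) {
    members <- which(membership == g)
    members[which.min(fitness[members])]
  }, integer(1))

  list(k = k, m = m, membership = membership, leaders = leaders)
}

#' Golden-spiral exploration step
#'
#' The double-spiral search replaces the baseline random-search branch: the
#' agent departs from its own position along a spiral whose radius is set by
#' a randomly weighted other agent, `X' = r * exp(theta) * cos(2*pi*theta) +
#' X_m` with `r = |W * X_rand - X_m|`. Because `exp(theta)` can exceed 1 the
#' move spirals either inward (nearby refinement) or outward (escape from
#' stagnation).
#'
#' @param x_m current position.
#' @param x_rand position of an agent from another subpopulation (any other
#'   agent when only one subpopulation remains).
#' @param theta spiral angle, one scalar per move (drawn from `U[-1, 1]`).
#' @param w random weight vector with components in `[0, 1]`.
#' @return Updated position, not yet boundary-corrected.
#' @export
dss_update <- function(x_m, x_rand, theta, w) {
  if (length(x_m) != length(x_rand))
    stop("'x_m' and 'x_rand' must have the same length")
  if (identical(x_m, x_rand))
    stop("'x_rand' must be a different agent's position")
  r <- abs(w * x_rand - x_m)
  r * (exp(theta) * cos(2 * pi * theta)) + x_m
}

#' Quadratic-interpolation point
#'
#' Per-dimension vertex of the parabola through three solutions: the
#' subpopulation best `g`, a member `m`, and a random agent `r`, with scalar
#' fitnesses `f_g`, `f_m`, `f_r`. Dimensions whose interpolation denominator
#' falls below `tol` (collinear or coincident coordinates) fall back to the
#' best solution's coordinate.
#'
#' @param g,m,r position vectors of the subpopulation best, the member, and
#'   the random agent.
#' @param f_g,f_m,f_r their fitness values.
#' @param tol degeneracy tolerance on the absolute denominator.
#' @return Position vector of the interpolated point.
#' @export
qi_point <- function(g, m, r, f_g, f_m, f_r, tol = 1e-12) {
  stopifnot(length(g) == length(m), length(m) == length(r))
  num <- (m^2 - r^2) * f_g + (r^2 - g^2) * f_m + (g^2 - m^2) * f_r
  den <- 2 * ((m - r) * f_g + (r - g) * f_m + (g - m) * f_r)
  q <- ifelse(abs(den) < tol, g, num / den)
  q
}

#' Baleen neighbourhood refinement of a subpopulation best
#'
#' Early-phase local search: active only while `t / max_iter <
#' bes_fraction` (otherwise a strict no-op costing zero objective calls).
#' For each subpopulation member it interpolates a candidate through the
#' leader, the member and a random agent ([qi_point()]), crosses it with the
#' leader per dimension (keep the interpolated coordinate when a fresh
#' uniform draw is `>= 0.5`, else the leader's), evaluates the crossover
#' point once, and adopts it as the new leader when strictly better.
#'
#' @param members integer indices of the subpopulation's agents.
#' @param leader index of the current subpopulation best.
#' @param positions population position matrix.
#' @param fitness evaluated fitness vector.
#' @param objective objective function (minimized).
#' @param t,max_iter iteration index and budget (0-based gate).
#' @param bes_fraction fraction of the run during which refinement is active
#'   (default 0.2).
#' @param lower,upper search box for boundary correction of candidates.
#' @return List with `position`, `fitness` (possibly improved leader) and
#'   `n_evals`, the number of objective calls spent.
#' @export
bes_refine <- function(members, leader, positions, fitness, objective,
                       t, max_iter, bes_fraction = 0.2,
                       lower = 0, upper = 1) {
  if (length(members) < 1L) stop("subpopulation must have at least one member")
  best_x <- positions[leader, ]
  best_f <- fitness[leader]
  if (t / max_iter >= bes_fraction)
    return(list(position = best_x, fitness = best_f, n_evals = 0L))

  n <- nrow(positions)
  d <- ncol(positions)
  n_evals <- 0L
  for (i in members) {
    j <- sample.int(n, 1L)
    q <- qi_point(best_x, positions[i, ], positions[j, ],
                  best_f, fitness[i], fitness[j])
    draws <- stats::runif(d)
    xc <- ifelse(draws >= 0.5, q, best_x)
    xc <- correct_bounds(xc, lower, upper)
    fc <- objective(xc)
    n_evals <- n_evals + 1L
    if (fc < best_f) {
      best_f <- fc
      best_x <- xc
    }
  }
  list(position = best_x, fitness = best_f, n_evals = n_evals)
}

#' Multispiral whale optimization algorithm
#'
#' Extends [woa_run()] with three strategies. (1) Adaptive multipopulation
#' merging: each iteration the population is partitioned into `K`
#' subpopulations ([partition_population()]); `K` shrinks exponentially from
#' `floor(N/2 + gamma)` to 1 ([subpop_count()]), membership follows the
#' fitness-distance ranking with periodic random regrouping, and every agent
#' is guided by its own subpopulation leader instead of a single global best.
#' (2) Double-spiral search: the exploration branch (`p < 0.5`, `|A| >= 1`)
#' becomes a golden-spiral move anchored at the agent itself
#' ([dss_update()]), with the partner drawn from another subpopulation.
#' (3) Baleen neighbourhood exploitation: during the first `bes_fraction` of
#' the run each leader is refined by quadratic interpolation plus crossover
#' ([bes_refine()]), at the price of one extra objective call per member.
#'
#' Leaders are recomputed after each subpopulation's update sweep, before
#' refinement. The global best is the elitist record over all agents, so the
#' returned history is non-increasing; with a fixed seed the run is
#' bit-reproducible.
#'
#' @inheritParams woa_run
#' @param gamma merge offset of the subpopulation schedule (default 0.8).
#' @param regroup_period iterations between random regroupings (default 5, the
#'   customary epoch of dynamic multi-swarm regrouping).
#' @param bes_fraction fraction of the run with neighbourhood refinement
#'   active (default 0.2).
#' @return An object of class `"spiral_run"`; see [woa_run()].
#' @export
mswoa_run <- function(objective, d, n_agents = 10, max_iter = 100,
                      gamma = 0.8, regroup_period = 5, bes_fraction = 0.2,
                      lower = 0, upper = 1, b = 1, seed = NULL,
                      callback = NULL) {
  stopifnot(d >= 1, n_agents >= 2, max_iter >= 1,
            regroup_period >= 1, bes_fraction > 0, bes_fraction <= 1)
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
    plan <- partition_population(pos, fit, t, max_iter, gamma, regroup_period)

    for (g in seq_len(plan$k)) {
      members <- which(plan$membership == g)
      # with a single merged subpopulation the algorithm degenerates to the
      # baseline, whose guide is the persistent best-so-far record
      leader_x <- if (plan$k == 1 && best_f < fit[plan$leaders[g]]) best_x
                  else pos[plan$leaders[g], ]

      for (i in members) {
        r_a <- stats::runif(1)
        r_c <- stats::runif(d)
        p <- stats::runif(1)
        l <- stats::runif(1, -1, 1)
        theta <- stats::runif(1, -1, 1)
        w <- stats::runif(d)
        a_coef <- 2 * a * r_a - a
        c_coef <- 2 * r_c
        new_x <- if (p < 0.5) {
          if (abs(a_coef) < 1) {
            encircle(pos[i, ], leader_x, a_coef, c_coef)
          } else {
            pool <- if (plan$k > 1) which(plan$membership != g)
                    else setdiff(seq_len(n_agents), i)
            j <- pool[sample.int(length(pool), 1L)]
            if (all(pos[j, ] == pos[i, ])) {
              # coincident partner: zero-radius spiral, agent stays put
              pos[i, ]
            } else {
              dss_update(pos[i, ], pos[j, ], theta, w)
            }
          }
        } else {
          spiral_attack(pos[i, ], leader_x, l, b)
        }
        pos[i, ] <- correct_bounds(new_x, lower, upper)
        fit[i] <- obj(pos[i, ])
      }

      # leader refreshed on the updated members, then refined early in the run
      leader <- members[which.min(fit[members])]
      ref <- bes_refine(members, leader, pos, fit, obj, t, max_iter,
                        bes_fraction, lower, upper)
      if (ref$fitness < fit[leader]) {
        pos[leader, ] <- ref$position
        fit[leader] <- ref$fitness
      }
    }

    m <- which.min(fit)
    if (fit[m] < best_f) {
      best_f <- fit[m]
      best_x <- pos[m, ]
    }
    history[t + 1L] <- best_f
    if (!is.null(callback)) callback(t, best_f)
  }

  new_spiral_run("mswoa", best_x, best_f, history, counted$env$n, seed)
}
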