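test_that("subpopulation count merges exponentially and monotonically", {
  expect_identical(subpop_count(0, 10, 100, 0.8), 5L)
  expect_identical(subpop_count(100, 10, 100, 0.8), 1L)
  expect_identical(subpop_count(50, 10, 100, 0.8),
                   as.integer(floor(5 * 5^-0.5 + 0.8)))
  ks <- sapply(0:100, subpop_count, n_agents = 10, max_iter = 100)
  expect_false(is.unsorted(rev(ks)))
  expect_true(all(ks >= 1))
  expect_error(subpop_count(0, 1, 100))
  expect_error(subpop_count(0, 10, 100, gamma = 1.2))
})

test_that("fitness-distance scores follow the hand-computed normalization", {
  pos <- rbind(c(0, 0), c(0.4, 0), c(0.2, 0))
  fit <- c(0.1, 0.2, 0.9)
  sc <- fd_scores(pos, fit)
  expect_equal(sc$fit_norm, c(0, 0.125, 1))
  expect_equal(sc$dis_norm, c(0, 1, 0.5))
  expect_equal(sc$fd, c(1, 1.875, 0.5))
  # the best agent always scores FD = 1; identical agents all score 1
  expect_equal(sc$fd[which.min(fit)], 1)
  same <- fd_scores(matrix(0.3, 4, 2), rep(0.5, 4))
  expect_equal(same$fd, rep(1, 4))
  expect_true(all(sc$fd >= 0 & sc$fd <= 2))
  expect_error(fd_scores(pos, c(0.1, NA, 0.2)))
})

test_that("partition is a true partition with the remainder in the last block", {
  set.seed(1)
  pos <- matrix(runif(20), 10, 2)
  fit <- runif(10)
  # t = 0, N = 10 -> K = 5 blocks of 2
  p5 <- partition_population(pos, fit, t = 0, max_iter = 100)
  expect_identical(p5$k, 5L)
  expect_identical(sort(unique(p5$membership)), 1:5)
  expect_true(all(table(p5$membership) == 2))
  # K = 3 -> sizes (3, 3, 4); long regroup period keeps the FD ordering path
  p3 <- partition_population(pos, fit, t = 50, max_iter = 100,
                             regroup_period = 999)
  expect_identical(p3$k, 3L)
  expect_equal(as.integer(table(p3$membership)), c(3L, 3L, 4L))
  # final iterations: one subpopulation led by the global best
  p1 <- partition_population(pos, fit, t = 99, max_iter = 100)
  expect_identical(p1$k, 1L)
  expect_true(all(p1$membership == 1L))
  expect_identical(p1$leaders, which.min(fit))
  # each leader minimizes fitness within its block
  for (g in seq_len(p3$k)) {
    members <- which(p3$membership == g)
    expect_equal(fit[p3$leaders[g]], min(fit[members]))
  }
  # FD ordering: highest-FD agents populate the first block
  fd <- fd_scores(pos, fit)$fd
  expect_true(min(fd[p3$membership == 1]) >= max(fd[p3$membership == 3]))
})

test_that("regrouping iterations shuffle membership randomly but reproducibly", {
  pos <- matrix(runif(20), 10, 2)
  fit <- runif(10)
  set.seed(42)
  a <- partition_population(pos, fit, t = 10, max_iter = 100)
  set.seed(42)
  b <- partition_population(pos, fit, t = 10, max_iter = 100)
  expect_identical(a$membership, b$membership)
  expect_true(all(table(a$membership) >= a$m))
})

test_that("double-spiral step matches its closed form", {
  # quarter turn annihilates the radial term
  expect_equal(dss_update(c(0.5, 0.2), c(0.9, 0.7), 0.25, c(0.3, 0.8)),
               c(0.5, 0.2))
  # zero radius: W * x_rand equal to x_m
  expect_equal(dss_update(0.4, 0.8, 0.7, 0.5), 0.4)
  # hand-computed scalar case: r = 0.1, theta = 0.5
  expect_equal(dss_update(0.5, 0.6, 0.5, 1.0),
               0.5 + 0.1 * exp(0.5) * cos(pi), tolerance = 1e-12)
  expect_error(dss_update(c(0.5, 0.2), c(0.5, 0.2), 0.1, c(1, 1)))
})

test_that("quadratic interpolation recovers vertices and falls back when degenerate", {
  # parabola f(x) = (x - 2)^2 through x = 1, 3, 4
  expect_equal(qi_point(1, 3, 4, 1, 1, 4), 2)
  # f(x) = x^2 through 0.2, 0.5, 0.9
  expect_equal(qi_point(0.2, 0.5, 0.9, 0.04, 0.25, 0.81), 0)
  # coincident coordinates in one dimension fall back to the best agent's
  q <- qi_point(c(1, 0.7), c(3, 0.7), c(4, 0.7), 1, 1, 4)
  expect_equal(q, c(2, 0.7))
  # property: exact vertex recovery over random non-degenerate quadratics
  set.seed(99)
  for (rep in 1:50) {
    a <- runif(1, 0.5, 3); v <- runif(1, -2, 2); c0 <- runif(1)
    xs <- sort(runif(3, -3, 3))
    while (min(diff(xs)) < 0.05) xs <- sort(runif(3, -3, 3))
    fv <- a * (xs - v)^2 + c0
    expect_equal(qi_point(xs[1], xs[2], xs[3], fv[1], fv[2], fv[3]), v,
                 tolerance = 1e-9)
  }
})

test_that("baleen refinement is gated, elitist and costed correctly", {
  set.seed(3)
  pos <- matrix(runif(12), 6, 2)
  obj <- function(x) sum((x - 0.5)^2)
  fit <- apply(pos, 1, obj)
  leader <- which.min(fit)
  calls <- 0L
  counting <- function(x) { calls <<- calls + 1L; obj(x) }
  # gate: late in the run it does nothing and spends nothing
  late <- bes_refine(1:6, leader, pos, fit, counting, t = 20, max_iter = 100)
  expect_identical(late$n_evals, 0L)
  expect_identical(calls, 0L)
  expect_identical(late$position, pos[leader, ])
  # active: one evaluation per member, never worse than the incumbent
  act <- bes_refine(1:6, leader, pos, fit, counting, t = 5, max_iter = 100)
  expect_identical(act$n_evals, 6L)
  expect_identical(calls, 6L)
  expect_lte(act$fitness, fit[leader])
})

test_that("multispiral optimizer is elitist, reproducible, and competitive", {
  sphere <- function(x) sum((x - 0.5)^2)
  r1 <- mswoa_run(sphere, d = 5, n_agents = 10, max_iter = 50, seed = 7)
  r2 <- mswoa_run(sphere, d = 5, n_agents = 10, max_iter = 50, seed = 7)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$history, r2$history)
  expect_false(is.unsorted(-r1$history))
  expect_gte(r1$history[1], r1$history[length(r1$history)])
  expect_lt(r1$best_fitness, 0.01)
  # evaluation accounting: N * MaxIter core updates plus early-phase extras
  expect_gte(r1$n_evals, 10 + 10 * 50)
  expect_lte(r1$n_evals, 10 + 10 * 50 + 10 * 10 + 10)
})
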