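quad_objective <- function(target) function(x) sum((x - target)^2)

box_bounds <- function(d, lo = -2, hi = 2) {
  matrix(c(rep(lo, d), rep(hi, d)), d, 2)
}

test_that("init_population sizes roles and bounds as configured", {
  cfg <- ssa_config(n = 20L, iter_max = 10L, bounds = box_bounds(3, 0, 1),
                    seed = 5L)
  st <- init_population(cfg, quad_objective(rep(0.5, 3)))
  # 7:3 at n = 20: 14 discoverers, 6 participants
  expect_identical(st$n_disc, 14L)
  expect_identical(dim(st$X), c(20L, 3L))
  expect_true(all(st$X >= 0 & st$X <= 1))
  # sorted best-first
  expect_identical(st$fitness, sort(st$fitness))
  st2 <- init_population(cfg, quad_objective(rep(0.5, 3)))
  expect_identical(st$X, st2$X)
  expect_error(init_population(cfg, quad_objective(numeric(0)), d = 0L),
               "dimension")
})

test_that("discoverer updates match the printed equation on frozen draws", {
  cfg <- ssa_config(n = 4L, iter_max = 50L, discoverer_fraction = 0.5,
                    bounds = box_bounds(2, -10, 10), seed = 1L, ST = 0.8)
  st <- init_population(cfg, quad_objective(c(0, 0)))
  X0 <- st$X
  # safe branch, alpha = 1, exponent -i / iter_max
  upd <- update_discoverers(st, cfg,
                            draws = list(R2 = 0, alpha = c(1, 1),
                                         Q = c(0, 0)))
  for (i in 1:2) {
    expect_equal(upd$X[i, ], X0[i, ] * exp(-i / 50), tolerance = 1e-14)
  }
  # alarm branch with Q drawn as zero: unchanged
  upd2 <- update_discoverers(st, cfg,
                             draws = list(R2 = 0.9, alpha = c(1, 1),
                                          Q = c(0, 0)))
  expect_equal(upd2$X[1:2, ], X0[1:2, ], tolerance = 1e-15)
  # clipping keeps a bound-hugging position exactly on the bound
  st$X[1, ] <- c(10, -10)
  upd3 <- update_discoverers(st, cfg,
                             draws = list(R2 = 0.9, alpha = c(1, 1),
                                          Q = c(5, 0)))
  expect_identical(upd3$X[1, ], c(10, -5))
})

test_that("participant updates match the printed equation on frozen draws", {
  cfg <- ssa_config(n = 4L, iter_max = 10L, discoverer_fraction = 0.5,
                    bounds = box_bounds(2, -10, 10), seed = 2L)
  st <- init_population(cfg, quad_objective(c(0, 0)))
  st$XP <- c(1, -1)
  st$worst <- st$X[4L, ]
  # rank 3 of n = 4 -> i > n/2 branch: Q * exp((worst - X) / i^2)
  X0 <- st$X
  upd <- update_participants(st, cfg,
                             draws = list(Q = c(2, 0),
                                          A = matrix(1, 2, 2)))
  expect_equal(upd$X[3, ], 2 * exp((st$worst - X0[3, ]) / 9),
               tolerance = 1e-12)
  # rank 4 drew Q = 0: collapses to the origin of the exponential term
  expect_equal(upd$X[4, ], c(0, 0), tolerance = 1e-15)
  # a participant exactly at X_P stays at X_P in the compete branch (d = 1:
  # A+ L reduces to the identity, so the step is |X - X_P| = 0)
  cfg1 <- ssa_config(n = 4L, iter_max = 10L, discoverer_fraction = 0.25,
                     bounds = box_bounds(1, -5, 5), seed = 3L)
  st1 <- init_population(cfg1, function(x) sum(x^2))
  st1$XP <- st1$X[2L, ]
  upd1 <- update_participants(st1, cfg1,
                              draws = list(Q = c(0, 0, 0),
                                           A = matrix(1, 3, 1)))
  expect_identical(upd1$X[2L, ], st1$XP)
})

test_that("watchman updates match the printed equation on frozen draws", {
  cfg <- ssa_config(n = 20L, iter_max = 10L, bounds = box_bounds(2, -10, 10),
                    seed = 4L, sense = "min")
  st <- init_population(cfg, quad_objective(c(0.5, 0.5)))
  # 20% of n = 20 -> 4 watchmen per iteration
  upd <- update_watchmen(st, cfg)
  expect_length(attr(upd, "moved"), 4L)
  # worse-than-best branch with beta = 1: X_best + |X - X_best| exactly
  i <- 10L
  upd2 <- update_watchmen(st, cfg,
                          draws = list(idx = i, beta = 1, K = 0))
  expect_equal(upd2$X[i, ], st$best + abs(st$X[i, ] - st$best),
               tolerance = 1e-14)
  # at-the-best branch with K = 0: unchanged
  upd3 <- update_watchmen(st, cfg, draws = list(idx = 1L, beta = 1, K = 0))
  expect_identical(upd3$X[1L, ], st$X[1L, ])
})

test_that("update ops agree with an independent transcription on random frozen draws", {
  # straight-from-the-equations re-evaluation, written independently of the
  # package internals
  for (s in 1:5) {
    d <- 3L
    cfg <- ssa_config(n = 10L, iter_max = 30L, discoverer_fraction = 0.7,
                      bounds = box_bounds(d, -50, 50), seed = s)
    st <- init_population(cfg, quad_objective(rep(0.3, d)))
    nd <- st$n_disc
    withr::with_seed(1000 + s, {
      draws_d <- list(R2 = runif(1), alpha = runif(nd), Q = rnorm(nd))
      npart <- cfg$n - nd
      draws_p <- list(Q = rnorm(npart),
                      A = matrix(sample(c(-1, 1), npart * d, TRUE),
                                 npart, d))
      draws_w <- list(idx = sample.int(cfg$n, 2L),
                      beta = matrix(rnorm(2L * d), 2L, d),
                      K = runif(2L, -1, 1))
    })
    got_d <- update_discoverers(st, cfg, draws = draws_d)
    exp_X <- st$X
    for (i in seq_len(nd)) {
      exp_X[i, ] <- if (draws_d$R2 < cfg$ST) {
        st$X[i, ] * exp(-i / (draws_d$alpha[i] * cfg$iter_max))
      } else {
        st$X[i, ] + draws_d$Q[i] * rep(1, d)
      }
      exp_X[i, ] <- pmin(pmax(exp_X[i, ], -50), 50)
    }
    expect_equal(got_d$X[seq_len(nd), ], exp_X[seq_len(nd), ],
                 tolerance = 1e-13)

    got_p <- update_participants(got_d, cfg, draws = draws_p)
    exp_X <- got_d$X
    for (k in seq_len(npart)) {
      i <- nd + k
      exp_X[i, ] <- if (i > cfg$n / 2) {
        draws_p$Q[k] * exp((got_d$worst - got_d$X[i, ]) / i^2)
      } else {
        A <- draws_p$A[k, , drop = FALSE]
        Ap <- t(A) %*% solve(A %*% t(A))
        got_d$XP + drop(abs(got_d$X[i, ] - got_d$XP) %*% Ap) * rep(1, d)
      }
      exp_X[i, ] <- pmin(pmax(exp_X[i, ], -50), 50)
    }
    expect_equal(got_p$X, exp_X, tolerance = 1e-13)

    got_w <- update_watchmen(got_p, cfg, draws = draws_w)
    exp_X <- got_p$X
    for (k in seq_along(draws_w$idx)) {
      i <- draws_w$idx[k]
      fi <- got_p$fitness[i]
      if (fi > got_p$best_f + 1e-12) {
        exp_X[i, ] <- got_p$best +
          draws_w$beta[k, ] * abs(got_p$X[i, ] - got_p$best)
      } else if (abs(fi - got_p$best_f) <= 1e-12) {
        exp_X[i, ] <- got_p$X[i, ] + draws_w$K[k] *
          (abs(got_p$X[i, ] - got_p$worst) /
             ((fi - got_p$worst_f) + cfg$eps))
      }
      exp_X[i, ] <- pmin(pmax(exp_X[i, ], -50), 50)
    }
    expect_equal(got_w$X, exp_X, tolerance = 1e-13)
  }
})

test_that("positions stay within bounds under long fuzzed runs", {
  cfg <- ssa_config(n = 12L, iter_max = 1000L,
                    bounds = box_bounds(3, -1.5, 0.5), seed = 11L)
  res <- run_ssa(quad_objective(c(-0.2, 0.3, -1)), cfg)
  expect_true(all(res$state$X >= -1.5 & res$state$X <= 0.5))
  expect_true(all(res$position >= -1.5 & res$position <= 0.5))
})

test_that("run_ssa is elitist, reproducible and converges on a 2-D quadratic", {
  target <- c(0.3, -0.7)
  cfg <- ssa_config(n = 20L, iter_max = 100L, bounds = box_bounds(2),
                    seed = 1L)
  dist <- vapply(1:10, function(s) {
    cfg$seed <- s
    res <- run_ssa(quad_objective(target), cfg)
    expect_true(all(diff(res$history) <= 0))
    sqrt(sum((res$position - target)^2))
  }, numeric(1))
  expect_gte(sum(dist <= 1e-2), 9L)
  cfg$seed <- 42L
  r1 <- run_ssa(quad_objective(target), cfg)
  r2 <- run_ssa(quad_objective(target), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$position, r2$position)
  # zero iterations: the best of the initial population
  cfg0 <- ssa_config(n = 10L, iter_max = 0L, bounds = box_bounds(2),
                     seed = 3L)
  r0 <- run_ssa(quad_objective(target), cfg0)
  st0 <- init_population(ssa_config(n = 10L, iter_max = 0L,
                                    bounds = box_bounds(2), seed = 3L),
                         quad_objective(target))
  expect_identical(r0$fitness, st0$fitness[1L])
  # an objective that raises aborts with the position in the message
  bad <- function(x) if (x[1] > -Inf) stop("boom") else 0
  expect_error(run_ssa(bad, cfg0), "objective failed")
})

test_that("optimize_model searches (c, g) inside the printed range", {
  blobs <- two_blobs(n_per = 20L, seed = 2L)
  opt <- optimize_model("svm", blobs$X, blobs$y, folds = 5L, seed = 1L,
                        ssa_n = 6L, ssa_iter = 3L)
  expect_length(opt$best_position, 2L)
  expect_true(all(opt$best_position > 1e-5 & opt$best_position < 100))
  expect_s3_class(opt$model, "nirmeat_svm")
  # degenerate 1-sparrow 0-iteration search: a single random candidate
  one <- optimize_model("svm", blobs$X, blobs$y, folds = 5L, seed = 2L,
                        ssa_n = 1L, ssa_iter = 0L)
  expect_identical(one$search$evaluations, 1L)
})

test_that("SSA-SVM matches grid-search accuracy on a separable task", {
  blobs <- two_blobs(n_per = 30L, seed = 7L)
  folds <- kfold_by_sample(seq_along(blobs$y), k = 10L, seed = 3L)
  gs <- grid_search_svm(blobs$X, blobs$y, c_grid = 2^seq(-4, 6, 2),
                        g_grid = 2^seq(-6, 2, 2), folds = folds)
  opt <- optimize_model("svm", blobs$X, blobs$y, folds = 10L, seed = 4L,
                        ssa_n = 10L, ssa_iter = 10L)
  ssa_cv_acc <- 1 - opt$best_fitness
  expect_gte(ssa_cv_acc, gs$best_score - 0.01)
})

test_that("SSA-ELM beats a single random ELM on noise-free mixtures", {
  m <- tiny_endmembers(25L)
  mutton <- generate_endmembers(m, "mutton")
  pork <- generate_endmembers(m, "pork_essence")
  p <- rep(c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4), each = 6L)
  X <- t(vapply(p, function(pp) mix_spectrum(pp, mutton, pork),
                numeric(25L)))
  X <- X + withr::with_seed(1, matrix(rnorm(length(X), 0, 1e-4), nrow(X)))
  wins <- 0L
  for (s in 1:10) {
    base <- train_elm(X, p, n_hidden = 15L, seed = s)
    base_rmse <- sqrt(mean((predict(base, X) - p)^2))
    opt <- optimize_model("elm", X, p, folds = 6L, seed = s,
                          n_hidden = 15L, ssa_n = 6L, ssa_iter = 4L)
    opt_rmse <- sqrt(mean((predict(opt$model, X) - p)^2))
    wins <- wins + (opt_rmse <= base_rmse)
  }
  expect_gte(wins, 8L)
})
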