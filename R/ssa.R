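#' Sparrow search algorithm configuration
#'
#' Population metaheuristic modelling sparrow foraging: discoverers lead the
#' search, participants follow or scatter, and a random subset of watchmen
#' perturbs against predation each iteration. Study configuration: population
#' 20, 100 iterations, discoverer:participant ratio 7:3, 20% watchmen.
#' Symbols left open by the update equations are drawn as: safety value
#' `R2 ~ U[0,1]` per iteration vs safety threshold `ST` (default 0.8);
#' `alpha ~ U(0,1]` per discoverer; step `Q ~ N(0,1)` per sparrow; `L` the
#' all-ones row; `A` a random +/-1 row with `A+ = t(A) (A t(A))^-1`;
#' `beta ~ N(0,1)`; `K ~ U[-1,1]`; `eps = 1e-50` guards the zero division.
#'
#' @param n population size.
#' @param iter_max maximum iterations.
#' @param discoverer_fraction fraction of the population acting as
#'   discoverers (7:3 ratio = 0.7).
#' @param watchman_fraction fraction re-sampled as watchmen each iteration
#'   (at most 0.2).
#' @param ST safety threshold in `[0.5, 1]`.
#' @param bounds d x 2 matrix (or `c(lo, hi)` recycled) of per-dimension
#'   position bounds, `lo < hi`.
#' @param seed integer seed.
#' @param sense `"min"` or `"max"`: the objective's direction.
#' @param boundary `"clip"` (default) or `"reflect"` out-of-bounds handling.
#' @param eps small constant in the watchman equal-fitness branch.
#' @param tie_tol tolerance for the `f_i = f_g` comparison.
#' @return list of class `ssa_config`.
#' @export
ssa_config <- function(n = 20L, iter_max = 100L, discoverer_fraction = 0.7,
                       watchman_fraction = 0.2, ST = 0.8, bounds,
                       seed = NULL, sense = c("min", "max"),
                       boundary = c("clip", "reflect"),
                       eps = 1e-50, tie_tol = 1e-12) {
  sense <- match.arg(sense)
  boundary <- match.arg(boundary)
  check_number(n, "n", 1)
  check_number(iter_max, "iter_max", 0)
  if (discoverer_fraction <= 0 || discoverer_fraction >= 1) {
    stop_nirmeat("ssa_config: discoverer_fraction must lie in (0, 1)")
  }
  if (watchman_fraction <= 0 || watchman_fraction > 0.2 + 1e-9) {
    stop_nirmeat("ssa_config: watchman_fraction must lie in (0, 0.2]")
  }
  if (ST < 0.5 || ST > 1) stop_nirmeat("ssa_config: ST must lie in [0.5, 1]")
  if (is.vector(bounds) && length(bounds) == 2L) {
    bounds <- matrix(bounds, 1L, 2L)
  }
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1] >= bounds[, 2])) {
    stop_nirmeat("ssa_config: bounds must be a d x 2 matrix with lo < hi")
  }
  structure(list(n = as.integer(n), iter_max = as.integer(iter_max),
                 discoverer_fraction = discoverer_fraction,
                 watchman_fraction = watchman_fraction, ST = ST,
                 bounds = bounds, seed = seed, sense = sense,
                 boundary = boundary, eps = eps, tie_tol = tie_tol),
            class = "ssa_config")
}

# sense-aware comparison helpers: "worse" means larger for minimisation
is_worse <- function(a, b, sense) if (sense == "min") a > b else a < b

apply_bounds <- function(X, config) {
  lo <- config$bounds[, 1]
  hi <- config$bounds[, 2]
  if (nrow(config$bounds) == 1L) {
    lo <- rep(lo, ncol(X))
    hi <- rep(hi, ncol(X))
  }
  for (j in seq_len(ncol(X))) {
    if (config$boundary == "reflect") {
      w <- hi[j] - lo[j]
      v <- (X[, j] - lo[j]) %% (2 * w)
      X[, j] <- lo[j] + ifelse(v > w, 2 * w - v, v)
    } else {
      X[, j] <- pmin(pmax(X[, j], lo[j]), hi[j])
    }
  }
  X
}

expand_bounds <- function(config, d) {
  b <- config$bounds
  if (nrow(b) == 1L) b <- b[rep(1L, d), , drop = FALSE]
  if (nrow(b) != d) stop_nirmeat("ssa: bounds do not match dimension d")
  b
}

#' Initialise the sparrow population
#'
#' Positions drawn uniformly within bounds under the config seed, fitness
#' evaluated and the population sorted best-first; the first
#' `ceiling(discoverer_fraction * n)` sparrows are the discoverers.
#'
#' @param config an [ssa_config()].
#' @param objective function of a position vector returning a finite scalar.
#' @param d problem dimension (defaults to `nrow(config$bounds)`).
#' @return list of class `ssa_state` with positions `X`, `fitness`, bests,
#'   worsts and role bookkeeping.
#' @export
init_population <- function(config, objective, d = nrow(config$bounds)) {
  stopifnot(inherits(config, "ssa_config"))
  if (d < 1L) stop_nirmeat("init_population: dimension must be >= 1")
  b <- expand_bounds(config, d)
  X <- with_local_seed(config$seed, {
    matrix(stats::runif(config$n * d), config$n, d) %*%
      diag(b[, 2] - b[, 1], d) +
      matrix(b[, 1], config$n, d, byrow = TRUE)
  })
  fitness <- apply(X, 1L, objective)
  state <- sort_population(list(X = X, fitness = fitness, t = 0L, d = d),
                           config)
  state$n_disc <- as.integer(ceiling(config$discoverer_fraction * config$n))
  state$best_ever <- state$X[1L, ]
  state$best_ever_f <- state$fitness[1L]
  class(state) <- "ssa_state"
  state
}

# sort best-first and refresh best/worst/XP bookkeeping
sort_population <- function(state, config) {
  ord <- order(state$fitness,
               decreasing = identical(config$sense, "max"))
  state$X <- state$X[ord, , drop = FALSE]
  state$fitness <- state$fitness[ord]
  n <- nrow(state$X)
  state$best <- state$X[1L, ]
  state$best_f <- state$fitness[1L]
  state$worst <- state$X[n, ]
  state$worst_f <- state$fitness[n]
  state$XP <- state$X[1L, ]
  state
}

#' Discoverer position update
#'
#' In a safe environment (`R2 < ST`) discoverer `i` contracts towards the
#' origin, `X * exp(-i / (alpha * iter_max))`; under alarm it takes a normal
#' step, `X + Q`. Positions are then pulled back into bounds.
#'
#' @param state an `ssa_state` (sorted, roles assigned).
#' @param config an [ssa_config()].
#' @param draws optional frozen draws for testing: list with scalar `R2`,
#'   vectors `alpha`, `Q` of length `n_disc`.
#' @return the updated state.
#' @export
update_discoverers <- function(state, config, draws = NULL) {
  nd <- state$n_disc
  R2 <- draws$R2 %||% stats::runif(1L)
  alpha <- draws$alpha %||% stats::runif(nd)
  Q <- draws$Q %||% stats::rnorm(nd)
  for (i in seq_len(nd)) {
    state$X[i, ] <- if (R2 < config$ST) {
      state$X[i, ] * exp(-i / (alpha[i] * config$iter_max))
    } else {
      state$X[i, ] + Q[i]
    }
  }
  state$X[seq_len(nd), ] <- apply_bounds(state$X[seq_len(nd), , drop = FALSE],
                                         config)
  state$XP <- state$X[1L, ]
  state
}

#' Participant position update
#'
#' Low-ranked participants (`i > n/2`) scatter towards the worst position's
#' complement, `Q * exp((X_worst - X) / i^2)`; the rest compete around the
#' best discoverer position `X_P` via the +/-1 row `A` and its pseudo-inverse
#' `A+ = t(A) (A t(A))^-1`, moving to `X_P + |X - X_P| A+ L`: the row vector
#' `|X - X_P|` (1 x d) times `A+` (d x 1) gives a signed scalar step that is
#' applied along the all-ones row `L`, contracting the participant towards
#' the discoverer's position.
#'
#' @param state an `ssa_state` with discoverers already updated (`X_P`
#'   current).
#' @param config an [ssa_config()].
#' @param draws optional frozen draws: vector `Q` (length n - n_disc) and
#'   +/-1 matrix `A` ((n - n_disc) x d).
#' @return the updated state.
#' @export
update_participants <- function(state, config, draws = NULL) {
  n <- config$n
  nd <- state$n_disc
  if (nd >= n) return(state)
  idx <- (nd + 1L):n
  Q <- draws$Q %||% stats::rnorm(length(idx))
  A <- draws$A %||% matrix(sample(c(-1, 1), length(idx) * state$d,
                                  replace = TRUE),
                           length(idx), state$d)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (i > n / 2) {
      state$X[i, ] <- Q[k] * exp((state$worst - state$X[i, ]) / i^2)
    } else {
      Arow <- matrix(A[k, ], 1L, state$d)
      Aplus <- t(Arow) %*% solve(Arow %*% t(Arow))
      L <- rep(1, state$d)
      step <- as.numeric(matrix(abs(state$X[i, ] - state$XP), 1L) %*% Aplus)
      state$X[i, ] <- state$XP + step * L
    }
  }
  state$X[idx, ] <- apply_bounds(state$X[idx, , drop = FALSE], config)
  state
}

#' Watchman position update
#'
#' A random 20% of the population (re-sampled each iteration, any role) react
#' to danger: a sparrow whose fitness is worse than the global best moves
#' towards the best position, `X_best + beta * |X - X_best|`; a sparrow
#' already at the best fitness moves relative to the worst,
#' `X + K * |X - X_worst| / ((f_i - f_w) + eps)`.
#'
#' @param state an `ssa_state` with current fitness values.
#' @param config an [ssa_config()].
#' @param draws optional frozen draws: integer vector `idx`, `beta` (vector
#'   of length `length(idx)`, or matrix `length(idx) x d` for per-dimension
#'   steps) and numeric `K` of length `length(idx)`.
#' @return the updated state; attribute `moved` lists the watchman indices.
#' @export
update_watchmen <- function(state, config, draws = NULL) {
  n <- config$n
  nw <- max(1L, floor(config$watchman_fraction * n))
  idx <- draws$idx %||% sample.int(n, nw)
  beta <- draws$beta %||% matrix(stats::rnorm(length(idx) * state$d),
                                 length(idx), state$d)
  if (is.null(dim(beta))) {
    beta <- matrix(beta, length(idx), state$d)
  }
  K <- draws$K %||% stats::runif(length(idx), -1, 1)
  for (k in seq_along(idx)) {
    i <- idx[k]
    fi <- state$fitness[i]
    if (is_worse(fi, state$best_f, config$sense) &&
        abs(fi - state$best_f) > config$tie_tol) {
      state$X[i, ] <- state$best + beta[k, ] * abs(state$X[i, ] - state$best)
    } else if (abs(fi - state$best_f) <= config$tie_tol) {
      state$X[i, ] <- state$X[i, ] +
        K[k] * (abs(state$X[i, ] - state$worst) /
                  ((fi - state$worst_f) + config$eps))
    }
  }
  state$X[idx, ] <- apply_bounds(state$X[idx, , drop = FALSE], config)
  attr(state, "moved") <- idx
  state
}

# keep a proposal only where it strictly improves that sparrow's own fitness
# (ties rejected, as in the reference implementation; accepting ties lets the
# population drift across fitness plateaus toward the bound corners)
greedy_merge <- function(state, proposal, idx, obj, config) {
  for (i in idx) {
    f_new <- obj(proposal$X[i, ])
    if (is_worse(state$fitness[i], f_new, config$sense)) {
      state$X[i, ] <- proposal$X[i, ]
      state$fitness[i] <- f_new
    }
  }
  state
}

refresh_best <- function(state, config) {
  i_best <- if (config$sense == "min") which.min(state$fitness) else
    which.max(state$fitness)
  i_worst <- if (config$sense == "min") which.max(state$fitness) else
    which.min(state$fitness)
  state$best <- state$X[i_best, ]
  state$best_f <- state$fitness[i_best]
  state$worst <- state$X[i_worst, ]
  state$worst_f <- state$fitness[i_worst]
  if (is_worse(state$best_ever_f, state$best_f, config$sense)) {
    state$best_ever <- state$best
    state$best_ever_f <- state$best_f
  }
  state
}

#' Run the sparrow search algorithm
#'
#' Iterates the three role updates with re-sorting and role re-assignment
#' each iteration. As in the reference formulation of the algorithm, each
#' sparrow keeps its personal-best position: a proposed move (Eqs. of
#' [update_discoverers()], [update_participants()], [update_watchmen()]) is
#' evaluated and retained only when it improves that sparrow's own fitness.
#' The global best is additionally tracked with elitism, so the reported
#' best fitness never worsens.
#'
#' @param objective function of an in-bounds position vector returning a
#'   finite scalar; an error raised by the objective aborts the run with the
#'   offending position in the message.
#' @param config an [ssa_config()].
#' @param d problem dimension (defaults to `nrow(config$bounds)`).
#' @return list with `position`, `fitness`, `history` (best fitness after
#'   each iteration), `evaluations` and the final `state`.
#' @export
run_ssa <- function(objective, config, d = nrow(config$bounds)) {
  stopifnot(inherits(config, "ssa_config"))
  n_eval <- 0L
  obj <- function(x) {
    val <- tryCatch(objective(x), error = function(e) {
      stop_nirmeat(sprintf(
        "run_ssa: objective failed at position (%s): %s",
        paste(signif(x, 4), collapse = ", "), conditionMessage(e)))
    })
    n_eval <<- n_eval + 1L
    val
  }
  with_local_seed(config$seed, {
    cfg <- config
    cfg$seed <- NULL  # the outer with_local_seed owns the stream
    state <- init_population(cfg, obj, d = d)
    history <- numeric(config$iter_max)
    nd <- state$n_disc
    for (t in seq_len(config$iter_max)) {
      state$t <- t
      state <- sort_population(state, cfg)
      prop <- update_discoverers(state, cfg)
      state <- greedy_merge(state, prop, seq_len(nd), obj, cfg)
      # X_P: the best discoverer position after this iteration's moves
      bd <- if (cfg$sense == "min") which.min(state$fitness[seq_len(nd)]) else
        which.max(state$fitness[seq_len(nd)])
      state$XP <- state$X[bd, ]
      if (nd < cfg$n) {
        prop <- update_participants(state, cfg)
        state <- greedy_merge(state, prop, (nd + 1L):cfg$n, obj, cfg)
      }
      state <- refresh_best(state, cfg)
      prop <- update_watchmen(state, cfg)
      state <- greedy_merge(state, prop, attr(prop, "moved"), obj, cfg)
      state <- refresh_best(state, cfg)
      history[t] <- state$best_ever_f
    }
    list(position = state$best_ever, fitness = state$best_ever_f,
         history = history, evaluations = n_eval, state = state)
  })
}
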