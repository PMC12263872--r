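#' Dragonfly algorithm configuration
#'
#' Position update `x_new = x_old + alpha * r + beta * Delta`, where `r`
#' is a fresh uniform(-1, 1) vector and `Delta` the difference between
#' two randomly selected other dragonflies. `alpha` decays linearly from
#' `alpha_start` to `alpha_end` over the run (strong exploration early,
#' exploitation late); `beta` weights the social difference vector.
#' Defaults follow the reference experiment settings: population 50,
#' 200 iterations, alpha 1 -> 0.1, beta 0.5.
#'
#' @param pop_size Population size (`>= 3`: the difference vector needs
#'   two distinct others).
#' @param n_iter Number of iterations.
#' @param alpha_start,alpha_end Randomness weight schedule endpoints.
#' @param beta Difference-vector weight.
#' @return Object of class `c("da_config", "swarm_config")`.
#' @export
da_config <- function(pop_size = 50, n_iter = 200,
                      alpha_start = 1.0, alpha_end = 0.1, beta = 0.5) {
  if (pop_size < 3) stop("dragonfly needs pop_size >= 3", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  structure(list(pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 beta = beta),
            class = c("da_config", "swarm_config"))
}

#' Firefly algorithm configuration
#'
#' Movement of firefly i toward every brighter j:
#' `X_i <- X_i + beta(r) * (X_j - X_i) + alpha * (rho - 0.5)` with
#' `beta(r) = beta0 * exp(-gamma * r^2)` and `rho` uniform(0, 1) per
#' dimension. `gamma = 0` recovers a constant attractiveness `beta0`.
#' Defaults follow the reference experiment: population 50, 200
#' iterations, alpha 0.2, beta0 1.0, gamma 1.0.
#'
#' @param pop_size Population size (`>= 2`).
#' @param n_iter Number of iterations.
#' @param alpha Randomization weight.
#' @param beta0 Attractiveness at zero distance.
#' @param gamma Light-absorption coefficient (`>= 0`).
#' @return Object of class `c("fa_config", "swarm_config")`.
#' @export
fa_config <- function(pop_size = 50, n_iter = 200,
                      alpha = 0.2, beta0 = 1.0, gamma = 1.0) {
  if (pop_size < 2) stop("firefly needs pop_size >= 2", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
                 alpha = alpha, beta0 = beta0, gamma = gamma),
            class = c("fa_config", "swarm_config"))
}

#' Moth-flame optimization configuration
#'
#' Logarithmic-spiral update
#' `X_i(t+1) = D_i * exp(b*t) * cos(2*pi*t) + F_j` around a shrinking
#' sorted flame set. Defaults follow the reference experiment:
#' population 50, 200 iterations, spiral shape `b = 1`.
#'
#' @param pop_size Population size (`>= 2`).
#' @param n_iter Number of iterations.
#' @param b Spiral shape constant.
#' @return Object of class `c("mfo_config", "swarm_config")`.
#' @export
mfo_config <- function(pop_size = 50, n_iter = 200, b = 1.0) {
  if (pop_size < 2) stop("moth-flame needs pop_size >= 2", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  structure(list(pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
                 b = b),
            class = c("mfo_config", "swarm_config"))
}

#' Linear randomness-weight schedule
#'
#' `alpha(it) = alpha_start - (alpha_start - alpha_end) * it / (n_iter - 1)`
#' for 0-based iteration `it`; a single-iteration run returns
#' `alpha_start`.
#'
#' @param iteration 0-based iteration index, `0 <= iteration < n_iter`.
#' @param n_iter Total iterations.
#' @param alpha_start,alpha_end Schedule endpoints.
#' @return The scheduled weight.
#' @export
alpha_schedule <- function(iteration, n_iter, alpha_start = 1.0,
                           alpha_end = 0.1) {
  if (iteration < 0 || iteration >= n_iter) {
    stop("iteration must satisfy 0 <= iteration < n_iter", call. = FALSE)
  }
  if (n_iter == 1) return(alpha_start)
  alpha_start - (alpha_start - alpha_end) * iteration / (n_iter - 1)
}

#' Distance-dependent firefly attractiveness
#'
#' `beta(r) = beta0 * exp(-gamma * r^2)`: maximal at zero distance and
#' strictly decreasing in `r` for `gamma > 0`; constant for `gamma = 0`.
#'
#' @param beta0 Attractiveness at distance 0.
#' @param gamma Light-absorption coefficient.
#' @param distance Non-negative distance.
#' @return Attractiveness value.
#' @export
attractiveness <- function(beta0, gamma, distance) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  beta0 * exp(-gamma * distance^2)
}

#' Flame-count schedule for moth-flame optimization
#'
#' `round(pop_size - iteration * (pop_size - 1) / n_iter)`, clamped to
#' `[1, pop_size]`: all moths chase distinct flames at the start, and
#' the flame set shrinks toward a single flame by the final iteration.
#'
#' @param iteration 0-based iteration index.
#' @param n_iter Total iterations.
#' @param pop_size Population size.
#' @return Integer number of flames.
#' @export
flame_count <- function(iteration, n_iter, pop_size) {
  if (iteration < 0 || iteration >= n_iter) {
    stop("iteration must satisfy 0 <= iteration < n_iter", call. = FALSE)
  }
  as.integer(max(1, min(pop_size,
                        round(pop_size - iteration * (pop_size - 1) / n_iter))))
}

# --- swarm state -----------------------------------------------------------

clip_to_bounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

evaluate_positions <- function(positions, objective) {
  vapply(seq_len(nrow(positions)),
         function(i) objective(positions[i, ]), numeric(1))
}

#' Initialize a swarm state
#'
#' Positions are drawn uniformly inside the box bounds; fitnesses are
#' evaluated once and the incumbent recorded.
#'
#' @param objective Function mapping a position vector to a scalar to
#'   minimize; must be pure.
#' @param lower,upper Finite numeric bound vectors (length D).
#' @param pop_size Number of agents.
#' @return Object of class `swarm_state`: list with `positions`
#'   (pop x D), `fitness`, `best_position`, `best_fitness`, `iteration`
#'   (completed steps), `lower`, `upper`, `flames` (moth-flame only).
#' @export
init_swarm <- function(objective, lower, upper, pop_size) {
  if (length(lower) != length(upper)) stop("bound length mismatch", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  D <- length(lower)
  positions <- matrix(stats::runif(pop_size * D), nrow = pop_size)
  positions <- sweep(sweep(positions, 2, upper - lower, `*`), 2, lower, `+`)
  fitness <- evaluate_positions(positions, objective)
  ib <- which.min(fitness)
  structure(list(positions = positions, fitness = fitness,
                 best_position = positions[ib, ], best_fitness = fitness[ib],
                 iteration = 0L, lower = lower, upper = upper, flames = NULL),
            class = "swarm_state")
}

update_incumbent <- function(state) {
  ib <- which.min(state$fitness)
  if (state$fitness[ib] < state$best_fitness) {
    state$best_fitness <- state$fitness[ib]
    state$best_position <- state$positions[ib, ]
  }
  state
}

#' One dragonfly-algorithm iteration
#'
#' Synchronous sweep: each agent moves by `alpha * r + beta * Delta`
#' with `r` uniform(-1, 1) per dimension and `Delta` the difference of
#' two distinct randomly chosen other agents (evaluated on the
#' pre-step positions). `alpha` comes from [alpha_schedule()] at the
#' state's iteration counter.
#'
#' @param state A `swarm_state`.
#' @param cfg A [da_config()].
#' @param objective Objective function (minimized).
#' @return The advanced `swarm_state`.
#' @export
da_step <- function(state, cfg, objective) {
  stopifnot(inherits(state, "swarm_state"), inherits(cfg, "da_config"))
  pop <- nrow(state$positions)
  if (pop < 3) stop("dragonfly step needs >= 3 agents", call. = FALSE)
  D <- ncol(state$positions)
  alpha <- alpha_schedule(state$iteration, cfg$n_iter,
                          cfg$alpha_start, cfg$alpha_end)
  old <- state$positions
  for (i in seq_len(pop)) {
    others <- seq_len(pop)[-i]
    ab <- others[sample.int(pop - 1L, 2L)]
    r <- stats::runif(D, -1, 1)
    delta <- old[ab[1L], ] - old[ab[2L], ]
    state$positions[i, ] <- clip_to_bounds(
      old[i, ] + alpha * r + cfg$beta * delta, state$lower, state$upper)
  }
  state$fitness <- evaluate_positions(state$positions, objective)
  state$iteration <- state$iteration + 1L
  update_incumbent(state)
}

#' One firefly-algorithm iteration
#'
#' Asynchronous index-order sweep: firefly i moves once toward every
#' currently brighter j (lower fitness), each move adding the
#' attraction term and an `alpha * (rho - 0.5)` random walk; the
#' brightest firefly performs only the random walk. Each firefly is
#' re-evaluated once after its full sweep, so later fireflies see
#' updated brightnesses.
#'
#' @param state A `swarm_state`.
#' @param cfg A [fa_config()].
#' @param objective Objective function (minimized).
#' @return The advanced `swarm_state`.
#' @export
fa_step <- function(state, cfg, objective) {
  stopifnot(inherits(state, "swarm_state"), inherits(cfg, "fa_config"))
  pop <- nrow(state$positions)
  if (pop < 2) stop("firefly step needs >= 2 agents", call. = FALSE)
  D <- ncol(state$positions)
  for (i in seq_len(pop)) {
    xi <- state$positions[i, ]
    moved <- FALSE
    for (j in seq_len(pop)) {
      if (state$fitness[j] < state$fitness[i]) {
        xj <- state$positions[j, ]
        beta <- attractiveness(cfg$beta0, cfg$gamma,
                               sqrt(sum((xj - xi)^2)))
        xi <- xi + beta * (xj - xi) + cfg$alpha * (stats::runif(D) - 0.5)
        moved <- TRUE
      }
    }
    if (!moved) {  # brightest: pure random walk
      xi <- xi + cfg$alpha * (stats::runif(D) - 0.5)
    }
    xi <- clip_to_bounds(xi, state$lower, state$upper)
    state$positions[i, ] <- xi
    state$fitness[i] <- objective(xi)
  }
  state$iteration <- state$iteration + 1L
  update_incumbent(state)
}

#' One moth-flame-optimization iteration
#'
#' Flames are the best [flame_count()] positions from the sorted union
#' of the previous flames and the current moths. Moth i spirals around
#' its assigned flame (`min(i, n_flames)`) per dimension:
#' `X = D * exp(b*t) * cos(2*pi*t) + F` with `t` uniform(-1, 1) and
#' `D = |F - X|`.
#'
#' @param state A `swarm_state`.
#' @param cfg An [mfo_config()].
#' @param iteration 0-based iteration index used by the flame schedule
#'   (defaults to the state's own counter).
#' @param objective Objective function (minimized).
#' @return The advanced `swarm_state`.
#' @export
mfo_step <- function(state, cfg, iteration = state$iteration, objective) {
  stopifnot(inherits(state, "swarm_state"), inherits(cfg, "mfo_config"))
  pop <- nrow(state$positions)
  D <- ncol(state$positions)
  cand_pos <- rbind(if (!is.null(state$flames)) state$flames$positions,
                    state$positions)
  cand_fit <- c(if (!is.null(state$flames)) state$flames$fitness,
                state$fitness)
  nf <- flame_count(iteration, cfg$n_iter, pop)
  keep <- order(cand_fit)[seq_len(nf)]
  flame_pos <- cand_pos[keep, , drop = FALSE]
  flame_fit <- cand_fit[keep]
  for (i in seq_len(pop)) {
    j <- min(i, nf)
    f <- flame_pos[j, ]
    t_rand <- stats::runif(D, -1, 1)
    dist <- abs(f - state$positions[i, ])
    state$positions[i, ] <- clip_to_bounds(
      dist * exp(cfg$b * t_rand) * cos(2 * pi * t_rand) + f,
      state$lower, state$upper)
  }
  state$fitness <- evaluate_positions(state$positions, objective)
  state$flames <- list(positions = flame_pos, fitness = flame_fit)
  state$iteration <- state$iteration + 1L
  update_incumbent(state)
}

#' Run a swarm optimizer on a box-bounded objective
#'
#' Unified driver for the dragonfly, firefly and moth-flame algorithms:
#' initializes the population uniformly inside the bounds under `seed`,
#' runs `n_iter` steps, and returns the incumbent and its history. The
#' total number of objective evaluations is
#' `pop_size * (n_iter + 1)` (one initial sweep plus one per
#' iteration).
#'
#' @param objective Pure function: position vector -> scalar (minimized).
#' @param lower,upper Finite bound vectors, one entry per dimension.
#' @param kind One of `"dragonfly"`, `"firefly"`, `"mothflame"`.
#' @param config Matching `*_config()` object; defaults to the kind's
#'   defaults.
#' @param seed Integer seed controlling every random draw of the run.
#' @return Object of class `optimization_result`: `best_position`,
#'   `best_fitness`, `history` (per-iteration incumbent fitness,
#'   length `n_iter`), `evaluations`, `final_positions`,
#'   `final_fitness`, `kind`, `seed`.
#' @examples
#' res <- swarm_optimize(function(x) sum(x^2), lower = rep(-5, 2),
#'                       upper = rep(5, 2), kind = "firefly",
#'                       config = fa_config(pop_size = 10, n_iter = 20),
#'                       seed = 1)
#' res$best_fitness
#' @export
swarm_optimize <- function(objective, lower, upper,
                           kind = c("dragonfly", "firefly", "mothflame"),
                           config = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(config)) {
    config <- switch(kind, dragonfly = da_config(), firefly = fa_config(),
                     mothflame = mfo_config())
  }
  expected <- switch(kind, dragonfly = "da_config", firefly = "fa_config",
                     mothflame = "mfo_config")
  if (!inherits(config, expected)) {
    stop(sprintf("config must be a %s for kind '%s'", expected, kind),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  state <- init_swarm(objective, lower, upper, config$pop_size)
  history <- numeric(config$n_iter)
  for (it in seq_len(config$n_iter)) {
    state <- switch(kind,
      dragonfly = da_step(state, config, objective),
      firefly = fa_step(state, config, objective),
      mothflame = mfo_step(state, config, iteration = it - 1L,
                           objective = objective))
    history[it] <- state$best_fitness
  }
  structure(list(best_position = state$best_position,
                 best_fitness = state$best_fitness,
                 history = history,
                 evaluations = config$pop_size * (config$n_iter + 1L),
                 final_positions = state$positions,
                 final_fitness = state$fitness,
                 kind = kind, seed = as.integer(seed)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result: %s, best fitness %.6g after %d evaluations>\n",
              x$kind, x$best_fitness, x$evaluations))
  invisible(x)
}

#' Write a convergence history as delimited text
#'
#' @param result An `optimization_result`.
#' @param path Output CSV path (columns `iteration`, `best_fitness`).
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  stopifnot(inherits(result, "optimization_result"))
  utils::write.csv(data.frame(iteration = seq_along(result$history),
                              best_fitness = result$history),
                   path, row.names = FALSE)
  invisible(path)
}
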