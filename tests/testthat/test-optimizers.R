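test_that("alpha schedule interpolates linearly between its endpoints", {
  expect_equal(alpha_schedule(0, 200, 1.0, 0.1), 1.0)
  expect_equal(alpha_schedule(199, 200, 1.0, 0.1), 0.1)
  expect_equal(alpha_schedule(100, 200, 1.0, 0.1), 1.0 - 0.9 * 100 / 199)
  expect_equal(alpha_schedule(0, 1, 0.7, 0.1), 0.7)
  expect_error(alpha_schedule(200, 200), "iteration")
  expect_error(alpha_schedule(-1, 200), "iteration")
})

test_that("attractiveness decays as beta0 * exp(-gamma r^2)", {
  expect_equal(attractiveness(2.5, 1, 0), 2.5)
  expect_equal(attractiveness(1, 1, 1), exp(-1))
  r <- seq(0, 3, by = 0.5)
  expect_equal(attractiveness(1, 0, r), rep(1, length(r)))  # constant-beta mode
  vals <- attractiveness(1, 2, r)
  expect_true(all(diff(vals) < 0))
  expect_error(attractiveness(1, 1, -0.1), ">= 0")
})

test_that("flame count shrinks from pop_size to 1", {
  expect_equal(flame_count(0, 200, 50), 50L)
  expect_equal(flame_count(199, 200, 50), 1L)
  expect_equal(flame_count(100, 200, 50), 26L)
  counts <- vapply(0:199, flame_count, integer(1), n_iter = 200,
                   pop_size = 50)
  expect_true(all(diff(counts) <= 0))
  expect_true(all(counts >= 1 & counts <= 50))
})

test_that("dragonfly step implements x + alpha r + beta Delta", {
  obj <- function(x) sum(x^2)
  # alpha = 0 (via equal schedule endpoints at 0) and beta = 0: frozen swarm
  cfg0 <- da_config(pop_size = 5, n_iter = 3, alpha_start = 0,
                    alpha_end = 0, beta = 0)
  set.seed(1)
  st <- init_swarm(obj, rep(-5, 3), rep(5, 3), 5)
  st2 <- da_step(st, cfg0, obj)
  expect_equal(st2$positions, st$positions)
  expect_equal(st2$fitness, st$fitness)

  # 1-D hand case: x=0, alpha=0.5, forced r=1 via degenerate runif bounds
  # is not injectable, so verify the arithmetic on the recorded draws:
  # run one step with pop 3 and reconstruct the update from the RNG.
  cfg <- da_config(pop_size = 3, n_iter = 1, alpha_start = 0.5,
                   alpha_end = 0.5, beta = 0.5)
  set.seed(7)
  st <- init_swarm(obj, -5, 5, 3)
  old <- st$positions
  set.seed(99)
  st2 <- da_step(st, cfg, obj)
  set.seed(99)
  expected <- old
  for (i in 1:3) {
    ab <- (1:3)[-i][sample.int(2, 2)]
    r <- runif(1, -1, 1)
    expected[i, ] <- pmin(pmax(
      old[i, ] + 0.5 * r + 0.5 * (old[ab[1], ] - old[ab[2], ]), -5), 5)
  }
  expect_equal(st2$positions, expected)
  # hand instance with those numbers: 0 + 0.5*1 + 0.5*2 = 1.5
  expect_equal(0 + 0.5 * 1 + 0.5 * 2, 1.5)
})

test_that("firefly step matches the attraction equation", {
  obj <- function(x) sum(x^2)
  mk_state <- function(positions) {
    st <- structure(list(positions = positions,
                         fitness = apply(positions, 1, obj),
                         best_position = positions[1, ], best_fitness = Inf,
                         iteration = 0L,
                         lower = rep(-10, ncol(positions)),
                         upper = rep(10, ncol(positions)), flames = NULL),
                    class = "swarm_state")
    st$best_fitness <- min(st$fitness)
    st
  }
  # full attraction (gamma = 0, beta0 = 1), alpha = 0: i lands on j
  st <- mk_state(rbind(c(5, 5), c(1, 1)))
  cfg <- fa_config(pop_size = 2, n_iter = 1, alpha = 0, beta0 = 1, gamma = 0)
  st2 <- fa_step(st, cfg, obj)
  expect_equal(st2$positions[1, ], c(1, 1))

  # half-step: beta = 0.5 constant, 1-D, 0 moves toward 2 -> 1
  st <- mk_state(rbind(matrix(4, 1, 1), matrix(2, 1, 1)))
  # make agent 1 at 4 brighter? no: fitness(2) < fitness(4), so 4 -> 3
  cfg <- fa_config(pop_size = 2, n_iter = 1, alpha = 0, beta0 = 0.5,
                   gamma = 0)
  st2 <- fa_step(st, cfg, obj)
  expect_equal(st2$positions[1, 1], 3)

  # equal fitness everywhere and alpha = 0: nobody moves
  st <- mk_state(rbind(c(2, 0), c(0, 2), c(-2, 0)))
  cfg <- fa_config(pop_size = 3, n_iter = 1, alpha = 0, beta0 = 1, gamma = 1)
  st2 <- fa_step(st, cfg, obj)
  expect_equal(st2$positions, st$positions)
})

test_that("moth-flame spiral matches hand evaluations", {
  # scalar spiral: D=2, b=1, t=0 -> D + F = 5; t=-1 -> 2/e + 3
  b <- 1
  spiral <- function(D, t, F) D * exp(b * t) * cos(2 * pi * t) + F
  expect_equal(spiral(2, 0, 3), 5)
  expect_equal(spiral(2, -1, 3), 2 * exp(-1) * cos(-2 * pi) + 3)
  expect_equal(spiral(0, 0.37, 3), 3)  # moth at its flame stays

  # a moth exactly at its flame stays there for any t draw
  obj <- function(x) sum(x^2)
  st <- structure(list(positions = matrix(0, 2, 2),
                       fitness = c(0, 0), best_position = c(0, 0),
                       best_fitness = 0, iteration = 0L,
                       lower = rep(-5, 2), upper = rep(5, 2), flames = NULL),
                  class = "swarm_state")
  cfg <- mfo_config(pop_size = 2, n_iter = 5)
  set.seed(3)
  st2 <- mfo_step(st, cfg, iteration = 0L, objective = obj)
  expect_equal(st2$positions, matrix(0, 2, 2))
})

test_that("incumbent monotone, bounds kept, runs reproducible (properties)", {
  objectives <- list(sphere = sphere,
                     shifted = function(x) sum((x - 1)^2),
                     rastrigin = function(x) {
                       sum(x^2 - 10 * cos(2 * pi * x) + 10)
                     })
  kinds <- c("dragonfly", "firefly", "mothflame")
  case <- 0L
  for (kind in kinds) {
    for (rep_i in 1:6) {
      case <- case + 1L
      obj <- objectives[[1L + (case %% length(objectives))]]
      D <- 1L + (case %% 4L)
      cfg <- make_config(kind, pop = 6, iters = 8)
      res <- swarm_optimize(obj, rep(-5, D), rep(5, D), kind, cfg,
                            seed = 1000 + case)
      expect_length(res$history, 8)
      expect_true(all(diff(res$history) <= 0))
      expect_equal(res$best_fitness, min(res$history))
      expect_true(all(res$final_positions >= -5 & res$final_positions <= 5))
      expect_equal(res$evaluations, 6 * 9)
      # bit reproducibility
      res2 <- swarm_optimize(obj, rep(-5, D), rep(5, D), kind, cfg,
                             seed = 1000 + case)
      expect_identical(res$best_position, res2$best_position)
      expect_identical(res$history, res2$history)
    }
  }
})

test_that("flat objective yields best fitness 0 from iteration 0", {
  for (kind in c("dragonfly", "firefly", "mothflame")) {
    res <- swarm_optimize(function(x) 0, rep(-1, 2), rep(1, 2), kind,
                          make_config(kind, 5, 4), seed = 2)
    expect_equal(res$history, rep(0, 4))
    expect_equal(res$best_fitness, 0)
  }
})

test_that("firefly and moth-flame beat random search on the 2-D sphere", {
  # The as-printed dragonfly update (random walk + pairwise difference,
  # no attraction term) is statistically indistinguishable from random
  # search on the sphere; see the vignette. The paired-seed dominance
  # property is asserted for the two optimizers that possess an
  # exploitation mechanism.
  for (kind in c("firefly", "mothflame")) {
    wins <- vapply(1:10, function(s) {
      cfg <- make_config(kind, 20, 50)
      b <- swarm_optimize(sphere, c(-5, -5), c(5, 5), kind, cfg,
                          seed = s)$best_fitness
      rs <- random_search_best(sphere, c(-5, -5), c(5, 5),
                               n = 20 * 51, seed = 10000 + s)
      b < rs
    }, logical(1))
    expect_gte(sum(wins), 9)
  }
})

test_that("configuration validation rejects bad inputs", {
  expect_error(da_config(pop_size = 2), ">= 3")
  expect_error(fa_config(pop_size = 1), ">= 2")
  expect_error(fa_config(gamma = -1), ">= 0")
  expect_error(swarm_optimize(sphere, -5, 5, "simulated_annealing"),
               "arg")
  expect_error(swarm_optimize(sphere, c(-5, -5), 5, "firefly"),
               "mismatch")
  expect_error(swarm_optimize(sphere, -5, 5, "firefly",
                              config = da_config()), "fa_config")
})

test_that("convergence history export is well-formed", {
  res <- swarm_optimize(sphere, -5, 5, "mothflame", mfo_config(5, 6),
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(res, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("iteration", "best_fitness"))
  expect_equal(tab$best_fitness, res$history)
})
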