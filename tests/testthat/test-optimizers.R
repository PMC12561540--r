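test_that("population initialisation respects ranges, modes and seeds", {
  cfg <- optimizer_config("jde", np = 30, max_evals = 3000, seed = 1)
  bounds <- threshold_bounds()
  rng <- efscontrol:::local_rng(1)
  pop <- initialize_population(10, cfg, sa_mode = FALSE, bounds, rng,
                               mock_eval_mean, theta_global = 0.5)
  expect_identical(dim(pop$genes), c(30L, 10L))
  expect_true(all(pop$genes >= 0 & pop$genes <= 1))
  expect_null(pop$theta)
  expect_equal(pop$F, rep(0.5, 30))
  expect_equal(pop$CR, rep(0.9, 30))
  # determinism
  pop2 <- initialize_population(10, cfg, FALSE, bounds,
                                efscontrol:::local_rng(1), mock_eval_mean,
                                0.5)
  expect_identical(pop, pop2)
  # SA mode adds bounded theta genes
  pop3 <- initialize_population(10, cfg, TRUE, bounds,
                                efscontrol:::local_rng(1), mock_eval_mean)
  expect_length(pop3$theta, 30)
  expect_true(all(pop3$theta >= 0.1 & pop3$theta <= 0.9))
  expect_error(optimizer_config("de", np = 3), "np >= 4")
  expect_error(optimizer_config("jde", np = 30, max_evals = 20), "budget")
})

test_that("DE/rand/1/bin follows the mutation and crossover arithmetic", {
  tgt <- c(0.2, 0.2, 0.2)
  # zero difference vector, CR = 1 -> trial equals x_r1
  tr <- de_rand_1_bin(tgt, c(.6, .6, .6), c(.3, .3, .3), c(.3, .3, .3),
                      F = 0.5, CR = 1, rand_cr = rep(0.5, 3), j_rand = 1)
  expect_equal(tr, rep(0.6, 3))
  # CR = 0 -> exactly one coordinate (j_rand) from the mutant
  tr0 <- de_rand_1_bin(tgt, c(.6, .6, .6), c(.9, .9, .9), c(.1, .1, .1),
                       F = 0.5, CR = 0, rand_cr = rep(0.5, 3), j_rand = 2)
  expect_equal(sum(tr0 != tgt), 1)
  expect_equal(tr0[2], 0.6 + 0.5 * 0.8)
  # direct arithmetic
  tr1 <- de_rand_1_bin(0.0, 0.5, 0.9, 0.1, F = 0.5, CR = 1,
                       rand_cr = 0, j_rand = 1)
  expect_equal(tr1, 0.9)
})

test_that("jDE regeneration probabilities and ranges hold", {
  # tau = 0: always inherit
  a <- jde_adapt(0.33, 0.44, tau1 = 0, tau2 = 0, u = runif(4))
  expect_equal(a, list(F = 0.33, CR = 0.44))
  # tau = 1: always regenerate, into the documented ranges
  set.seed(2)
  for (i in 1:50) {
    a <- jde_adapt(0.33, 0.44, tau1 = 1, tau2 = 1, u = runif(4))
    expect_true(a$F >= 0.1 && a$F <= 1.0)
    expect_true(a$CR >= 0 && a$CR <= 1)
  }
  # regeneration frequency ~ tau over many draws (3 sigma band)
  set.seed(3)
  n <- 10000
  hits <- sum(replicate(n, jde_adapt(0.5, 0.5, u = runif(4))$F != 0.5))
  expect_lt(abs(hits / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("DE selection minimizes with ties favouring the trial", {
  expect_true(de_select(0.3, 0.2))
  expect_true(de_select(0.3, 0.3))
  expect_false(de_select(0.2, 0.3))
})

test_that("PSO update is a fixed point at consensus and moves toward gbest", {
  # stationary when x = pbest = gbest and v = 0
  mv <- pso_step(rep(.4, 3), rep(0, 3), rep(.4, 3), rep(.4, 3),
                 w = 0.7, c1 = 1.5, c2 = 1.5, r1 = runif(3), r2 = runif(3))
  expect_equal(mv$x, rep(.4, 3))
  # frozen swarm when all coefficients vanish
  mv0 <- pso_step(c(.1, .9), c(.2, -.2), c(.5, .5), c(.5, .5),
                  w = 0, c1 = 0, c2 = 0, r1 = runif(2), r2 = runif(2))
  expect_equal(mv0$x, c(.1, .9))
  # gbest pull only: moves strictly toward gbest
  mv1 <- pso_step(0.2, 0, 0.2, 0.8, w = 0, c1 = 0, c2 = 1.5,
                  r1 = 0.5, r2 = 0.5)
  expect_gt(mv1$x, 0.2)
  expect_lte(mv1$x, 0.8)
  # velocity clamp
  mv2 <- pso_step(0, 0, 0, 10, w = 0, c1 = 0, c2 = 2, r1 = 1, r2 = 1)
  expect_equal(mv2$v, 1)
})

test_that("random search emits uniform seed-deterministic genotypes", {
  r1 <- efscontrol:::local_rng(5)
  r2 <- efscontrol:::local_rng(5)
  g1 <- random_search_step(50, r1)
  expect_true(all(g1 >= 0 & g1 <= 1))
  expect_identical(g1, random_search_step(50, r2))
  # uniform marginals (KS test at n = 1e4)
  r3 <- efscontrol:::local_rng(6)
  ks <- suppressWarnings(ks.test(random_search_step(1e4, r3), "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("evolve respects the budget and keeps an elitist best trace", {
  cfg <- optimizer_config("jde", np = 10, max_evals = 10, seed = 1)
  ctrl <- make_controller("static")
  rec <- evolve(5, mock_eval_mean, cfg, ctrl)
  expect_equal(rec$generations, 0L)  # budget floor: init only
  expect_equal(rec$gtc, 0L)
  expect_length(rec$best_fitness, 1)

  for (alg in c("jde", "de", "pso", "rs")) {
    cfg <- optimizer_config(alg, np = 10, max_evals = 200, seed = 2)
    rec <- evolve(8, mock_eval_mean, cfg, make_controller("static"))
    expect_lte(max(rec$evals), 200)
    expect_equal(max(rec$evals), 10 + rec$generations * 10)
    expect_true(all(diff(rec$best_fitness) <= 0))
    # replay
    rec2 <- evolve(8, mock_eval_mean, cfg, make_controller("static"))
    expect_identical(rec, rec2)
  }
})

test_that("jDE minimizes an analytic objective within the standard budget", {
  cfg <- optimizer_config("jde", np = 30, max_evals = 3000, seed = 4)
  rec <- evolve(20, mock_eval_mean, cfg, make_controller("static"))
  expect_lt(rec$best$fitness, 0.05)   # mean genotype driven near 0
})

test_that("genotypes and theta genes never leave their boxes during evolution", {
  capture_eval <- local({
    seen <- new.env(); seen$bad <- FALSE
    function(genotype, theta) {
      if (any(genotype < 0 | genotype > 1)) seen$bad <<- TRUE
      if (!is.na(theta) && (theta < 0.1 - 1e-12 || theta > 0.9 + 1e-12))
        seen$bad <<- TRUE
      list(fitness = mean(genotype) + theta / 10, accuracy = 0,
           subset_size = 0L, bad = seen$bad)
    }
  })
  for (alg in c("jde", "pso", "rs")) {
    cfg <- optimizer_config(alg, np = 8, max_evals = 160, seed = 3)
    rec <- evolve(6, capture_eval, cfg, make_controller("sa"))
    expect_true(all(rec$best$genotype >= 0 & rec$best$genotype <= 1))
    expect_true(rec$best$theta >= 0.1 && rec$best$theta <= 0.9)
  }
})

test_that("the optimizer registry accepts external plug-ins", {
  # a do-nothing backend: keeps the population, burns np evaluations
  prev <- register_optimizer("noop", function(pop, ctx) {
    for (i in seq_len(ctx$np)) ctx$eval_fn(pop$genes[i, ], ctx$theta)
    pop
  })
  on.exit(if (is.null(prev)) register_optimizer("noop", NULL))
  cfg <- optimizer_config("noop", np = 5, max_evals = 20, seed = 1)
  rec <- evolve(4, mock_eval_mean, cfg, make_controller("static"))
  expect_equal(rec$generations, 3L)
  expect_equal(diff(rec$best_fitness), rep(0, 3))
})
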