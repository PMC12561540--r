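#' Optimizer configuration
#'
#' @param algorithm \code{"jde"} (self-adaptive differential evolution,
#'   the study's strongest baseline), \code{"de"} (DE/rand/1/bin with fixed
#'   F and CR), \code{"pso"} (particle swarm optimisation) or \code{"rs"}
#'   (random search). Further algorithms can be plugged in via
#'   [register_optimizer].
#' @param np population size (default 30); DE variants need \code{np >= 4}.
#' @param max_evals evaluation budget including the initial population
#'   (default 3000).
#' @param seed integer root seed for the run.
#' @param params named list of algorithm constants overriding the
#'   defaults: DE \code{F = 0.5}, \code{CR = 0.9}; jDE \code{Fl = 0.1},
#'   \code{Fu = 0.9}, \code{tau1 = tau2 = 0.1}; PSO \code{w = 0.7},
#'   \code{c1 = c2 = 1.5}.
#' @return A list of class \code{optimizer_config}.
#' @export
optimizer_config <- function(algorithm = c("jde", "de", "pso", "rs"),
                             np = 30L, max_evals = 3000L, seed = 1L,
                             params = list()) {
  algorithm <- if (is.character(algorithm) && length(algorithm) > 1L)
    match.arg(algorithm) else algorithm
  if (!algorithm %in% names(optimizer_registry$steps))
    stop("unknown optimizer '", algorithm, "'")
  if (algorithm %in% c("jde", "de") && np < 4L)
    stop("DE variants need np >= 4 (three distinct donors plus the target)")
  if (max_evals < np) stop("evaluation budget smaller than the population")
  defaults <- switch(algorithm,
    de = list(F = 0.5, CR = 0.9),
    jde = list(Fl = 0.1, Fu = 0.9, tau1 = 0.1, tau2 = 0.1),
    pso = list(w = 0.7, c1 = 1.5, c2 = 1.5),
    list())
  params <- utils::modifyList(defaults, params)
  structure(list(algorithm = algorithm, np = as.integer(np),
                 max_evals = as.integer(max_evals), seed = as.integer(seed),
                 params = params),
            class = "optimizer_config")
}

optimizer_registry <- new.env(parent = emptyenv())
optimizer_registry$steps <- list()

#' Register an optimizer backend
#'
#' Extends the generic evolutionary loop with a new variation mechanism.
#' The step function receives the internal population state and must
#' produce, evaluate and select one generation; GA, ABC or LSHADE backends
#' can be attached this way without touching the loop.
#'
#' @param name algorithm identifier used in [optimizer_config].
#' @param step_fn function \code{(pop, ctx) -> pop} advancing one
#'   generation; see the built-in backends in the package source for the
#'   contract.
#' @return Invisibly, the previous registration (or NULL).
#' @export
register_optimizer <- function(name, step_fn) {
  prev <- optimizer_registry$steps[[name]]
  optimizer_registry$steps[[name]] <- step_fn
  invisible(prev)
}

# ---- variation operators -------------------------------------------------

#' DE/rand/1 mutation with binomial crossover
#'
#' Builds the mutant \code{v = x_r1 + F (x_r2 - x_r3)} and crosses it with
#' the target: coordinate j takes the mutant value when \code{rand_j < CR}
#' or \code{j == j_rand}, otherwise the target's. The caller projects the
#' trial into its box.
#'
#' @param target numeric target vector.
#' @param x_r1,x_r2,x_r3 three donor vectors, pairwise distinct from each
#'   other and from the target.
#' @param F scale factor.
#' @param CR crossover rate in \code{[0,1]}.
#' @param rand_cr uniform draws in \code{[0,1)}, one per coordinate.
#' @param j_rand index forced to take the mutant value.
#' @return The trial vector (not yet projected).
#' @export
de_rand_1_bin <- function(target, x_r1, x_r2, x_r3, F, CR, rand_cr, j_rand) {
  v <- x_r1 + F * (x_r2 - x_r3)
  take <- rand_cr < CR
  take[j_rand] <- TRUE
  ifelse(take, v, target)
}

#' jDE strategy-parameter adaptation
#'
#' With probability tau1 the scale factor is regenerated as
#' \code{Fl + rand * Fu}, otherwise inherited; with probability tau2 the
#' crossover rate is regenerated uniformly on \code{[0,1]}. The adapted
#' values build the trial and survive only if the trial replaces its
#' parent.
#'
#' @param F,CR the parent's current strategy parameters.
#' @param Fl,Fu lower bound and range of the scale factor (defaults
#'   0.1 / 0.9).
#' @param tau1,tau2 regeneration probabilities (defaults 0.1).
#' @param u four uniform draws in \code{[0,1)}.
#' @return List with the (possibly regenerated) \code{F} and \code{CR}.
#' @export
jde_adapt <- function(F, CR, Fl = 0.1, Fu = 0.9, tau1 = 0.1, tau2 = 0.1,
                      u = stats::runif(4)) {
  stopifnot(Fl > 0, Fu > 0, tau1 >= 0, tau1 <= 1, tau2 >= 0, tau2 <= 1)
  list(F = if (u[1] < tau1) Fl + u[2] * Fu else F,
       CR = if (u[3] < tau2) u[4] else CR)
}

#' Greedy DE survivor selection
#'
#' Minimization with ties favouring the trial, which lets the search drift
#' across plateaus of equal fitness.
#'
#' @param parent_fitness,trial_fitness scalar fitness values.
#' @return TRUE when the trial survives.
#' @export
de_select <- function(parent_fitness, trial_fitness) {
  trial_fitness <= parent_fitness
}

#' One particle-swarm velocity/position update
#'
#' \code{v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)}; velocities are
#' clamped to \code{[-1, 1]} and the new position is returned unprojected
#' (the caller applies the box projection).
#'
#' @param x,v position and velocity vectors.
#' @param pbest,gbest personal and global best positions.
#' @param w,c1,c2 inertia, cognitive and social coefficients.
#' @param r1,r2 uniform draws in \code{[0,1)}, one per coordinate.
#' @return List with new \code{x} and \code{v}.
#' @export
pso_step <- function(x, v, pbest, gbest, w, c1, c2, r1, r2) {
  v <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  v <- pmin(pmax(v, -1), 1)
  list(x = x + v, v = v)
}

#' Fresh uniform genotype for random search
#'
#' @param n number of problem genes.
#' @param rng a stream from the package's internal RNG (any list with a
#'   \code{runif} element).
#' @return A uniform vector in \code{[0,1]^n}.
#' @export
random_search_step <- function(n, rng) rng$runif(n)

# Project problem genes into [0,1] and, in self-adaptive mode, the trailing
# threshold gene into its bounds.
project_genes <- function(x) pmin(pmax(x, 0), 1)

# ---- population initialisation ------------------------------------------

#' Initialize and evaluate a population
#'
#' Genes are uniform on \code{[0,1]}; in self-adaptive mode every
#' individual additionally draws a threshold gene uniform on the threshold
#' bounds. jDE individuals start with F = 0.5 and CR = 0.9. All
#' individuals are evaluated, consuming \code{np} evaluations of the
#' budget.
#'
#' @param n number of features (problem genes).
#' @param cfg an [optimizer_config].
#' @param sa_mode TRUE when the controller is self-adaptive.
#' @param bounds an [threshold_bounds] (used for the threshold genes).
#' @param rng an internal RNG stream.
#' @param eval_fn function \code{(genotype, theta) -> list(fitness,
#'   accuracy, subset_size)}.
#' @param theta_global the global threshold used to evaluate the initial
#'   population when not in self-adaptive mode.
#' @return The internal population state (matrix of genes plus per-slot
#'   vectors).
#' @export
initialize_population <- function(n, cfg, sa_mode, bounds, rng, eval_fn,
                                  theta_global = NA_real_) {
  stopifnot(n >= 1L)
  np <- cfg$np
  genes <- matrix(rng$runif(np * n), np, n)
  theta <- if (sa_mode) rng$runif(np, bounds$theta_min, bounds$theta_max)
           else NULL
  pop <- list(genes = genes, theta = theta,
              F = if (cfg$algorithm == "jde") rep(0.5, np),
              CR = if (cfg$algorithm == "jde") rep(0.9, np),
              vel = if (cfg$algorithm == "pso")
                matrix(0, np, n + as.integer(sa_mode)),
              fitness = numeric(np), accuracy = numeric(np),
              subset_size = integer(np))
  for (i in seq_len(np)) {
    th <- if (sa_mode) theta[i] else theta_global
    ev <- eval_fn(genes[i, ], th)
    pop$fitness[i] <- ev$fitness
    pop$accuracy[i] <- ev$accuracy
    pop$subset_size[i] <- ev$subset_size
  }
  if (cfg$algorithm == "pso") {
    pop$pbest_genes <- genes
    pop$pbest_theta <- theta
    pop$pbest_fitness <- pop$fitness
    pop$pbest_accuracy <- pop$accuracy
    pop$pbest_size <- pop$subset_size
  }
  pop
}

# ---- built-in generation steps ------------------------------------------
# Contract: step(pop, ctx) -> pop after one full generation (np trial
# evaluations + selection). ctx carries np, n, sa_mode, bounds, theta (the
# frozen global threshold, NA in SA mode), eval_fn, rng and cfg$params.

step_de_family <- function(pop, ctx) {
  np <- ctx$np; n <- ctx$n; p <- ctx$params
  jde <- ctx$algorithm == "jde"
  for (i in seq_len(np)) {
    if (jde) {
      ad <- jde_adapt(pop$F[i], pop$CR[i], p$Fl, p$Fu, p$tau1, p$tau2,
                      u = ctx$rng$runif(4))
      Fi <- ad$F; CRi <- ad$CR
    } else { Fi <- p$F; CRi <- p$CR }
    r <- setdiff(seq_len(np), i)[ctx$rng$sample_int(np - 1L, 3L)]
    d <- n + as.integer(ctx$sa_mode)
    tgt <- c(pop$genes[i, ], if (ctx$sa_mode) pop$theta[i])
    don <- lapply(r, function(j)
      c(pop$genes[j, ], if (ctx$sa_mode) pop$theta[j]))
    j_rand <- ctx$rng$sample_int(d, 1L)
    trial <- de_rand_1_bin(tgt, don[[1]], don[[2]], don[[3]], Fi, CRi,
                           rand_cr = ctx$rng$runif(d), j_rand = j_rand)
    tg <- project_genes(trial[seq_len(n)])
    tt <- if (ctx$sa_mode) project_theta(trial[d], ctx$bounds) else ctx$theta
    ev <- ctx$eval_fn(tg, tt)
    if (de_select(pop$fitness[i], ev$fitness)) {
      pop$genes[i, ] <- tg
      if (ctx$sa_mode) pop$theta[i] <- tt
      if (jde) { pop$F[i] <- Fi; pop$CR[i] <- CRi }
      pop$fitness[i] <- ev$fitness
      pop$accuracy[i] <- ev$accuracy
      pop$subset_size[i] <- ev$subset_size
    }
  }
  pop
}

step_pso <- function(pop, ctx) {
  np <- ctx$np; n <- ctx$n; p <- ctx$params
  d <- n + as.integer(ctx$sa_mode)
  gb <- which.min(pop$pbest_fitness)
  gbest <- c(pop$pbest_genes[gb, ], if (ctx$sa_mode) pop$pbest_theta[gb])
  for (i in seq_len(np)) {
    x <- c(pop$genes[i, ], if (ctx$sa_mode) pop$theta[i])
    pb <- c(pop$pbest_genes[i, ], if (ctx$sa_mode) pop$pbest_theta[i])
    mv <- pso_step(x, pop$vel[i, ], pb, gbest, p$w, p$c1, p$c2,
                   r1 = ctx$rng$runif(d), r2 = ctx$rng$runif(d))
    pop$vel[i, ] <- mv$v
    tg <- project_genes(mv$x[seq_len(n)])
    tt <- if (ctx$sa_mode) project_theta(mv$x[d], ctx$bounds) else ctx$theta
    ev <- ctx$eval_fn(tg, tt)
    pop$genes[i, ] <- tg
    if (ctx$sa_mode) pop$theta[i] <- tt
    pop$fitness[i] <- ev$fitness
    pop$accuracy[i] <- ev$accuracy
    pop$subset_size[i] <- ev$subset_size
    if (ev$fitness < pop$pbest_fitness[i]) {
      pop$pbest_genes[i, ] <- tg
      if (ctx$sa_mode) pop$pbest_theta[i] <- tt
      pop$pbest_fitness[i] <- ev$fitness
      pop$pbest_accuracy[i] <- ev$accuracy
      pop$pbest_size[i] <- ev$subset_size
    }
  }
  pop
}

step_rs <- function(pop, ctx) {
  np <- ctx$np; n <- ctx$n
  for (i in seq_len(np)) {
    tg <- random_search_step(n, ctx$rng)
    tt <- if (ctx$sa_mode)
      ctx$rng$runif(1, ctx$bounds$theta_min, ctx$bounds$theta_max)
    else ctx$theta
    ev <- ctx$eval_fn(tg, tt)
    if (ev$fitness < pop$fitness[i]) {
      pop$genes[i, ] <- tg
      if (ctx$sa_mode) pop$theta[i] <- tt
      pop$fitness[i] <- ev$fitness
      pop$accuracy[i] <- ev$accuracy
      pop$subset_size[i] <- ev$subset_size
    }
  }
  pop
}

optimizer_registry$steps <- list(jde = step_de_family, de = step_de_family,
                                 pso = step_pso, rs = step_rs)

# ---- the generic loop ----------------------------------------------------

#' Run the generic evolutionary feature-selection loop
#'
#' Initializes a population, then repeats modify / evaluate / select until
#' the evaluation budget is exhausted, with the threshold controller
#' advanced once per generation. Records per-generation traces and the
#' global best individual.
#'
#' @param n_features number of problem genes.
#' @param eval_fn function \code{(genotype, theta) -> list(fitness,
#'   accuracy, subset_size)}; typically a closure over
#'   [evaluate_individual] with precomputed folds.
#' @param cfg an [optimizer_config].
#' @param controller an \code{efs_controller} from [make_controller].
#' @return A list of class \code{efs_run}: per-generation vectors
#'   \code{best_fitness}, \code{mean_theta}, \code{rho}, \code{sr},
#'   \code{evals} (cumulative, \code{<= max_evals}); \code{best} (genotype,
#'   theta, fitness, accuracy, subset_size); \code{generations} (count
#'   excluding generation 0) and \code{gtc}.
#' @export
evolve <- function(n_features, eval_fn, cfg, controller) {
  np <- cfg$np
  if (cfg$max_evals < np) stop("budget smaller than one population")
  sa_mode <- controller$kind == "sa"
  bounds <- controller$bounds
  rng <- local_rng(derive_seed(cfg$seed, 7L))
  step_fn <- optimizer_registry$steps[[cfg$algorithm]]

  theta_global <- if (sa_mode) NA_real_ else controller_theta(controller)
  pop <- initialize_population(n_features, cfg, sa_mode, bounds, rng,
                               eval_fn, theta_global)
  evals <- np
  cur_theta <- function() if (sa_mode) pop$theta else controller_theta(controller)

  best_i <- which.min(pop$fitness)
  best <- list(genotype = pop$genes[best_i, ],
               theta = if (sa_mode) pop$theta[best_i] else theta_global,
               fitness = pop$fitness[best_i],
               accuracy = pop$accuracy[best_i],
               subset_size = pop$subset_size[best_i])

  tr_best <- pop$fitness[best_i]
  tr_theta <- mean(cur_theta())
  tr_rho <- compute_selection_rate(pop$genes, cur_theta())
  tr_sr <- NA_real_
  tr_evals <- evals

  gen <- 0L
  while (evals + np <= cfg$max_evals) {
    gen <- gen + 1L
    prev_fitness <- pop$fitness
    ctx <- list(np = np, n = n_features, sa_mode = sa_mode, bounds = bounds,
                theta = if (sa_mode) NA_real_ else controller_theta(controller),
                eval_fn = eval_fn, rng = rng, params = cfg$params,
                algorithm = cfg$algorithm)
    pop <- step_fn(pop, ctx)
    evals <- evals + np

    sr_t <- compute_success_rate(pop$fitness, prev_fitness,
                                 direction = controller$sr_direction)
    rho_t <- compute_selection_rate(pop$genes, cur_theta())
    controller <- controller_update(controller,
                                    list(rho_t = rho_t, sr_t = sr_t))

    bi <- which.min(pop$fitness)
    if (pop$fitness[bi] < best$fitness) {
      best <- list(genotype = pop$genes[bi, ],
                   theta = if (sa_mode) pop$theta[bi] else ctx$theta,
                   fitness = pop$fitness[bi],
                   accuracy = pop$accuracy[bi],
                   subset_size = pop$subset_size[bi])
    }
    tr_best <- c(tr_best, best$fitness)
    tr_theta <- c(tr_theta, mean(cur_theta()))
    tr_rho <- c(tr_rho, rho_t)
    tr_sr <- c(tr_sr, sr_t)
    tr_evals <- c(tr_evals, evals)
  }

  rec <- structure(
    list(best_fitness = tr_best, mean_theta = tr_theta, rho = tr_rho,
         sr = tr_sr, evals = tr_evals, best = best, generations = gen,
         controller_kind = controller$kind, algorithm = cfg$algorithm,
         seed = cfg$seed),
    class = "efs_run")
  rec$gtc <- gtc(rec)
  rec
}

#' @export
print.efs_run <- function(x, ...) {
  cat("EFS run:", x$algorithm, "+", x$controller_kind, "control |",
      x$generations, "generations,", max(x$evals), "evaluations\n")
  cat(sprintf("best fitness %.4f (accuracy %.4f, %d features), GTC %d\n",
              x$best$fitness, x$best$accuracy, x$best$subset_size, x$gtc))
  invisible(x)
}
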