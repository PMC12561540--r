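#' Threshold bounds
#'
#' The feature-inclusion threshold is confined to an interval
#' \code{(theta_min, theta_max)} throughout the search; the replication
#' protocol uses 0.1 and 0.9.
#'
#' @param theta_min,theta_max reals with \code{0 < theta_min < theta_max < 1}.
#' @return A list of class \code{efs_bounds}.
#' @export
threshold_bounds <- function(theta_min = 0.1, theta_max = 0.9) {
  if (!(theta_min > 0 && theta_min < theta_max && theta_max < 1))
    stop("require 0 < theta_min < theta_max < 1")
  structure(list(theta_min = theta_min, theta_max = theta_max),
            class = "efs_bounds")
}

#' Project a threshold into its bounds
#'
#' Clamps theta to \code{[theta_min, theta_max]}; applied after every
#' controller update and after every variation of a self-adaptive threshold
#' gene.
#'
#' @param theta numeric value(s).
#' @param bounds an [threshold_bounds] object.
#' @return The clamped value(s).
#' @export
project_theta <- function(theta, bounds) {
  pmin(pmax(theta, bounds$theta_min), bounds$theta_max)
}

#' Decode a genotype into a feature mask
#'
#' The genotype-phenotype mapping of threshold-based evolutionary feature
#' selection: feature j is selected iff its gene value is at least theta
#' (inclusive).
#'
#' @param genotype numeric vector in \code{[0,1]^n}.
#' @param theta threshold in \code{[0,1]}.
#' @return Logical mask of the same length.
#' @export
decode_subset <- function(genotype, theta) {
  if (any(!is.finite(genotype))) stop("genotype contains non-finite values")
  genotype >= theta
}

#' Linear ramp threshold schedule
#'
#' Deterministic control: the threshold increases linearly from
#' \code{theta_min} at generation 0 to \code{theta_max} at generation T.
#'
#' @param t current generation, \code{0 <= t <= T}.
#' @param T horizon (total generations), \code{>= 1}.
#' @param bounds an [threshold_bounds].
#' @return The threshold at generation t.
#' @export
lr_schedule <- function(t, T, bounds = threshold_bounds()) {
  if (T < 1) stop("schedule horizon T must be >= 1")
  if (t < 0 || t > T) stop("generation t must lie in [0, T]")
  bounds$theta_min + (t / T) * (bounds$theta_max - bounds$theta_min)
}

#' Cosine ramp threshold schedule
#'
#' Deterministic control following a half-cosine: slow increase at the start
#' and end of the run with a faster transition in the middle.
#'
#' @inheritParams lr_schedule
#' @return The threshold at generation t.
#' @export
cr_schedule <- function(t, T, bounds = threshold_bounds()) {
  if (T < 1) stop("schedule horizon T must be >= 1")
  if (t < 0 || t > T) stop("generation t must lie in [0, T]")
  bounds$theta_min +
    (bounds$theta_max - bounds$theta_min) / 2 * (1 - cos(pi * t / T))
}

#' Realized selection rate of a population
#'
#' Mean over individuals of the fraction of features their decoded mask
#' selects; the quantity the proportional controller regulates.
#'
#' @param genotypes numeric matrix, individuals in rows (problem genes only).
#' @param theta the active threshold: a scalar (global control) or a vector
#'   with one threshold per individual (self-adaptive control).
#' @return Selection rate in \code{[0,1]}.
#' @export
compute_selection_rate <- function(genotypes, theta) {
  if (nrow(genotypes) == 0L) stop("empty population")
  if (length(theta) == 1L) {
    frac <- rowMeans(genotypes >= theta)
  } else {
    if (length(theta) != nrow(genotypes))
      stop("theta must be scalar or one per individual")
    frac <- vapply(seq_len(nrow(genotypes)),
                   function(i) mean(genotypes[i, ] >= theta[i]), numeric(1))
  }
  mean(frac)
}

#' Population success rate
#'
#' Fraction of population slots whose fitness improved between consecutive
#' generations. Fitness is minimized, so with the default
#' \code{direction = "improvement"} a slot counts when its fitness strictly
#' decreased; \code{direction = "literal"} counts strict increases instead.
#'
#' @param fitness_now,fitness_prev equal-length numeric vectors of the
#'   population's fitness at generations t and t-1 (same slot order).
#' @param direction \code{"improvement"} (strict decrease counts) or
#'   \code{"literal"} (strict increase counts).
#' @return Success rate in \code{[0,1]}.
#' @export
compute_success_rate <- function(fitness_now, fitness_prev,
                                 direction = c("improvement", "literal")) {
  direction <- match.arg(direction)
  if (length(fitness_now) != length(fitness_prev))
    stop("fitness vectors differ in length")
  if (length(fitness_now) == 0L) stop("empty fitness vectors")
  if (direction == "improvement") mean(fitness_now < fitness_prev)
  else mean(fitness_now > fitness_prev)
}

#' Create a threshold controller
#'
#' One interface over the six control mechanisms: \code{static} (fixed
#' theta), deterministic schedules \code{lr} and \code{cr}, adaptive
#' feedback controllers \code{pc} (proportional control toward a target
#' selection rate) and \code{sra} (success-rate adaptation with
#' multiplicative steps), and \code{sa} (self-adaptive per-individual
#' threshold gene, handled by the optimizer).
#'
#' @param kind one of \code{"static"}, \code{"lr"}, \code{"cr"},
#'   \code{"pc"}, \code{"sra"}, \code{"sa"}.
#' @param bounds an [threshold_bounds].
#' @param T schedule horizon in generations (lr/cr).
#' @param theta0 initial/static threshold; defaults to 0.5, the
#'   conventional static setting.
#' @param eta proportional-control learning rate (default 0.05).
#' @param rho_star target selection rate for pc (default 0.2).
#' @param sr_star target success rate for sra (default 0.15).
#' @param c_down,c_up multiplicative factors for sra (defaults 0.85 / 1.15).
#' @param sr_direction passed to [compute_success_rate].
#' @return A list of class \code{efs_controller} holding the state; update
#'   it with [controller_update] and read the active threshold with
#'   [controller_theta].
#' @export
make_controller <- function(kind = c("static", "lr", "cr", "pc", "sra", "sa"),
                            bounds = threshold_bounds(), T = 100L,
                            theta0 = 0.5, eta = 0.05, rho_star = 0.2,
                            sr_star = 0.15, c_down = 0.85, c_up = 1.15,
                            sr_direction = "improvement") {
  kind <- match.arg(kind)
  if (kind %in% c("lr", "cr") && T < 1) stop("schedules need horizon T >= 1")
  theta_t <- switch(kind,
    static = theta0,
    lr = lr_schedule(0, T, bounds),
    cr = cr_schedule(0, T, bounds),
    pc = theta0,
    sra = theta0,
    sa = NA_real_)
  structure(list(kind = kind, theta_t = theta_t, bounds = bounds, t = 0L,
                 T = as.integer(T), eta = eta, rho_star = rho_star,
                 sr_star = sr_star, c_down = c_down, c_up = c_up,
                 sr_direction = sr_direction),
            class = "efs_controller")
}

#' Active global threshold of a controller
#'
#' @param state an \code{efs_controller}.
#' @return The current global threshold; errors for self-adaptive control,
#'   where each individual carries its own threshold gene.
#' @export
controller_theta <- function(state) {
  if (state$kind == "sa")
    stop("self-adaptive control has no global threshold; read the individual's theta gene")
  state$theta_t
}

#' One proportional-control update
#'
#' Moves the threshold by \code{eta * (rho_t - rho_star)} and projects it
#' into bounds: a selection rate above target raises the threshold (smaller
#' subsets next generation) and vice versa.
#'
#' @param state an \code{efs_controller} of kind \code{pc}.
#' @param rho_t realized selection rate in \code{[0,1]}.
#' @return The updated controller state.
#' @export
pc_update <- function(state, rho_t) {
  stopifnot(state$kind == "pc", rho_t >= 0, rho_t <= 1)
  state$theta_t <- project_theta(
    state$theta_t + state$eta * (rho_t - state$rho_star), state$bounds)
  state$t <- state$t + 1L
  state
}

#' One success-rate-adaptation update
#'
#' Multiplies the threshold by \code{c_down} (0.85) when the success rate
#' exceeds its target and by \code{c_up} (1.15) otherwise (ties take the
#' increase branch), then projects into bounds.
#'
#' @param state an \code{efs_controller} of kind \code{sra}.
#' @param sr_t success rate in \code{[0,1]}.
#' @return The updated controller state.
#' @export
sra_update <- function(state, sr_t) {
  stopifnot(state$kind == "sra", sr_t >= 0, sr_t <= 1)
  fac <- if (sr_t > state$sr_star) state$c_down else state$c_up
  state$theta_t <- project_theta(state$theta_t * fac, state$bounds)
  state$t <- state$t + 1L
  state
}

#' Advance a controller by one generation
#'
#' Global controllers update exactly once per generation, after all trial
#' evaluations, from that generation's population summary; during a
#' generation the threshold is frozen.
#'
#' @param state an \code{efs_controller}.
#' @param summary list with elements \code{rho_t} (selection rate) and
#'   \code{sr_t} (success rate), as produced by the evolutionary loop.
#' @return The updated controller state.
#' @export
controller_update <- function(state, summary) {
  switch(state$kind,
    static = { state$t <- state$t + 1L; state },
    lr = {
      state$t <- min(state$t + 1L, state$T)
      state$theta_t <- lr_schedule(state$t, state$T, state$bounds)
      state
    },
    cr = {
      state$t <- min(state$t + 1L, state$T)
      state$theta_t <- cr_schedule(state$t, state$T, state$bounds)
      state
    },
    pc = pc_update(state, summary$rho_t),
    sra = sra_update(state, summary$sr_t),
    sa = { state$t <- state$t + 1L; state })
}

#' Read an individual's self-adaptive threshold gene
#'
#' @param individual a population individual (see [initialize_population]).
#' @return Its threshold gene.
#' @export
sa_threshold <- function(individual) {
  if (is.null(individual$theta_gene))
    stop("individual carries no threshold gene; self-adaptive mode is off")
  individual$theta_gene
}

#' Draw an initial self-adaptive threshold gene
#'
#' @param bounds an [threshold_bounds].
#' @param rng a stream from \code{local_rng} (internal) or any list with a
#'   \code{runif(n, min, max)} element.
#' @return A uniform draw on \code{[theta_min, theta_max]}.
#' @export
sa_init <- function(bounds, rng) {
  rng$runif(1, bounds$theta_min, bounds$theta_max)
}
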