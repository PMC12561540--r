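#' Generation-to-convergence metric
#'
#' The generation index at which a run's final best fitness value was first
#' attained; generation 0 is the initial population. Captures how quickly
#' the search reaches its eventual optimum.
#'
#' @param record an \code{efs_run} (or any list with a numeric
#'   \code{best_fitness} trace).
#' @return Integer generation index in \code{[0, generations]}.
#' @export
gtc <- function(record) {
  tr <- record$best_fitness
  final <- tr[length(tr)]
  which(tr == final)[1] - 1L
}

#' Experiment configuration
#'
#' Full replication protocol for one (dataset, optimizer, controller, beta)
#' cell: independent runs, each with its own stratified 70/30 split,
#' training-only min-max normalization, fixed cross-validation folds and an
#' evaluation budget.
#'
#' @param dataset an [efs_dataset].
#' @param algorithm optimizer name, see [optimizer_config].
#' @param controller controller kind, see [make_controller].
#' @param beta fitness weighting factor.
#' @param n_runs independent runs (the study uses 30).
#' @param base_seed run r uses seed \code{base_seed + r - 1}.
#' @param np population size.
#' @param max_evals evaluation budget per run.
#' @param train_fraction training share of the stratified split.
#' @param theta_min,theta_max threshold bounds.
#' @param controller_params extra arguments for [make_controller]
#'   (\code{theta0}, \code{eta}, \code{rho_star}, \code{sr_star},
#'   \code{c_down}, \code{c_up}, \code{sr_direction}).
#' @param optimizer_params extra constants for [optimizer_config].
#' @param k_neighbors,cv_folds,empty_subset_policy see [fitness_spec].
#' @return A list of class \code{efs_experiment_config}.
#' @export
experiment_config <- function(dataset, algorithm = "jde",
                              controller = "static", beta = 0.9,
                              n_runs = 30L, base_seed = 1L, np = 30L,
                              max_evals = 3000L, train_fraction = 0.7,
                              theta_min = 0.1, theta_max = 0.9,
                              controller_params = list(),
                              optimizer_params = list(),
                              k_neighbors = 5L, cv_folds = 5L,
                              empty_subset_policy = "worst_fitness") {
  stopifnot(inherits(dataset, "efs_dataset"), n_runs >= 1L)
  structure(list(dataset = dataset, algorithm = algorithm,
                 controller = controller, beta = beta,
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed), np = as.integer(np),
                 max_evals = as.integer(max_evals),
                 train_fraction = train_fraction,
                 theta_min = theta_min, theta_max = theta_max,
                 controller_params = controller_params,
                 optimizer_params = optimizer_params,
                 k_neighbors = as.integer(k_neighbors),
                 cv_folds = as.integer(cv_folds),
                 empty_subset_policy = empty_subset_policy),
            class = "efs_experiment_config")
}

# One full run: split -> normalize -> folds -> evolve -> test validation.
run_single <- function(cfg, run_seed) {
  ds <- cfg$dataset
  bounds <- threshold_bounds(cfg$theta_min, cfg$theta_max)
  fspec <- fitness_spec(beta = cfg$beta, k_neighbors = cfg$k_neighbors,
                        cv_folds = cfg$cv_folds,
                        empty_subset_policy = cfg$empty_subset_policy)
  split <- stratified_split(ds, cfg$train_fraction,
                            seed = derive_seed(run_seed, 1L))
  norm <- fit_minmax(ds, split$train_indices)
  dsn <- apply_minmax(norm, ds)
  folds <- stratified_kfold(dsn, split$train_indices, k = fspec$cv_folds,
                            seed = derive_seed(run_seed, 2L))
  horizon <- cfg$max_evals %/% cfg$np
  ctrl <- do.call(make_controller,
                  c(list(kind = cfg$controller, bounds = bounds,
                         T = horizon), cfg$controller_params))
  ocfg <- optimizer_config(cfg$algorithm, np = cfg$np,
                           max_evals = cfg$max_evals, seed = run_seed,
                           params = cfg$optimizer_params)
  eval_fn <- function(genotype, theta)
    evaluate_individual(genotype, theta, dsn, split$train_indices, fspec,
                        folds = folds)
  rec <- evolve(ds$n_features, eval_fn, ocfg, ctrl)
  val <- validate_on_test(rec$best$genotype, rec$best$theta, dsn, split,
                          fspec)
  rec$test_accuracy <- val$test_accuracy
  rec$test_subset_size <- val$subset_size
  rec$run_seed <- run_seed
  rec$split <- split
  rec$norm <- norm
  rec$beta <- cfg$beta
  rec
}

#' Run a multi-run experiment
#'
#' Executes \code{n_runs} independent runs of the protocol; run r uses
#' seed \code{base_seed + r - 1} for its split, folds and optimizer, so
#' the whole experiment replays exactly. A failing run is recorded with
#' its error and the remaining runs continue.
#'
#' @param cfg an [experiment_config].
#' @return List of \code{efs_run} records (failed runs carry class
#'   \code{efs_run_error}).
#' @export
run_experiment <- function(cfg) {
  lapply(seq_len(cfg$n_runs) - 1L, function(r) {
    tryCatch(run_single(cfg, cfg$base_seed + r),
             error = function(e) structure(
               list(run = r, message = conditionMessage(e)),
               class = "efs_run_error"))
  })
}

#' Summarise run records
#'
#' Mean, sample (n-1) standard deviation and median of selected per-run
#' fields, matching the summary statistics the replication protocol
#' reports per table cell.
#'
#' @param records list of \code{efs_run} records from [run_experiment].
#' @param fields character vector among \code{"test_accuracy"},
#'   \code{"cv_accuracy"}, \code{"fitness"}, \code{"subset_size"},
#'   \code{"gtc"}.
#' @return A data.frame with one row per field: mean, sd, median, n.
#' @export
aggregate_runs <- function(records,
                           fields = c("test_accuracy", "subset_size",
                                      "fitness", "gtc")) {
  records <- Filter(function(r) inherits(r, "efs_run"), records)
  if (!length(records)) stop("no successful runs to aggregate")
  pull <- function(rec, f) switch(f,
    test_accuracy = rec$test_accuracy,
    cv_accuracy = rec$best$accuracy,
    fitness = rec$best$fitness,
    subset_size = rec$best$subset_size,
    gtc = rec$gtc,
    stop("unknown field '", f, "'"))
  rows <- lapply(fields, function(f) {
    v <- vapply(records, pull, numeric(1), f = f)
    data.frame(field = f, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               median = stats::median(v), n = length(v))
  })
  do.call(rbind, rows)
}

#' Write run records as JSON lines
#'
#' One JSON object per run with the scalar summaries and the
#' per-generation traces.
#'
#' @param records list of \code{efs_run} records.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_run_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    if (!inherits(rec, "efs_run")) {
      writeLines(jsonlite::toJSON(list(error = rec$message), auto_unbox = TRUE),
                 con)
      next
    }
    obj <- list(algorithm = rec$algorithm, controller = rec$controller_kind,
                seed = rec$run_seed, beta = rec$beta,
                best_fitness = rec$best$fitness,
                cv_accuracy = rec$best$accuracy,
                subset_size = rec$best$subset_size,
                test_accuracy = rec$test_accuracy, gtc = rec$gtc,
                generations = rec$generations,
                evaluations = max(rec$evals),
                trace = list(best_fitness = rec$best_fitness,
                             mean_theta = rec$mean_theta,
                             rho = rec$rho, sr = rec$sr))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}
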