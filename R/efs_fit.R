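#' Evolutionary feature selection with threshold control
#'
#' Fits a wrapper-based evolutionary feature selector: a real-coded
#' population is evolved by a bio-inspired optimizer, each genotype is
#' decoded to a feature subset by thresholding, and subsets are scored by
#' cross-validated K-nearest-neighbour accuracy combined with a
#' subset-size penalty, \code{f(S) = beta (1 - Acc) + (1 - beta) |S|/n}.
#' The feature-inclusion threshold is governed by one of six control
#' mechanisms (static, linear or cosine schedule, proportional control,
#' success-rate adaptation, or a self-adaptive per-individual gene). The
#' selected subset is finally validated on a held-out stratified test
#' split.
#'
#' @param x numeric feature matrix (or, for the formula method, a formula
#'   such as \code{class ~ .}).
#' @param y class labels, one per row of \code{x}.
#' @param algorithm optimizer backend: \code{"jde"}, \code{"de"},
#'   \code{"pso"} or \code{"rs"}.
#' @param controller threshold control mechanism: \code{"static"},
#'   \code{"lr"}, \code{"cr"}, \code{"pc"}, \code{"sra"} or \code{"sa"}.
#' @param beta accuracy/subset-size weighting in (0,1).
#' @param np population size.
#' @param max_evals evaluation budget (including the initial population).
#' @param train_fraction share of instances in the training split.
#' @param theta_min,theta_max threshold bounds.
#' @param controller_params named list of controller constants
#'   (\code{theta0}, \code{eta}, \code{rho_star}, \code{sr_star},
#'   \code{c_down}, \code{c_up}, \code{sr_direction}).
#' @param optimizer_params named list of optimizer constants (see
#'   [optimizer_config]).
#' @param k_neighbors,cv_folds,empty_subset_policy see [fitness_spec].
#' @param seed integer seed; the whole fit replays exactly from it.
#' @param ... passed between methods.
#' @return An object of class \code{"efs"} with the selected feature mask,
#'   the held-out test accuracy, per-generation traces, and everything
#'   needed by \code{predict}. See [predict.efs], [summary.efs],
#'   [plot.efs], [coef.efs].
#' @examples
#' gen <- synth_generate(synth_spec(n_samples = 80, n_classes = 2,
#'                                  n_informative = 4, n_noise = 16,
#'                                  class_separation = 3, seed = 7))
#' fit <- efs(gen$dataset$X, gen$dataset$y, algorithm = "jde",
#'            controller = "sa", beta = 0.9, max_evals = 300, seed = 1)
#' summary(fit)
#' @export
efs <- function(x, ...) UseMethod("efs")

#' @rdname efs
#' @param formula a model formula whose left side is the class label.
#' @param data a data.frame holding the variables of \code{formula}.
#' @export
efs.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- mf[-1L]
  bad <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  out <- efs.default(as.matrix(X), y, ...)
  out$call <- match.call()
  out
}

#' @rdname efs
#' @export
efs.default <- function(x, y, algorithm = "jde", controller = "sa",
                        beta = 0.9, np = 30L, max_evals = 3000L,
                        train_fraction = 0.7, theta_min = 0.1,
                        theta_max = 0.9, controller_params = list(),
                        optimizer_params = list(), k_neighbors = 5L,
                        cv_folds = 5L,
                        empty_subset_policy = "worst_fitness",
                        seed = 1L, ...) {
  ds <- efs_dataset(x, y)
  cfg <- experiment_config(ds, algorithm = algorithm,
                           controller = controller, beta = beta,
                           n_runs = 1L, base_seed = seed, np = np,
                           max_evals = max_evals,
                           train_fraction = train_fraction,
                           theta_min = theta_min, theta_max = theta_max,
                           controller_params = controller_params,
                           optimizer_params = optimizer_params,
                           k_neighbors = k_neighbors, cv_folds = cv_folds,
                           empty_subset_policy = empty_subset_policy)
  rec <- run_single(cfg, as.integer(seed))
  dsn <- apply_minmax(rec$norm, ds)
  mask <- decode_subset(rec$best$genotype, rec$best$theta)
  if (!any(mask) && empty_subset_policy == "repair")
    mask[which.max(rec$best$genotype)] <- TRUE
  structure(
    list(call = match.call(), dataset = ds, record = rec,
         selected = mask, feature_names = ds$feature_names,
         theta = rec$best$theta, controller = controller,
         algorithm = algorithm, beta = beta,
         cv_accuracy = rec$best$accuracy, fitness = rec$best$fitness,
         test_accuracy = rec$test_accuracy,
         subset_size = sum(mask), gtc = rec$gtc,
         norm = rec$norm, split = rec$split,
         train_X = dsn$X[rec$split$train_indices, , drop = FALSE],
         train_y = ds$y[rec$split$train_indices],
         class_levels = ds$class_levels, k_neighbors = k_neighbors,
         seed = as.integer(seed)),
    class = "efs")
}

#' @export
print.efs <- function(x, ...) {
  cat("Evolutionary feature selection (", x$algorithm, " + ",
      x$controller, " threshold control)\n", sep = "")
  cat(sprintf("  %d of %d features selected | CV accuracy %.4f | test accuracy %.4f\n",
              x$subset_size, x$dataset$n_features, x$cv_accuracy,
              x$test_accuracy))
  cat(sprintf("  fitness %.4f (beta = %.2f) | GTC %d\n",
              x$fitness, x$beta, x$gtc))
  invisible(x)
}

#' Summarise a fitted evolutionary feature selector
#'
#' @param object an \code{efs} fit.
#' @param ... unused.
#' @return An object of class \code{summary.efs}.
#' @export
summary.efs <- function(object, ...) {
  structure(list(fit = object,
                 selected_names = object$feature_names[object$selected]),
            class = "summary.efs")
}

#' @export
print.summary.efs <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  final threshold %.4f | %d generations | %d evaluations\n",
              f$theta, f$record$generations, max(f$record$evals)))
  cat("  selected features:",
      paste(utils::head(x$selected_names, 12), collapse = ", "),
      if (length(x$selected_names) > 12)
        sprintf("... (%d total)", length(x$selected_names)) else "", "\n")
  invisible(x)
}

#' Best genotype of a fitted selector
#'
#' The real-coded gene values of the best individual; gene j selects
#' feature j iff its value is at least the fit's threshold (attribute
#' \code{"theta"}).
#'
#' @param object an \code{efs} fit.
#' @param ... unused.
#' @return Named numeric vector with attribute \code{theta}.
#' @export
coef.efs <- function(object, ...) {
  out <- object$record$best$genotype
  names(out) <- object$feature_names
  attr(out, "theta") <- object$theta
  out
}

#' Names of the selected features
#'
#' @param object an \code{efs} fit.
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(object) {
  stopifnot(inherits(object, "efs"))
  object$feature_names[object$selected]
}

#' Predict class labels with the selected subset
#'
#' Applies the fit's training-data min-max normalization to new instances
#' and classifies them by KNN on the selected features, using the full
#' training split as reference set.
#'
#' @param object an \code{efs} fit.
#' @param newdata numeric matrix or data.frame with the training feature
#'   columns.
#' @param ... unused.
#' @return Vector of predicted labels on the original label scale.
#' @export
predict.efs <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    keep <- intersect(object$feature_names, names(newdata))
    if (length(keep) != length(object$feature_names))
      stop("newdata is missing feature column(s): ",
           paste(setdiff(object$feature_names, names(newdata)), collapse = ", "))
    newdata <- as.matrix(newdata[object$feature_names])
  }
  Xn <- minmax_transform(object$norm, as.matrix(newdata))
  if (!any(object$selected)) stop("fit selected no features")
  pr <- knn_predict(object$train_X[, object$selected, drop = FALSE],
                    object$train_y, Xn[, object$selected, drop = FALSE],
                    k = object$k_neighbors)
  object$class_levels[pr + 1L]
}

#' Plot convergence and threshold traces
#'
#' Two stacked panels: the best-so-far fitness per generation and the mean
#' active threshold per generation.
#'
#' @param x an \code{efs} fit.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.efs <- function(x, ...) {
  rec <- x$record
  gens <- seq_along(rec$best_fitness) - 1L
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(gens, rec$best_fitness, type = "s", xlab = "generation",
       ylab = "best fitness", main = paste(x$algorithm, "+", x$controller), ...)
  graphics::abline(v = x$gtc, lty = 3)
  plot(gens, rec$mean_theta, type = "l", xlab = "generation",
       ylab = "mean threshold", ylim = c(0, 1), ...)
  invisible(x)
}
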