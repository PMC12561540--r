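#' Wrapper fitness specification
#'
#' Parameters of the wrapper evaluation: the accuracy/subset-size weighting
#' beta, the number of neighbours of the KNN classifier, the number of
#' cross-validation folds, and the policy applied when a genotype decodes
#' to an empty subset (a reachable state at high thresholds).
#'
#' @param beta weighting factor in (0,1); the study grid is 0.9, 0.7, 0.5.
#' @param k_neighbors KNN neighbourhood size (default 5).
#' @param cv_folds cross-validation folds on the training split (default 5).
#' @param empty_subset_policy \code{"worst_fitness"} assigns the worst
#'   possible fitness 1 (accuracy recorded as 0); \code{"repair"} selects
#'   the single feature with the largest gene value instead.
#' @return A list of class \code{fitness_spec}.
#' @export
fitness_spec <- function(beta = 0.9, k_neighbors = 5L, cv_folds = 5L,
                         empty_subset_policy = c("worst_fitness", "repair")) {
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly in (0,1)")
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(list(beta = beta, k_neighbors = as.integer(k_neighbors),
                 cv_folds = as.integer(cv_folds),
                 empty_subset_policy = match.arg(empty_subset_policy)),
            class = "fitness_spec")
}

#' K-nearest-neighbour prediction
#'
#' Euclidean KNN with fully deterministic tie handling: distance ties are
#' broken by training-row index; vote ties are broken in favour of the tied
#' class whose nearest member is closest, with any residual tie going to
#' the smallest encoded label.
#'
#' @param train_X numeric matrix of training instances.
#' @param train_y integer class codes for the training rows.
#' @param query_X numeric matrix of query instances (same columns).
#' @param k number of neighbours, \code{1 <= k <= nrow(train_X)}.
#' @return Integer vector of predicted class codes, one per query row.
#' @export
knn_predict <- function(train_X, train_y, query_X, k = 5L) {
  if (!is.matrix(train_X)) train_X <- as.matrix(train_X)
  if (!is.matrix(query_X)) query_X <- as.matrix(query_X)
  n <- nrow(train_X)
  if (k > n) stop("k = ", k, " exceeds the ", n, " training instances")
  if (ncol(train_X) != ncol(query_X)) stop("feature dimensions differ")
  m <- nrow(query_X)
  # squared Euclidean distances, queries in rows
  D <- matrix(rowSums(train_X^2), m, n, byrow = TRUE) +
    rowSums(query_X^2) - 2 * tcrossprod(query_X, train_X)
  # k nearest per query by repeated argmin; max.col(ties = "first") breaks
  # distance ties by training-row index
  NB <- matrix(0L, m, k)
  negD <- -D
  for (j in seq_len(k)) {
    idx <- max.col(negD, ties.method = "first")
    NB[, j] <- idx
    negD[cbind(seq_len(m), idx)] <- -Inf
  }
  pred <- integer(m)
  for (i in seq_len(m)) {
    lab <- train_y[NB[i, ]]
    cnt <- tabulate(lab + 1L)
    top <- which(cnt == max(cnt)) - 1L
    if (length(top) == 1L) {
      pred[i] <- top
    } else {
      # nearest member of each tied class; ord is sorted by distance
      nearest <- vapply(top, function(cl) which(lab == cl)[1], integer(1))
      pred[i] <- top[order(nearest, top)][1]
    }
  }
  pred
}

#' Cross-validated KNN accuracy of a feature subset
#'
#' Mean holdout accuracy over stratified folds of the training split, using
#' only the masked feature columns. Fold assignment is a function of the
#' seed alone, so every candidate subset within one run is scored on
#' identical folds.
#'
#' @param ds a normalized [efs_dataset].
#' @param train_indices rows forming the training split.
#' @param mask logical feature mask selecting at least one feature.
#' @param spec a [fitness_spec].
#' @param seed integer seed fixing the fold assignment.
#' @param folds optional precomputed folds from [stratified_kfold] (same
#'   contract); supplied by the evolutionary loop to avoid recomputation.
#' @return Mean fold accuracy in \code{[0,1]}.
#' @export
cv_accuracy <- function(ds, train_indices, mask, spec = fitness_spec(),
                        seed = 1L, folds = NULL) {
  if (!any(mask)) stop("empty feature mask; apply the empty-subset policy")
  if (is.null(folds))
    folds <- stratified_kfold(ds, train_indices, k = spec$cv_folds,
                              seed = seed)
  Xm <- ds$X[, mask, drop = FALSE]
  accs <- vapply(folds, function(fd) {
    pr <- knn_predict(Xm[fd$fit, , drop = FALSE], ds$y[fd$fit],
                      Xm[fd$hold, , drop = FALSE], k = spec$k_neighbors)
    mean(pr == ds$y[fd$hold])
  }, numeric(1))
  mean(accs)
}

#' Wrapper fitness of a subset
#'
#' Combines classification error and relative subset size:
#' \code{f = beta * (1 - Acc) + (1 - beta) * |S| / n}. Lower is better;
#' the value always lies in \code{[0,1]}.
#'
#' @param acc classification accuracy in \code{[0,1]}.
#' @param subset_size number of selected features.
#' @param n_features total number of features.
#' @param beta weighting factor in (0,1).
#' @return The fitness value.
#' @export
fitness_value <- function(acc, subset_size, n_features, beta) {
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly in (0,1)")
  stopifnot(acc >= 0, acc <= 1, subset_size >= 0, subset_size <= n_features)
  beta * (1 - acc) + (1 - beta) * subset_size / n_features
}

#' Evaluate one genotype under the active threshold
#'
#' Decodes the genotype, applies the empty-subset policy if needed, scores
#' the subset by cross-validated KNN accuracy and returns the combined
#' fitness.
#'
#' @param genotype real vector in \code{[0,1]^n} (problem genes only).
#' @param theta the active threshold (global or the individual's own).
#' @param ds a normalized [efs_dataset].
#' @param train_indices rows forming the training split.
#' @param spec a [fitness_spec].
#' @param seed seed fixing the cross-validation folds.
#' @param folds optional precomputed folds (see [cv_accuracy]).
#' @return List with \code{fitness}, \code{accuracy}, \code{subset_size}
#'   and the decoded (possibly repaired) \code{mask}.
#' @export
evaluate_individual <- function(genotype, theta, ds, train_indices,
                                spec = fitness_spec(), seed = 1L,
                                folds = NULL) {
  mask <- decode_subset(genotype, theta)
  if (!any(mask)) {
    if (spec$empty_subset_policy == "worst_fitness")
      return(list(fitness = 1, accuracy = 0, subset_size = 0L, mask = mask))
    mask[which.max(genotype)] <- TRUE   # repair: keep the strongest gene
  }
  acc <- cv_accuracy(ds, train_indices, mask, spec, seed, folds)
  list(fitness = fitness_value(acc, sum(mask), ds$n_features, spec$beta),
       accuracy = acc, subset_size = sum(mask), mask = mask)
}

#' Validate a selected subset on the held-out test split
#'
#' Fits KNN on the full training split restricted to the selected features
#' and reports accuracy on the test split, which stays unseen throughout
#' the search.
#'
#' @param genotype real vector of the best individual's problem genes.
#' @param theta the threshold under which it was selected.
#' @param ds a normalized [efs_dataset].
#' @param split an \code{efs_split} from [stratified_split].
#' @param spec a [fitness_spec].
#' @return List with \code{test_accuracy}, \code{subset_size} and the
#'   \code{mask}.
#' @export
validate_on_test <- function(genotype, theta, ds, split,
                             spec = fitness_spec()) {
  mask <- decode_subset(genotype, theta)
  if (!any(mask)) {
    if (spec$empty_subset_policy == "worst_fitness")
      return(list(test_accuracy = 0, subset_size = 0L, mask = mask))
    mask[which.max(genotype)] <- TRUE
  }
  tr <- split$train_indices; te <- split$test_indices
  pr <- knn_predict(ds$X[tr, mask, drop = FALSE], ds$y[tr],
                    ds$X[te, mask, drop = FALSE], k = spec$k_neighbors)
  list(test_accuracy = mean(pr == ds$y[te]), subset_size = sum(mask),
       mask = mask)
}
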