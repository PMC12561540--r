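#' Specification for a synthetic classification dataset
#'
#' Describes a dataset with three planted feature blocks: informative
#' columns drawn from class-conditional Gaussians whose means are separated
#' in the informative subspace, redundant columns that are noisy linear
#' mixtures of the informative block, and pure-noise columns independent of
#' the class. Emulates the structure of high-dimensional classification
#' benchmarks (tumour transcriptomics and UCI-style data) at test scale.
#'
#' @param n_samples total instances (>= 2 per class).
#' @param n_classes number of classes (>= 2).
#' @param n_informative informative features (>= 1).
#' @param n_redundant redundant (mixture) features.
#' @param n_noise pure-noise features.
#' @param class_separation distance between class mean vectors in the
#'   informative subspace, in units of the within-class standard deviation
#'   (which is 1).
#' @param redundancy_noise_sd sd of the Gaussian noise added to each
#'   redundant mixture.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A list of class \code{synth_spec}.
#' @export
synth_spec <- function(n_samples, n_classes = 2L, n_informative = 5L,
                       n_redundant = 0L, n_noise = 0L,
                       class_separation = 2, redundancy_noise_sd = 0.1,
                       seed = 1L) {
  if (n_informative < 1L) stop("need at least one informative feature")
  if (n_classes < 2L) stop("need at least two classes")
  if (n_samples < 2L * n_classes)
    stop("need at least 2 samples per class (", 2L * n_classes, " total)")
  if (n_redundant < 0L || n_noise < 0L) stop("feature counts must be >= 0")
  if (class_separation < 0) stop("class_separation must be >= 0")
  if (redundancy_noise_sd < 0) stop("redundancy_noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 class_separation = class_separation,
                 redundancy_noise_sd = redundancy_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Class mean vectors with pairwise distance `sep` in a d-dimensional
# informative subspace. For d >= K the means sit on scaled coordinate axes
# (a regular simplex up to translation); for d < K (degenerate request)
# random unit directions are scaled so the *average* pairwise distance is
# sep.
class_means <- function(K, d, sep, rng) {
  if (d >= K) {
    M <- matrix(0, K, d)
    M[cbind(seq_len(K), seq_len(K))] <- sep / sqrt(2)
    M
  } else {
    M <- matrix(rng$rnorm(K * d), K, d)
    D <- as.matrix(stats::dist(M))
    avg <- mean(D[upper.tri(D)])
    if (avg > 0) M * (sep / avg) else M
  }
}

#' Generate a synthetic classification dataset
#'
#' Draws a dataset according to a [synth_spec] together with the
#' ground-truth mask of class-associated features (informative and
#' redundant columns).
#'
#' @param spec a [synth_spec].
#' @return A list with elements \code{dataset} (an [efs_dataset]) and
#'   \code{truth_mask} (logical, TRUE for informative and redundant
#'   columns).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  rng <- local_rng(spec$seed)
  K <- spec$n_classes
  n <- spec$n_samples
  # balanced class sizes, remainder spread over the first classes
  base <- n %/% K
  sizes <- rep(base, K) + as.integer(seq_len(K) <= n %% K)
  y <- rep(seq_len(K) - 1L, times = sizes)

  M <- class_means(K, spec$n_informative, spec$class_separation, rng)
  Xi <- matrix(rng$rnorm(n * spec$n_informative), n, spec$n_informative)
  Xi <- Xi + M[y + 1L, , drop = FALSE]

  Xr <- NULL
  if (spec$n_redundant > 0L) {
    W <- matrix(rng$runif(spec$n_informative * spec$n_redundant, -1, 1),
                spec$n_informative, spec$n_redundant)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    Xr <- Xi %*% W +
      matrix(rng$rnorm(n * spec$n_redundant, sd = spec$redundancy_noise_sd),
             n, spec$n_redundant)
  }

  Xn <- NULL
  if (spec$n_noise > 0L)
    Xn <- matrix(rng$rnorm(n * spec$n_noise), n, spec$n_noise)

  X <- cbind(Xi, Xr, Xn)
  nm <- c(sprintf("inf%02d", seq_len(spec$n_informative)),
          if (spec$n_redundant) sprintf("red%02d", seq_len(spec$n_redundant)),
          if (spec$n_noise) sprintf("noi%03d", seq_len(spec$n_noise)))
  truth <- c(rep(TRUE, spec$n_informative + spec$n_redundant),
             rep(FALSE, spec$n_noise))
  list(dataset = efs_dataset(X, y, feature_names = nm), truth_mask = truth)
}

#' Precision and recall of a selected feature set
#'
#' Scores a selected feature mask against the generator's ground truth.
#'
#' @param selected_mask logical mask of selected features (non-empty).
#' @param truth_mask logical ground-truth mask of the same length.
#' @return Named numeric vector with \code{precision} and \code{recall}.
#' @export
recovery_scores <- function(selected_mask, truth_mask) {
  if (length(selected_mask) != length(truth_mask))
    stop("masks differ in length")
  if (!any(selected_mask))
    stop("empty selection; apply the empty-subset policy before scoring")
  hit <- sum(selected_mask & truth_mask)
  c(precision = hit / sum(selected_mask), recall = hit / sum(truth_mask))
}
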