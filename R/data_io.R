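#' Construct a classification dataset container
#'
#' Bundles a numeric feature matrix with integer class labels. Labels are
#' re-encoded to dense integer codes \code{0..n_classes-1} following the
#' sorted order of the original labels, which gives k-nearest-neighbour
#' voting a stable, reproducible tie-break.
#'
#' @param X numeric matrix, instances in rows, features in columns.
#' @param y class labels, one per row of \code{X}; any atomic type.
#' @param feature_names optional character vector of feature names; defaults
#'   to the column names of \code{X} or \code{f1..fn}.
#' @return An object of class \code{efs_dataset} with elements \code{X}
#'   (numeric matrix), \code{y} (integer codes \code{0..n_classes-1}),
#'   \code{feature_names}, \code{class_levels} (original labels in sorted
#'   order), \code{n_features} and \code{n_classes}.
#' @export
efs_dataset <- function(X, y, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y))
    stop("X has ", nrow(X), " rows but y has ", length(y), " labels")
  if (anyNA(X)) stop("X contains missing values")
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("dataset must contain at least two classes")
  y_code <- match(y, lev) - 1L
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  }
  colnames(X) <- feature_names
  structure(
    list(X = X, y = as.integer(y_code), feature_names = feature_names,
         class_levels = lev, n_features = ncol(X), n_classes = length(lev)),
    class = "efs_dataset")
}

#' @export
print.efs_dataset <- function(x, ...) {
  cat("Classification dataset:", nrow(x$X), "instances x", x$n_features,
      "features,", x$n_classes, "classes\n")
  cat("Class counts:", paste(table(x$y), collapse = "/"), "\n")
  invisible(x)
}

#' Read a tabular classification dataset from CSV
#'
#' Expects a comma-separated file with a header row, '.' decimal marks and
#' one label column; all other columns must be numeric features.
#'
#' @param path path to the CSV file.
#' @param label_column name or 1-based index of the class-label column.
#' @return An [efs_dataset] object.
#' @export
load_dataset_csv <- function(path, label_column = "class") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (is.numeric(label_column)) {
    if (label_column < 1 || label_column > ncol(df))
      stop("label column index out of range: ", label_column)
    lab_idx <- as.integer(label_column)
  } else {
    lab_idx <- match(label_column, names(df))
    if (is.na(lab_idx)) stop("label column not found: '", label_column, "'")
  }
  y <- df[[lab_idx]]
  feat <- df[-lab_idx]
  if (ncol(feat) == 0L) stop("no feature columns in ", path)
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  efs_dataset(as.matrix(feat), y, feature_names = names(feat))
}

#' Write a dataset to CSV
#'
#' Inverse of [load_dataset_csv]: features first, label column last. Labels
#' are written as the original class levels.
#'
#' @param ds an [efs_dataset].
#' @param path output file path.
#' @param label_column name for the label column.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(ds, path, label_column = "class") {
  df <- as.data.frame(ds$X)
  names(df) <- ds$feature_names
  df[[label_column]] <- ds$class_levels[ds$y + 1L]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Largest-remainder apportionment of `total` across classes with counts `n_c`
# and target fraction `frac`; ties in remainders broken by class order.
# Each class is guaranteed at least 1 drawn and 1 left behind.
apportion_train <- function(n_c, frac) {
  total <- floor(sum(n_c) * frac + 0.5)
  quota <- n_c * frac
  take <- floor(quota)
  rem <- quota - take
  short <- total - sum(take)
  if (short > 0) {
    ord <- order(-rem, seq_along(n_c))
    take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1L
  } else if (short < 0) {
    ord <- order(rem, seq_along(n_c))
    take[ord[seq_len(-short)]] <- take[ord[seq_len(-short)]] - 1L
  }
  # keep at least one instance on each side of the split per class
  take <- pmin(pmax(take, 1L), n_c - 1L)
  as.integer(take)
}

#' Stratified train/test split
#'
#' Splits instances into disjoint train and test index sets so that each
#' class's train fraction deviates from \code{train_fraction} by at most one
#' instance (largest-remainder apportionment of the train quota).
#'
#' @param ds an [efs_dataset].
#' @param train_fraction fraction of instances assigned to training,
#'   strictly between 0 and 1 (the replication protocol uses 0.7).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return A list of class \code{efs_split} with integer vectors
#'   \code{train_indices}, \code{test_indices} and the \code{seed}.
#' @export
stratified_split <- function(ds, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  cnt <- tabulate(ds$y + 1L, nbins = ds$n_classes)
  if (any(cnt < 2L))
    stop("class '", ds$class_levels[which(cnt < 2L)[1]],
         "' has fewer than 2 instances; stratified splitting impossible")
  take <- apportion_train(cnt, train_fraction)
  rng <- local_rng(seed)
  train <- integer(0)
  for (k in seq_len(ds$n_classes)) {
    idx <- which(ds$y == k - 1L)
    idx <- idx[rng$sample_perm(length(idx))]
    train <- c(train, idx[seq_len(take[k])])
  }
  train <- sort(train)
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_len(nrow(ds$X)), train),
                 seed = as.integer(seed)),
            class = "efs_split")
}

#' Fit min-max normalization parameters
#'
#' Computes per-feature minima and maxima on the given (training) indices
#' only, so that no information from held-out data leaks into scaling.
#'
#' @param ds an [efs_dataset].
#' @param indices row indices on which to compute the ranges.
#' @return A list of class \code{efs_minmax} with vectors \code{min} and
#'   \code{max}.
#' @export
fit_minmax <- function(ds, indices) {
  Xs <- ds$X[indices, , drop = FALSE]
  structure(list(min = apply(Xs, 2, min), max = apply(Xs, 2, max)),
            class = "efs_minmax")
}

#' Apply min-max normalization
#'
#' Maps each feature affinely so training values span [0, 1]; values outside
#' the training range (held-out data) are clipped to [0, 1], and
#' zero-variance features map to 0. Keeps k-nearest-neighbour distances
#' bounded and comparable across features.
#'
#' @param params an \code{efs_minmax} from [fit_minmax].
#' @param ds an [efs_dataset].
#' @return A new [efs_dataset] with normalized \code{X}.
#' @export
apply_minmax <- function(params, ds) {
  out <- ds
  out$X <- minmax_transform(params, ds$X)
  out
}

# transform a raw matrix with fitted min-max params (clipped to [0,1])
minmax_transform <- function(params, X) {
  rng <- params$max - params$min
  scale <- ifelse(rng > 0, 1 / rng, 0)
  Xn <- sweep(X, 2, params$min, "-")
  Xn <- sweep(Xn, 2, scale, "*")
  Xn[Xn < 0] <- 0
  Xn[Xn > 1] <- 1
  Xn
}

#' Stratified k-fold partition
#'
#' Partitions the given indices into k folds with per-class counts differing
#' by at most one across folds. Returns fit/hold pairs for cross-validation.
#'
#' @param ds an [efs_dataset].
#' @param indices row indices to partition (typically the training split).
#' @param k number of folds (>= 2); every class must have at least k
#'   instances among \code{indices}.
#' @param seed integer seed; folds are deterministic given the seed.
#' @return A list of k lists, each with integer vectors \code{fit} and
#'   \code{hold}; the holds are disjoint and cover \code{indices}.
#' @export
stratified_kfold <- function(ds, indices, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  y_sub <- ds$y[indices]
  cnt <- tabulate(y_sub + 1L, nbins = ds$n_classes)
  if (any(cnt < k))
    stop("class '", ds$class_levels[which(cnt < k)[1]], "' has ",
         min(cnt[cnt < k]), " instances among the given indices; need >= ", k)
  rng <- local_rng(seed)
  fold_of <- integer(length(indices))
  for (cl in seq_len(ds$n_classes)) {
    pos <- which(y_sub == cl - 1L)
    pos <- pos[rng$sample_perm(length(pos))]
    fold_of[pos] <- rep_len(seq_len(k), length(pos))
  }
  lapply(seq_len(k), function(f) {
    list(fit = indices[fold_of != f], hold = indices[fold_of == f])
  })
}
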