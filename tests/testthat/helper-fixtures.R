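# Fixtures and independent oracles shared across the suite.

# tiny two-class dataset with one perfectly separating feature
make_separable_dataset <- function(n_per_class = 20, n_noise = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(0:1, each = n_per_class)
  X <- cbind(sep = y * 10 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * n_noise), n, n_noise))
  colnames(X) <- c("sep", paste0("noise", seq_len(n_noise)))
  efs_dataset(X, y)
}

# brute-force KNN oracle: plain double loop, squared Euclidean distances,
# ties by index, majority vote with nearest-member then smallest-label
# tie-breaks -- independent of the package's vectorized path
knn_oracle <- function(train_X, train_y, query_X, k) {
  pred <- integer(nrow(query_X))
  for (i in seq_len(nrow(query_X))) {
    d <- numeric(nrow(train_X))
    for (j in seq_len(nrow(train_X)))
      d[j] <- sum((query_X[i, ] - train_X[j, ])^2)
    ord <- order(d, seq_along(d))              # ties by training-row index
    nb <- ord[seq_len(k)]
    lab <- train_y[nb]
    cnt <- table(factor(lab, levels = sort(unique(train_y))))
    best <- as.integer(names(cnt)[cnt == max(cnt)])
    if (length(best) == 1L) { pred[i] <- best; next }
    first_pos <- sapply(best, function(cl) min(which(lab == cl)))
    o <- order(first_pos, best)
    pred[i] <- best[o[1]]
  }
  pred
}

# small uniform-random population matrix
random_genotypes <- function(np, n, seed) {
  set.seed(seed)
  matrix(runif(np * n), np, n)
}

# mock evaluator: fitness is an analytic function of the genotype only
mock_eval_mean <- function(genotype, theta)
  list(fitness = mean(genotype), accuracy = 0, subset_size = 0L)
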