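test_that("KNN agrees with a brute-force oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:30) {
    n_tr <- sample(10:50, 1)
    n_q <- sample(3:10, 1)
    d <- sample(2:6, 1)
    k <- sample(1:5, 1)
    trX <- matrix(runif(n_tr * d), n_tr, d)
    trY <- sample(0:2, n_tr, replace = TRUE)
    qX <- matrix(runif(n_q * d), n_q, d)
    expect_identical(knn_predict(trX, trY, qX, k),
                     knn_oracle(trX, trY, qX, k))
  }
})

test_that("KNN boundary behaviours and tie handling are deterministic", {
  trX <- matrix(c(0, 1, 2, 3, 4, 5), ncol = 1)
  trY <- c(0L, 0L, 1L, 1L, 1L, 0L)
  # k = 1, query on a training row
  expect_identical(knn_predict(trX, trY, matrix(2), 1), 1L)
  # k = full training set: global majority everywhere
  trY2 <- c(rep(0L, 7), rep(1L, 3))
  trX2 <- matrix(runif(10), ncol = 1)
  expect_identical(knn_predict(trX2, trY2, matrix(c(.2, .8), ncol = 1), 10),
                   c(0L, 0L))
  # 5 nearest labelled 0,0,1,1,1 -> 1
  trX3 <- matrix(c(1, 2, 3, 4, 5, 50), ncol = 1)
  trY3 <- c(0L, 0L, 1L, 1L, 1L, 0L)
  expect_identical(knn_predict(trX3, trY3, matrix(0), 5), 1L)
  # vote tie: the tied class with the closest member wins
  trX4 <- matrix(c(1, 2, 3, 4), ncol = 1)
  trY4 <- c(1L, 0L, 0L, 1L)
  expect_identical(knn_predict(trX4, trY4, matrix(0), 4), 1L)
  expect_error(knn_predict(trX4, trY4, matrix(0), 5), "exceeds")
})

test_that("KNN agrees with class::knn on a tie-free fixture", {
  skip_if_not_installed("class")
  set.seed(21)
  trX <- matrix(rnorm(200), 50, 4)
  trY <- sample(0:1, 50, replace = TRUE)
  qX <- matrix(rnorm(80), 20, 4)
  ours <- knn_predict(trX, trY, qX, 3)
  ref <- as.integer(as.character(class::knn(trX, qX, factor(trY), k = 3)))
  expect_identical(ours, ref)
})

test_that("CV accuracy is perfect on separable data, chance on permuted labels", {
  ds <- make_separable_dataset(n_per_class = 25)
  dsn <- apply_minmax(fit_minmax(ds, 1:50), ds)
  mask <- c(TRUE, rep(FALSE, 3))
  expect_equal(cv_accuracy(dsn, 1:50, mask, fitness_spec(), seed = 1), 1.0)

  set.seed(5)
  n <- 200
  Xr <- matrix(runif(n * 4), n, 4)
  yr <- rep(0:1, each = n / 2)[sample(n)]
  dsr <- efs_dataset(Xr, yr)
  acc <- cv_accuracy(dsr, seq_len(n), rep(TRUE, 4), fitness_spec(), seed = 2)
  expect_lt(abs(acc - 0.5), 0.1)
  expect_error(cv_accuracy(dsn, 1:50, rep(FALSE, 4), fitness_spec(), 1),
               "empty")
})

test_that("CV accuracy is invariant to feature order permutation", {
  set.seed(8)
  gen <- synth_generate(synth_spec(n_samples = 60, n_informative = 3,
                                   n_noise = 3, seed = 8))
  ds <- apply_minmax(fit_minmax(gen$dataset, 1:60), gen$dataset)
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  perm <- sample(6)
  ds_p <- ds
  ds_p$X <- ds$X[, perm]
  a1 <- cv_accuracy(ds, 1:60, mask, fitness_spec(), seed = 3)
  a2 <- cv_accuracy(ds_p, 1:60, mask[perm], fitness_spec(), seed = 3)
  expect_equal(a1, a2)
})

test_that("fitness combines error and subset share and is monotone", {
  expect_equal(fitness_value(1, 10, 10, beta = 0.9), 0.1)
  expect_equal(fitness_value(0.8, 5, 10, beta = 0.5), 0.35)
  expect_equal(fitness_value(1, 0, 10, beta = 0.9), 0)
  expect_error(fitness_value(0.5, 1, 10, beta = 1), "beta")
  set.seed(4)
  for (i in 1:20) {
    b <- runif(1, 0.05, 0.95); acc <- runif(1); s <- sample(0:9, 1)
    f <- fitness_value(acc, s, 10, b)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_lt(fitness_value(min(acc + 0.1, 1), s, 10, b), f + 1e-12)
    expect_gt(fitness_value(acc, s + 1, 10, b), f)
  }
})

test_that("individual evaluation applies the empty-subset policy", {
  ds <- make_separable_dataset()
  dsn <- apply_minmax(fit_minmax(ds, 1:40), ds)
  g <- c(0.45, 0.2, 0.1, 0.3)   # everything below theta = 0.5
  ev <- evaluate_individual(g, 0.5, dsn, 1:40, fitness_spec(beta = 0.9))
  expect_equal(ev$fitness, 1)
  expect_equal(ev$accuracy, 0)
  expect_equal(ev$subset_size, 0L)
  spec_r <- fitness_spec(beta = 0.9, empty_subset_policy = "repair")
  ev_r <- evaluate_individual(g, 0.5, dsn, 1:40, spec_r)
  expect_equal(sum(ev_r$mask), 1)
  expect_true(ev_r$mask[1])     # strongest gene kept
  # determinism
  ev2 <- evaluate_individual(g, 0.4, dsn, 1:40, fitness_spec(), seed = 9)
  ev3 <- evaluate_individual(g, 0.4, dsn, 1:40, fitness_spec(), seed = 9)
  expect_identical(ev2, ev3)
})

test_that("test-split validation generalizes on separable data, not on noise", {
  gen <- synth_generate(synth_spec(n_samples = 200, n_classes = 2,
                                   n_informative = 5, n_noise = 10,
                                   class_separation = 6, seed = 31))
  ds <- gen$dataset
  sp <- stratified_split(ds, 0.7, seed = 1)
  dsn <- apply_minmax(fit_minmax(ds, sp$train_indices), ds)
  truth_gen <- as.numeric(gen$truth_mask)   # genes 1 on truth, 0 elsewhere
  v <- validate_on_test(truth_gen, 0.5, dsn, sp, fitness_spec())
  expect_gt(v$test_accuracy, 0.95)
  # pure-noise subset: near chance
  noise_gen <- as.numeric(!gen$truth_mask)
  v2 <- validate_on_test(noise_gen, 0.5, dsn, sp, fitness_spec())
  expect_lt(abs(v2$test_accuracy - 0.5), 0.15)
  # row order of the test split does not matter (prediction is per-row)
  pr_a <- knn_predict(dsn$X[sp$train_indices, 1:5], dsn$y[sp$train_indices],
                      dsn$X[sp$test_indices, 1:5], 5)
  rev_idx <- rev(sp$test_indices)
  pr_b <- knn_predict(dsn$X[sp$train_indices, 1:5], dsn$y[sp$train_indices],
                      dsn$X[rev_idx, 1:5], 5)
  expect_identical(pr_a, rev(pr_b))
})
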