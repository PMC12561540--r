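make_summaries <- function(n_datasets, methods, n_runs = 10, seed = 1,
                           shift = NULL) {
  set.seed(seed)
  out <- list()
  for (d in seq_len(n_datasets)) {
    ms <- lapply(seq_along(methods), function(j)
      rnorm(n_runs, mean = if (is.null(shift)) 0 else shift[j]))
    names(ms) <- methods
    out[[paste0("ds", d)]] <- ms
  }
  out
}

test_that("score matrix stacks one row per dataset-statistic pair", {
  s <- make_summaries(15, c("A", "B", "C"))
  m <- build_score_matrix(s, c("mean", "median"))
  expect_equal(nrow(m$scores), 30)
  m1 <- build_score_matrix(make_summaries(3, c("A", "B")), "mean")
  expect_equal(nrow(m1$scores), 3)
  dup <- make_summaries(2, c("A", "B"))
  names(dup) <- c("ds1", "ds1")
  expect_error(build_score_matrix(dup), "unique")
})

test_that("Friedman handles total ties and dominant methods", {
  scores <- matrix(1, 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  m <- structure(list(scores = scores, higher_is_better = TRUE),
                 class = "score_matrix")
  fr <- friedman_test(m)
  expect_equal(fr$statistic, 0)
  expect_equal(unname(fr$avg_ranks), rep(2, 3))

  set.seed(2)
  scores2 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  scores2[, 1] <- scores2[, 1] + 100   # strictly best everywhere
  m2 <- structure(list(scores = scores2, higher_is_better = TRUE),
                  class = "score_matrix")
  expect_equal(unname(friedman_test(m2)$avg_ranks["A"]), 1)
})

test_that("Friedman matches both a rank-formula oracle and stats::friedman.test", {
  set.seed(3)
  for (rep in 1:100) {
    N <- sample(4:12, 1); k <- sample(3:6, 1)
    scores <- matrix(rnorm(N * k), N, k,
                     dimnames = list(NULL, paste0("m", 1:k)))
    m <- structure(list(scores = scores, higher_is_better = FALSE),
                   class = "score_matrix")
    fr <- friedman_test(m)
    # independent oracle: rank each row, then the closed-form statistic
    R <- t(apply(scores, 1, rank))
    Rj <- colSums(R)
    chi <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
    expect_equal(fr$statistic, chi, tolerance = 1e-9)
    ref <- stats::friedman.test(scores)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(fr$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Nemenyi critical difference follows the published arithmetic", {
  # q_0.05 for 7 methods (studentized range at infinite df over sqrt 2)
  # equals 2.949 in Demsar's published table
  q7 <- qtukey(0.95, 7, Inf) / sqrt(2)
  expect_equal(q7, 2.949, tolerance = 1e-3)
  expect_equal(nemenyi_cd(7, 30), q7 * sqrt(7 * 8 / (6 * 30)))
  # scaling law and monotone decrease in N
  expect_equal(nemenyi_cd(5, 40), nemenyi_cd(5, 10) / 2)
  expect_lt(nemenyi_cd(4, 1000), nemenyi_cd(4, 10))
})

test_that("Wilcoxon signed-rank matches the exact enumeration and wilcox.test", {
  # n = 6 all-positive differences: exact two-sided p = 2/64
  x <- c(2, 3, 4, 5, 6, 7); y <- c(1, 1, 1, 1, 1, 1)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$method, "exact")
  # symmetry
  expect_equal(wilcoxon_signed_rank(y, x)$p_value, w$p_value)
  # all-zero differences are degenerate
  expect_error(wilcoxon_signed_rank(x, x), "zero")

  set.seed(4)
  for (rep in 1:100) {
    n <- sample(6:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- if (ours$method == "exact")
      stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    else
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                          correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("compare_all gates the post hoc stage on the Friedman p-value", {
  # null scores: no post hoc
  s0 <- make_summaries(6, c("A", "B", "C"), seed = 11)
  m0 <- build_score_matrix(s0)
  # force a comfortably non-significant configuration
  c0 <- compare_all(m0, alpha = 1e-6)
  expect_false(c0$posthoc)
  expect_null(c0$cd)

  # one dominant method becomes the control
  s1 <- make_summaries(10, c("A", "B", "C"), seed = 12,
                       shift = c(5, 0, 0))
  m1 <- build_score_matrix(s1, higher_is_better = TRUE)
  c1 <- compare_all(m1)
  expect_true(c1$posthoc)
  expect_equal(c1$control, "A")
  expect_false("A" %in% c1$wilcoxon$method)
  dd <- cd_diagram_data(c1)
  expect_equal(dd$cd, c1$cd)
})

test_that("compare_all flags match manual recomputation on a random matrix", {
  set.seed(13)
  scores <- matrix(rnorm(100), 20, 5,
                   dimnames = list(NULL, paste0("m", 1:5)))
  scores[, 2] <- scores[, 2] + 2
  m <- structure(list(scores = scores, higher_is_better = TRUE),
                 class = "score_matrix")
  cmp <- compare_all(m)
  if (cmp$posthoc) {
    R <- t(apply(-scores, 1, rank))
    rbar <- colMeans(R)
    cd <- qtukey(0.95, 5, Inf) / sqrt(2) * sqrt(5 * 6 / (6 * 20))
    expect_equal(unname(cmp$avg_ranks), unname(rbar))
    manual_sig <- abs(outer(rbar, rbar, "-")) > cd
    expect_equal(cmp$nemenyi_significant, manual_sig)
    ctrl <- names(which.min(rbar))
    expect_equal(cmp$control, ctrl)
    for (i in seq_len(nrow(cmp$wilcoxon))) {
      mm <- cmp$wilcoxon$method[i]
      ref <- suppressWarnings(
        stats::wilcox.test(scores[, ctrl], scores[, mm], paired = TRUE))
      expect_equal(cmp$wilcoxon$significant[i], ref$p.value < 0.05)
    }
  }
})
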