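#' Build a datasets-by-methods score matrix
#'
#' Stacks one row per (dataset, summary statistic) pair — the replication
#' protocol uses the mean and the median over runs, so 15 datasets yield
#' 2 x 15 = 30 paired observations per method comparison.
#'
#' @param summaries named list, one element per dataset, each a named list
#'   of per-method numeric run vectors (same method names everywhere).
#' @param statistics summary statistics applied per dataset and method;
#'   any of \code{"mean"}, \code{"median"}.
#' @param higher_is_better orientation of the scores (TRUE for accuracy,
#'   FALSE for fitness, subset size or GTC).
#' @return A list of class \code{score_matrix} with the numeric matrix
#'   \code{scores} (rows \code{dataset.statistic}, columns methods) and
#'   the orientation flag.
#' @export
build_score_matrix <- function(summaries, statistics = c("mean", "median"),
                               higher_is_better = TRUE) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  dn <- names(summaries)
  if (is.null(dn) || anyDuplicated(dn))
    stop("summaries must be a named list with unique dataset ids")
  methods <- names(summaries[[1]])
  if (length(methods) < 2L) stop("need at least two methods")
  for (d in dn)
    if (!identical(names(summaries[[d]]), methods))
      stop("dataset '", d, "' has a different method set")
  stat_fn <- list(mean = mean, median = stats::median)
  rows <- list()
  for (s in statistics)
    for (d in dn)
      rows[[paste(d, s, sep = ".")]] <-
        vapply(summaries[[d]], function(v) stat_fn[[s]](v), numeric(1))
  m <- do.call(rbind, rows)
  colnames(m) <- methods
  structure(list(scores = m, higher_is_better = higher_is_better),
            class = "score_matrix")
}

# within-row ranks, rank 1 = best under the matrix orientation; ties get
# average ranks
rank_rows <- function(m) {
  s <- if (m$higher_is_better) -m$scores else m$scores
  t(apply(s, 1, rank))
}

#' Friedman rank test over a score matrix
#'
#' Ranks methods within each row (ties averaged) and computes the classic
#' chi-squared Friedman statistic
#' \code{12 N / (k (k + 1)) * (sum(Rbar_j^2) - k (k + 1)^2 / 4)}
#' with k - 1 degrees of freedom.
#'
#' @param m a [build_score_matrix] result.
#' @return List with \code{statistic}, \code{p_value}, \code{df},
#'   \code{avg_ranks} (named, lower = better), \code{n_rows} and
#'   \code{n_methods}.
#' @export
friedman_test <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  k <- ncol(m$scores); N <- nrow(m$scores)
  if (k < 2L || N < 2L) stop("need >= 2 methods and >= 2 rows")
  R <- rank_rows(m)
  rbar <- colMeans(R)
  stat <- 12 * N / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       df = k - 1L, avg_ranks = rbar, n_rows = N, n_methods = k)
}

#' Nemenyi critical difference
#'
#' Two methods differ significantly when their average ranks differ by
#' more than \code{CD = q_alpha(k) * sqrt(k (k + 1) / (6 N))}, where
#' \code{q_alpha(k)} is the studentized-range quantile at infinite degrees
#' of freedom divided by sqrt(2).
#'
#' @param k number of methods.
#' @param N number of rows (paired observations).
#' @param alpha significance level (default 0.05).
#' @return The critical difference.
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  stopifnot(k >= 2L, N >= 1L, alpha > 0, alpha < 1)
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

# exact null distribution of the positive-rank sum for n untied ranks:
# probability vector over W = 0..n(n+1)/2, built by convolution
signed_rank_null <- function(n) {
  p <- 1
  for (r in seq_len(n)) p <- (c(p, numeric(r)) + c(numeric(r), p)) / 2
  p
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided test of the paired differences \code{x - y}. Zero differences
#' are dropped; the null distribution is exact (full enumeration by
#' convolution) when at most 25 nonzero pairs remain and their absolute
#' differences are untied, and a tie-corrected normal approximation
#' (without continuity correction) otherwise.
#'
#' @param x,y equal-length paired score vectors.
#' @param alpha significance level used for the \code{significant} flag.
#' @return List with \code{statistic} (positive-rank sum W), \code{p_value},
#'   \code{n} (pairs after dropping zeros), \code{method} ("exact" or
#'   "approx") and \code{significant}; errors when all differences are
#'   zero.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero: no difference to test")
  if (n < 5L) warning("fewer than 5 nonzero pairs; the test has little power")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25L && !ties) {
    null <- signed_rank_null(n)
    w_vals <- 0:(n * (n + 1) / 2)
    p <- if (W > n * (n + 1) / 4)
      2 * sum(null[w_vals >= W]) else 2 * sum(null[w_vals <= W])
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approx"
  }
  list(statistic = W, p_value = p, n = n, method = method,
       significant = p < alpha)
}

#' Full method comparison: Friedman gate, Nemenyi, Wilcoxon vs control
#'
#' Runs the Friedman test; only when its null hypothesis is rejected at
#' \code{alpha} does it proceed to the post hoc stage: the Nemenyi critical
#' difference over average ranks, and Wilcoxon signed-rank tests of every
#' method against the control (the method with the lowest average rank).
#' Raw pairwise p-values are reported; an optional Holm correction is
#' available.
#'
#' @param m a [build_score_matrix] result.
#' @param alpha significance level (default 0.05).
#' @param holm apply Holm correction across the Wilcoxon family
#'   (default FALSE, matching conventional reporting of raw p-values).
#' @return A list of class \code{efs_comparison}: \code{friedman},
#'   \code{avg_ranks}, and (when the gate rejects) \code{cd},
#'   \code{control}, \code{wilcoxon} (data.frame per non-control method)
#'   and \code{nemenyi_significant} (logical matrix).
#' @export
compare_all <- function(m, alpha = 0.05, holm = FALSE) {
  fr <- friedman_test(m)
  out <- list(friedman = fr, avg_ranks = fr$avg_ranks, alpha = alpha,
              posthoc = fr$p_value < alpha)
  if (!out$posthoc) return(structure(out, class = "efs_comparison"))

  k <- fr$n_methods; N <- fr$n_rows
  out$cd <- nemenyi_cd(k, N, alpha)
  dr <- abs(outer(fr$avg_ranks, fr$avg_ranks, "-"))
  out$nemenyi_significant <- dr > out$cd
  control <- names(which.min(fr$avg_ranks))
  out$control <- control

  others <- setdiff(colnames(m$scores), control)
  res <- lapply(others, function(mm) {
    w <- wilcoxon_signed_rank(m$scores[, control], m$scores[, mm], alpha)
    data.frame(method = mm, statistic = w$statistic, p_value = w$p_value,
               test = w$method)
  })
  wdf <- do.call(rbind, res)
  if (holm) wdf$p_value <- stats::p.adjust(wdf$p_value, "holm")
  wdf$significant <- wdf$p_value < alpha
  out$wilcoxon <- wdf
  structure(out, class = "efs_comparison")
}

#' @export
print.efs_comparison <- function(x, ...) {
  fr <- x$friedman
  cat(sprintf("Friedman chi-squared = %.4f, df = %d, p = %.4g\n",
              fr$statistic, fr$df, fr$p_value))
  cat("Average ranks (lower is better):\n")
  print(round(sort(fr$avg_ranks), 3))
  if (!x$posthoc) {
    cat("Friedman null not rejected at alpha =", x$alpha,
        "- no post hoc analysis.\n")
    return(invisible(x))
  }
  cat(sprintf("Nemenyi CD = %.4f | control method: %s\n", x$cd, x$control))
  cat("Wilcoxon signed-rank vs control:\n")
  print(x$wilcoxon, row.names = FALSE)
  invisible(x)
}

#' Critical-difference diagram data
#'
#' Emits the average ranks and the critical difference in a plain list
#' suitable for external plotting of a critical-difference diagram.
#'
#' @param comparison an \code{efs_comparison} from [compare_all].
#' @return List with \code{methods}, \code{avg_ranks} and \code{cd}
#'   (NULL when the Friedman gate did not reject).
#' @export
cd_diagram_data <- function(comparison) {
  stopifnot(inherits(comparison, "efs_comparison"))
  list(methods = names(comparison$avg_ranks),
       avg_ranks = unname(comparison$avg_ranks),
       cd = if (comparison$posthoc) comparison$cd else NULL)
}
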