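## Enumeration-exact nonparametric tests for small repeated-measures designs.
## The omnibus Friedman statistic, its exact permutation null, exact all-pairs
## rank-sum-difference comparisons, and an exact Mann-Whitney test. Exhaustive
## enumeration is used whenever the configuration count (k!)^n stays below
## `enum_limit`; all-pairs comparisons otherwise fall back to seeded Monte
## Carlo, the omnibus to the chi-square approximation.

# all permutations of seq_len(k), one per row
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (pos in seq_len(k)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                 sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# within-block midranks and the tie term sum(t^3 - t) per block
block_ranks <- function(m) {
  r <- t(apply(m, 1, rank))
  tie_term <- sum(apply(r, 1, function(u) { tb <- table(u); sum(tb^3 - tb) }))
  list(r = r, tie_term = tie_term)
}

friedman_statistic <- function(colsums, n, k, tie_term) {
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(0)
  (12 * sum((colsums - n * (k + 1) / 2)^2)) / denom
}

#' Friedman rank-sum test with an enumeration-exact small-sample null
#'
#' Within-block ranks (midranks on ties); the tie-corrected chi-square-form
#' statistic. The p-value comes from exhaustive enumeration of all `(k!)^n`
#' equally likely within-block orderings when that count does not exceed
#' `enum_limit` (the enumeration is carried out as a convolution over column
#' rank-sum vectors, so it is feasible whenever the gate allows it), and from
#' the `chi^2_(k-1)` approximation otherwise.
#'
#' @param m Numeric matrix: rows are blocks (flights), columns treatments
#'   (time bins). No missing cells.
#' @param exact `"auto"` (gate on `enum_limit`), `"never"`, or `"always"`.
#' @param enum_limit Maximum number of configurations enumerated.
#' @return An object of class `htest` with `statistic`, `p.value`, `method`.
#' @export
friedman_test <- function(m, exact = c("auto", "never", "always"),
                          enum_limit = 1e6) {
  exact <- match.arg(exact)
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  br <- block_ranks(m)
  stat <- friedman_statistic(colSums(br$r), n, k, br$tie_term)
  n_config <- factorial(k)^n
  use_exact <- switch(exact,
    auto = n_config <= enum_limit,
    always = TRUE,
    never = FALSE)
  if (use_exact) {
    dist <- friedman_null_distribution(br$r, br$tie_term)
    p <- sum(dist$prob[dist$stat >= stat - 1e-9])
    method <- sprintf("Friedman rank sum test (exact, %g configurations)", n_config)
  } else {
    p <- stats::pchisq(stat, k - 1, lower.tail = FALSE)
    method <- "Friedman rank sum test (chi-square approximation)"
  }
  structure(
    list(statistic = c(`Friedman chi-squared` = stat),
         parameter = c(df = k - 1), p.value = min(p, 1),
         method = method, data.name = deparse(substitute(m))),
    class = "htest")
}

# full permutation null of the Friedman statistic: convolution over the
# distribution of column rank-sum vectors, blocks processed one at a time
friedman_null_distribution <- function(r, tie_term) {
  n <- nrow(r); k <- ncol(r)
  perms <- permutations_of(k)
  # state: unique column-sum vectors with probabilities
  sums <- matrix(0, 1, k); prob <- 1
  for (i in seq_len(n)) {
    block_vecs <- matrix(r[i, ][perms], nrow(perms), k)
    ns <- sums[rep(seq_len(nrow(sums)), each = nrow(block_vecs)), , drop = FALSE] +
      block_vecs[rep(seq_len(nrow(block_vecs)), nrow(sums)), , drop = FALSE]
    np <- rep(prob, each = nrow(block_vecs)) / nrow(block_vecs)
    key <- do.call(paste, c(as.data.frame(ns), sep = ","))
    agg <- rowsum(np, key)
    keep <- match(rownames(agg), key)
    sums <- ns[keep, , drop = FALSE]
    prob <- as.numeric(agg)
  }
  stat <- apply(sums, 1, friedman_statistic, n = n, k = k, tie_term = tie_term)
  list(stat = stat, prob = prob)
}

#' Exact all-pairs comparisons of Friedman-type ranked data
#'
#' For every pair of treatments (j, j'), the statistic is the absolute
#' difference of column rank sums, `D = |R_j - R_j'|`, computed on the
#' within-block midranks. Its null distribution enumerates the within-block
#' permutations exhaustively (convolution over the per-block rank-pair
#' differences) when `(k!)^n <= enum_limit`, and otherwise uses seeded Monte
#' Carlo with at least `mc_draws` draws. Two-sided p-values `P(D* >= D)` are
#' adjusted for the `k(k-1)/2` comparisons (Bonferroni by default, capped
#' at 1).
#'
#' @inheritParams friedman_test
#' @param p_adjust Multiplicity adjustment method (see [stats::p.adjust()]).
#' @param mc_draws Monte Carlo draws when enumeration is infeasible.
#' @param seed Optional seed for the Monte Carlo fallback.
#' @return data.frame of class `pairwise_result`: columns `treat_i`,
#'   `treat_j`, `statistic`, `p`, `p_adj`, `method`.
#' @export
friedman_allpairs <- function(m, p_adjust = "bonferroni", enum_limit = 1e6,
                              mc_draws = 1e5, seed = NULL) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  br <- block_ranks(m); r <- br$r
  labs <- colnames(m) %||% as.character(seq_len(k))
  use_exact <- factorial(k)^n <= enum_limit
  if (!use_exact && !is.null(seed)) set.seed(seed)
  pairs <- utils::combn(k, 2)
  res <- data.frame(
    treat_i = labs[pairs[1, ]], treat_j = labs[pairs[2, ]],
    statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
    method = if (use_exact) "exact enumeration" else
      sprintf("Monte Carlo (%d draws)", as.integer(mc_draws)),
    stringsAsFactors = FALSE)
  for (q in seq_len(ncol(pairs))) {
    j1 <- pairs[1, q]; j2 <- pairs[2, q]
    D <- abs(sum(r[, j1]) - sum(r[, j2]))
    res$statistic[q] <- D
    res$p[q] <- if (use_exact) {
      pair_diff_exact_p(r, j1, j2, D)
    } else {
      pair_diff_mc_p(r, D, mc_draws)
    }
  }
  res$p_adj <- pmin(stats::p.adjust(res$p, method = p_adjust), 1)
  structure(res, class = c("pairwise_result", "data.frame"))
}

# exact P(|sum_i d_i| >= D) where d_i is the rank difference between two
# distinct uniformly chosen positions of block i; integer convolution on a
# half-rank grid (midranks are multiples of 1/2)
pair_diff_exact_p <- function(r, j1, j2, D) {
  n <- nrow(r); k <- ncol(r)
  span <- as.integer(2 * n * (k - 1))          # |2*sum d| bound
  dist <- numeric(2L * span + 1L); dist[span + 1L] <- 1
  for (i in seq_len(n)) {
    ri <- 2 * r[i, ]                            # integers
    idx <- expand.grid(a = seq_len(k), b = seq_len(k))
    idx <- idx[idx$a != idx$b, ]
    d <- as.integer(ri[idx$a] - ri[idx$b])
    step <- tabulate(d - min(d) + 1L, max(d) - min(d) + 1L) / length(d)
    new <- numeric(length(dist))
    offs <- seq(min(d), max(d))
    for (w in seq_along(offs)) {
      if (step[w] == 0) next
      sh <- offs[w]
      src <- seq_along(dist)
      dst <- src + sh
      okk <- dst >= 1 & dst <= length(dist)
      new[dst[okk]] <- new[dst[okk]] + dist[src[okk]] * step[w]
    }
    dist <- new
  }
  vals <- abs(seq(-span, span))
  sum(dist[vals >= 2 * D - 1e-9])
}

# Monte Carlo version of the same null, fully vectorized
pair_diff_mc_p <- function(r, D, B) {
  n <- nrow(r); k <- ncol(r); B <- as.integer(B)
  i1 <- sample.int(k, n * B, replace = TRUE)
  i2r <- sample.int(k - 1L, n * B, replace = TRUE)
  i2 <- i2r + (i2r >= i1)
  rows <- rep(seq_len(n), B)
  d <- r[cbind(rows, i1)] - r[cbind(rows, i2)]
  Ds <- abs(colSums(matrix(d, n, B)))
  (1 + sum(Ds >= D - 1e-9)) / (B + 1)
}

#' Lower-triangular matrix of adjusted pairwise p-values
#'
#' Reshapes a [friedman_allpairs()] result into the lower-triangular layout of
#' published all-pairs tables (rows/columns are treatments, cells adjusted
#' p-values).
#'
#' @param res A `pairwise_result`.
#' @param value `"p_adj"` or `"p"`.
#' @return A square matrix with `NA` on and above the diagonal.
#' @export
allpairs_matrix <- function(res, value = c("p_adj", "p")) {
  value <- match.arg(value)
  labs <- unique(c(res$treat_i, res$treat_j))
  k <- length(labs)
  out <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (q in seq_len(nrow(res))) {
    i <- match(res$treat_j[q], labs); j <- match(res$treat_i[q], labs)
    out[max(i, j), min(i, j)] <- res[[value]][q]
  }
  out
}

#' Mann-Whitney U test with an enumeration-exact p-value
#'
#' U is computed from joint midranks. When there are no ties and the number of
#' group labelings `choose(n1 + n2, n1)` does not exceed `enum_limit`, the
#' two-sided p-value enumerates all labelings exactly; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact `"auto"`, `"never"`, or `"always"` (errors on ties).
#' @param enum_limit Maximum number of labelings enumerated.
#' @return An object of class `htest` with the U `statistic` and `p.value`.
#' @export
mann_whitney <- function(x, y, exact = c("auto", "never", "always"),
                         enum_limit = 1e6) {
  exact <- match.arg(exact)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  n_lab <- choose(n1 + n2, n1)
  use_exact <- switch(exact,
    auto = !ties && n_lab <= enum_limit,
    always = TRUE,
    never = FALSE)
  if (use_exact && ties) stop("exact enumeration requires untied data")
  mu <- n1 * n2 / 2
  if (use_exact) {
    labelings <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(rk[labelings], n1)) - n1 * (n1 + 1) / 2
    p <- sum(abs(Us - mu) >= abs(U - mu) - 1e-9) / ncol(labelings)
    method <- sprintf("Mann-Whitney U test (exact, %g labelings)", n_lab)
  } else {
    N <- n1 + n2
    tb <- table(rk)
    sig2 <- n1 * n2 / 12 * (N + 1 - sum(tb^3 - tb) / (N * (N - 1)))
    p <- if (sig2 <= 0) 1 else 2 * stats::pnorm(-abs(U - mu) / sqrt(sig2))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(
    list(statistic = c(U = U), p.value = min(p, 1), method = method,
         data.name = paste(deparse(substitute(x)), "vs", deparse(substitute(y)))),
    class = "htest")
}

#' Type-I error rate of the omnibus test on simulated null cohorts
#'
#' Runs `null_generator()` `reps` times; each call must return an epoch matrix
#' generated under no manipulation response. Returns the fraction of omnibus
#' Friedman p-values below `alpha`.
#'
#' @param null_generator Function of no arguments returning a numeric matrix.
#' @param alpha Significance level.
#' @param reps Number of replicates (>= 100).
#' @param seed Optional seed set before the first replicate.
#' @param ... Passed on to [friedman_test()].
#' @return Rejection rate in \[0, 1\].
#' @export
type_one_error_sim <- function(null_generator, alpha = 0.01, reps = 1000,
                               seed = NULL, ...) {
  if (reps < 100) stop("reps must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(reps)) {
    p <- friedman_test(null_generator(), ...)$p.value
    if (p <= alpha) hits <- hits + 1L   # exact-test convention: reject at p <= alpha
  }
  hits / reps
}

#' Export pairwise results as CSV
#'
#' @param res A `pairwise_result`.
#' @param path Output file.
#' @export
write_pairwise_csv <- function(res, path) {
  utils::write.csv(as.data.frame(res), path, row.names = FALSE)
  invisible(path)
}
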