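# Independent brute-force oracles for the exact rank tests. These share no
# code with the package: permutations come from the lexicographic successor
# algorithm, statistics are written out from their defining formulas, and
# p-values are plain fractions over the enumerated configuration space.

# all permutations of 1..k in lexicographic order
lex_perms <- function(k) {
  p <- seq_len(k)
  out <- list(p)
  repeat {
    i <- k - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- k
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):k] <- rev(p[(i + 1L):k])
    out[[length(out) + 1L]] <- p
  }
  do.call(rbind, out)
}

# enumerate every within-block permutation of the observed values; return the
# omnibus statistic and all pairwise rank-sum differences for each
# configuration, with the observed values
oracle_enumerate <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  tie <- sum(apply(r, 1, function(u) { tb <- table(u); sum(tb^3 - tb) }))
  denom <- n * k * (k + 1) - tie / (k - 1)
  perms <- lex_perms(k)
  P <- nrow(perms)
  idx <- as.matrix(expand.grid(rep(list(seq_len(P)), n)))
  cs <- matrix(0, nrow(idx), k)
  for (i in seq_len(n)) {
    permed <- matrix(r[i, ][perms], P, k)
    cs <- cs + permed[idx[, i], , drop = FALSE]
  }
  stat_of <- function(csums) 12 * rowSums((csums - n * (k + 1) / 2)^2) / denom
  pairs <- utils::combn(k, 2)
  list(
    n_config = nrow(idx),
    stat = stat_of(cs),
    obs_stat = stat_of(matrix(colSums(r), 1)),
    pair_D = lapply(seq_len(ncol(pairs)), function(q) {
      abs(cs[, pairs[1, q]] - cs[, pairs[2, q]])
    }),
    obs_D = apply(pairs, 2, function(jj) abs(sum(r[, jj[1]]) - sum(r[, jj[2]])))
  )
}

oracle_friedman_p <- function(m) {
  e <- oracle_enumerate(m)
  mean(e$stat >= e$obs_stat - 1e-9)
}

oracle_allpairs_p <- function(m) {
  e <- oracle_enumerate(m)
  vapply(seq_along(e$pair_D),
         function(q) mean(e$pair_D[[q]] >= e$obs_D[q] - 1e-9), 0)
}

oracle_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  rk <- rank(c(x, y))
  u_of <- function(sel) sum(rk[sel]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  lab <- utils::combn(N, n1)
  us <- apply(lab, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# trajectory builder for pipeline tests: a plain 100 Hz record
make_traj <- function(z, id = "t1", dt = 0.01, mode = "parallel",
                      texture = "white", experiment = "exp1") {
  t <- (seq_along(z) - 1) * dt
  structure(data.frame(t = t, x = 55 * t, z = z),
            class = c("trajectory", "data.frame"),
            flight_id = id, mode = mode, texture = texture,
            experiment = experiment, forward_speed = 55)
}
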