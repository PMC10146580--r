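test_that("Friedman omnibus matches its reference cases", {
  # identical columns: statistic 0, p = 1
  m0 <- matrix(rep(1:4, 3), 4, 3)
  ft0 <- friedman_test(m0, exact = "always")
  expect_equal(unname(ft0$statistic), 0)
  expect_equal(ft0$p.value, 1)
  # three blocks, all ranked 1 < 2 < 3
  m <- matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5), 3, 3, byrow = TRUE)
  ft <- friedman_test(m, exact = "always")
  expect_equal(unname(ft$statistic), 6)
  expect_equal(ft$p.value, 6 / 216)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman_test(matrix(1:3, 1, 3)), "at least 2")
})

test_that("the chi-square route agrees with base R and tracks the exact p", {
  set.seed(1)
  m <- matrix(rnorm(30), 10, 3)
  mine <- friedman_test(m, exact = "never")
  base <- stats::friedman.test(m)
  expect_equal(unname(mine$statistic), unname(base$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, base$p.value, tolerance = 1e-12)
  pe <- friedman_test(m, exact = "always")$p.value
  expect_lt(abs(mine$p.value - pe) / pe, 0.10)
})

test_that("exact omnibus and all-pairs p-values equal brute-force enumeration", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(2:4, 1); k <- sample(2:3, 1)
    m <- matrix(rnorm(n * k), n, k)
    expect_equal(friedman_test(m, exact = "always")$p.value,
                 oracle_friedman_p(m), tolerance = 1e-12)
    expect_equal(friedman_allpairs(m)$p, oracle_allpairs_p(m), tolerance = 1e-12)
  }
  # with ties (midranks) as well
  mt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 4, 4), 3, 3)
  expect_equal(friedman_test(mt, exact = "always")$p.value,
               oracle_friedman_p(mt), tolerance = 1e-12)
  expect_equal(friedman_allpairs(mt)$p, oracle_allpairs_p(mt), tolerance = 1e-12)
})

test_that("all-pairs results behave under null and separated data", {
  m0 <- matrix(rep(1:4, 3), 4, 3)
  ap0 <- friedman_allpairs(m0)
  expect_true(all(ap0$p_adj == 1))
  # maximally separated pair, n = 4, k = 3
  m <- matrix(c(1, 5, 9), 4, 3, byrow = TRUE) + matrix(rnorm(12, 0, 0.1), 4, 3)
  ap <- friedman_allpairs(m)
  expect_equal(ap$p, oracle_allpairs_p(m), tolerance = 1e-12)
  q13 <- which(ap$treat_i == "1" & ap$treat_j == "3")
  expect_equal(ap$p[q13], min(ap$p))
  expect_true(all(ap$p_adj >= ap$p - 1e-15) && all(ap$p_adj <= 1))
  # lower-triangular export
  M <- allpairs_matrix(ap)
  expect_true(all(is.na(M[upper.tri(M, diag = TRUE)])))
  expect_equal(M[3, 1], ap$p_adj[q13])
})

test_that("Monte Carlo all-pairs approximates the exact pair p-values", {
  set.seed(21)
  m <- matrix(rnorm(12), 4, 3)
  ex <- friedman_allpairs(m)$p
  mc <- friedman_allpairs(m, enum_limit = 1, mc_draws = 4e4, seed = 9)$p
  expect_lt(max(abs(ex - mc)), 0.02)
  # seeded Monte Carlo is reproducible
  mc2 <- friedman_allpairs(m, enum_limit = 1, mc_draws = 4e4, seed = 9)$p
  expect_identical(mc, mc2)
})

test_that("shifting one column weakly strengthens its pairwise evidence", {
  # raising a column that already ranks at least as high as its partner can
  # only increase their rank-sum separation, hence weakly decrease the p-value
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(rnorm(12), 4, 3)
    r <- t(apply(m, 1, rank))
    p0 <- friedman_allpairs(m)$p
    for (shift in c(1, 3)) {
      m2 <- m; m2[, 3] <- m2[, 3] + shift
      p1 <- friedman_allpairs(m2)$p
      for (j in 1:2) {
        if (sum(r[, 3]) >= sum(r[, j])) {
          q <- if (j == 1) 2 else 3  # pairs (1,3) and (2,3) in combn order
          expect_lte(p1[q], p0[q] + 1e-12)
        }
      }
    }
  }
})

test_that("Mann-Whitney matches enumeration and its identities", {
  mw <- mann_whitney(1:3, 4:6)
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 0.1)
  set.seed(41)
  for (rep in 1:6) {
    x <- rnorm(sample(3:5, 1)); y <- rnorm(sample(3:5, 1))
    expect_equal(mann_whitney(x, y)$p.value, oracle_mw_p(x, y), tolerance = 1e-12)
    # U identity
    ux <- unname(mann_whitney(x, y)$statistic)
    uy <- unname(mann_whitney(y, x)$statistic)
    expect_equal(ux + uy, length(x) * length(y))
  }
  # identical samples: ties force the corrected approximation, p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # agreement with base R where both are exact
  set.seed(42)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p.value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("the type-I harness is deterministic and saturates at alpha = 1", {
  gen <- function() matrix(rnorm(12), 4, 3)
  r1 <- type_one_error_sim(gen, alpha = 1, reps = 100, seed = 5)
  expect_equal(r1, 1)
  r2 <- type_one_error_sim(gen, alpha = 0.05, reps = 150, seed = 6, exact = "always")
  r3 <- type_one_error_sim(gen, alpha = 0.05, reps = 150, seed = 6, exact = "always")
  expect_equal(r2, r3)
  expect_error(type_one_error_sim(gen, reps = 10), "at least 100")
})
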