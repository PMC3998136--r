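# worked values below derive from the brute-force reversed-prefix sort and
# pairwise prefix-comparison oracles in helper-oracles.R

test_that("prefix-array step is a stable partition", {
  # one allele class: the partition is the identity
  expect_equal(pbwt_step(0:5, rep(0L, 6)), 0:5)
  expect_equal(pbwt_step(0:5, rep(1L, 6)), 0:5)

  X <- allele_matrix(p4())
  a0 <- 0:3
  a1 <- pbwt_step(a0, X[a0 + 1, 1])
  expect_equal(a1, c(0L, 2L, 1L, 3L))  # frozen from oracle_prefix(X, 1)
  a2 <- pbwt_step(a1, X[a1 + 1, 2])
  expect_equal(a2, c(2L, 0L, 1L, 3L))  # frozen from oracle_prefix(X, 2)
  expect_equal(a1, oracle_prefix(X, 1))
  expect_equal(a2, oracle_prefix(X, 2))

  expect_error(pbwt_step(0:3, c(0L, 1L)), "4")
  expect_error(pbwt_step(0:1, c(0L, 2L)), "0 or 1")
})

test_that("divergence step tracks neighbour match starts", {
  # all-zero panel: every pair matches from 0, sentinel d[0] = k
  a <- 0:4; d <- integer(5)
  for (k in 0:5) {
    expect_equal(d, c(k, 0L, 0L, 0L, 0L))
    st <- pbwt_step_divergence(a, d, rep(0L, 5), k)
    a <- st$a; d <- st$d
  }

  X <- allele_matrix(p4())
  a <- 0:3; d <- integer(4)
  for (k in 0:1) {
    st <- pbwt_step_divergence(a, d, X[a + 1, k + 1], k)
    a <- st$a; d <- st$d
  }
  expect_equal(d, c(2L, 2L, 1L, 0L))  # frozen from pairwise-prefix oracle
  expect_equal(d, oracle_divergence(X, 2, a))

  # M = 1: only the sentinel
  a <- 0L; d <- 0L
  for (k in 0:3) {
    expect_equal(d, k)
    st <- pbwt_step_divergence(a, d, 0L, k)
    a <- st$a; d <- st$d
  }
})

test_that("sweep equals brute force for a and d at every position", {
  set.seed(42)
  for (t in 1:12) {
    p <- if (t %% 2 == 0)
      random_panel(sample(2:20, 1), sample(2:40, 1))
    else
      simulate_copying_panel(copying_model_params(
        M = sample(5:20, 1), N = sample(10:40, 1), founders = 4, seed = t))
    X <- allele_matrix(p)
    sw <- hapbwt:::cpp_sweep_all(p$alleles)
    for (k in 0:n_sites(p)) {
      a <- oracle_prefix(X, k)
      expect_equal(sw$a[[k + 1]], a)
      expect_equal(sw$d[[k + 1]], oracle_divergence(X, k, a))
      # permutation conservation
      expect_setequal(sw$a[[k + 1]], 0:(n_seq(p) - 1))
    }
  }
})

test_that("R step functions and the C++ sweep agree", {
  set.seed(99)
  p <- random_panel(15, 30)
  X <- allele_matrix(p)
  sw <- hapbwt:::cpp_sweep_all(p$alleles)
  a <- 0:14; d <- integer(15)
  for (k in 0:29) {
    st <- pbwt_step_divergence(a, d, X[a + 1, k + 1], k)
    a <- st$a; d <- st$d
    expect_identical(a, sw$a[[k + 2]])
    expect_identical(d, sw$d[[k + 2]])
  }
})

test_that("bi-allelic neighbour property holds along the sweep", {
  # wherever d[i] > 0, the sorted neighbours carry alleles 0 then 1 at
  # position d[i] - 1 (they diverge there, in sorted order)
  set.seed(7)
  p <- random_panel(20, 50)
  X <- allele_matrix(p)
  sw <- hapbwt:::cpp_sweep_all(p$alleles)
  for (k in 1:50) {
    a <- sw$a[[k + 1]]; d <- sw$d[[k + 1]]
    for (i in 2:20) {
      if (d[i] > 0) {
        expect_equal(X[a[i - 1] + 1, d[i]], 0L)
        expect_equal(X[a[i] + 1, d[i]], 1L)
      }
    }
  }
})

test_that("column ranks count zeros and ones prefix-wise", {
  r <- column_ranks(c(0L, 0L, 1L, 1L))
  expect_equal(r$u, c(0L, 1L, 2L, 2L, 2L))
  expect_equal(r$v, c(0L, 0L, 0L, 1L, 2L))
  expect_equal(r$c, 2L)
  r0 <- column_ranks(integer(0))
  expect_equal(r0$u, 0L)
  expect_equal(r0$c, 0L)
  r1 <- column_ranks(rep(1L, 4))
  expect_equal(r1$c, 0L)
  expect_true(all(r1$u == 0L))
  # u[i] + v[i] = i
  set.seed(1)
  y <- rbinom(30, 1, 0.4)
  r <- column_ranks(y)
  expect_equal(r$u + r$v, 0:30)
  expect_error(column_ranks(c(0L, 2L)), "0 or 1")
})

test_that("boundary extension matches its rank definition", {
  r <- column_ranks(c(0L, 0L, 1L, 1L))
  expect_equal(pbwt_extend(r, 0, 0), 0L)
  expect_equal(pbwt_extend(r, 0, 1), r$c)
  expect_equal(pbwt_extend(r, 4, 0), r$c)
  expect_equal(pbwt_extend(r, 4, 1), 4L)
  expect_equal(pbwt_extend(r, 3, 1), 3L)  # c + v[3] = 2 + 1
  expect_error(pbwt_extend(r, 5, 0), "0..4")
  expect_error(pbwt_extend(r, 2, 2), "allele")

  # extend agrees with the prefix-array step: mapping every boundary
  # through w reproduces the positions the stable partition assigns
  set.seed(3)
  for (t in 1:10) {
    M <- sample(2:20, 1)
    a <- sample(0:(M - 1))
    y <- rbinom(M, 1, 0.5)
    r <- column_ranks(y)
    a_next <- pbwt_step(a, y)
    for (i in seq_len(M)) {
      # sequence at sorted position i-1 with allele y lands at w(i-1, y)
      dest <- pbwt_extend(r, i - 1, y[i])
      expect_equal(a_next[dest + 1], a[i])
    }
    # monotone in i for fixed allele
    for (al in 0:1) {
      w <- vapply(0:M, function(i) pbwt_extend(r, i, al), 1L)
      expect_true(all(diff(w) >= 0))
    }
  }
})
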