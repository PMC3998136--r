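# worked match sets below are frozen from the naive per-pair oracles,
# which implement the match definitions literally

test_that("long matches on the 4 x 4 example and degenerate panels", {
  p <- p4()
  got <- long_matches(p, 2)
  want <- data.frame(seq_a = c(0L, 1L, 0L), seq_b = c(1L, 3L, 3L),
                     start = c(1L, 0L, 1L), end = c(3L, 3L, 4L))
  expect_same_matches(got, want)
  expect_same_matches(got, naive_long_matches(p, 2))

  # identical sequences: all pairs over the full interval
  z <- haplotype_panel(matrix(0L, 4, 4))
  m <- long_matches(z, 4)
  expect_equal(nrow(m), 6)
  expect_true(all(m$start == 0 & m$end == 4))

  expect_error(long_matches(p, 5), "between 1 and")
  expect_error(long_matches(p, 0), "between 1 and")
})

test_that("set-maximal matches on the 4 x 4 example", {
  p <- p4()
  got <- set_maximal_matches(p)
  want <- data.frame(
    seq_a = c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L),
    seq_b = c(3L, 2L, 3L, 2L, 0L, 1L, 0L, 1L),
    start = c(1L, 0L, 0L, 3L, 0L, 3L, 1L, 0L),
    end   = c(4L, 1L, 3L, 4L, 1L, 4L, 4L, 3L))
  expect_same_matches(got, want)
  expect_same_matches(got, naive_set_maximal(p))

  # two identical sequences report each other over [0, N)
  twin <- haplotype_panel(rbind(c(1, 0, 1), c(1, 0, 1)))
  m <- set_maximal_matches(twin)
  expect_same_matches(m, data.frame(seq_a = 0:1, seq_b = 1:0,
                                    start = 0L, end = 3L))
  expect_error(set_maximal_matches(p[1, ]), "at least 2")
  expect_error(naive_set_maximal(p[1, ]), "at least 2")
})

test_that("query matching on the 4 x 4 example", {
  p <- p4()
  idx <- build_index(p, 2)
  want <- data.frame(seq_a = 0L,
                     seq_b = c(1L, 3L, 2L, 0L, 3L),
                     start = c(0L, 0L, 2L, 3L, 3L),
                     end   = c(2L, 2L, 3L, 4L, 4L))
  expect_same_matches(query_set_maximal(idx, c(1, 1, 1, 1)), want)
  expect_same_matches(naive_query(p, c(1, 1, 1, 1)), want)
  expect_same_matches(query_batch(p, c(1, 1, 1, 1)), want)

  # a query equal to a panel sequence reports the full interval,
  # including that sequence
  m <- query_set_maximal(idx, allele_matrix(p)[2, ])
  expect_true(any(m$seq_b == 1 & m$start == 0 & m$end == 4))
  expect_same_matches(m, naive_query(p, allele_matrix(p)[2, ]))

  expect_error(query_set_maximal(idx, c(1, 0)), "sites")
  expect_error(query_set_maximal(idx, c(1, 0, 2, 0)), "0 or 1")
  expect_equal(nrow(query_batch(p, matrix(0L, 0, 4))), 0)
})

test_that("fast matchers equal their oracles on random panels", {
  set.seed(101)
  for (t in 1:25) {
    p <- random_panel(sample(3:20, 1), sample(5:40, 1))
    N <- n_sites(p)
    L <- sample(seq_len(min(N, 10)), 1)
    expect_same_matches(long_matches(p, L), naive_long_matches(p, L),
                        info = paste("long", t))
    expect_same_matches(set_maximal_matches(p), naive_set_maximal(p),
                        info = paste("setmax", t))
    Z <- matrix(rbinom(2 * N, 1, 0.5), nrow = 2)
    qn <- naive_query(p, Z)
    expect_same_matches(query_set_maximal(build_index(p, 5), Z), qn,
                        info = paste("query", t))
    expect_same_matches(query_batch(p, Z), qn, info = paste("batch", t))
  }
})

test_that("emitted matches satisfy their own interval invariants", {
  set.seed(55)
  p <- simulate_copying_panel(copying_model_params(15, 40, founders = 4,
                                                   seed = 5))
  check_match_invariants(long_matches(p, 5), p)
  check_match_invariants(set_maximal_matches(p), p)
  Z <- matrix(rbinom(2 * 40, 1, 0.5), nrow = 2)
  check_match_invariants(query_batch(p, Z), p, queries = Z)
})

test_that("long matches are unique and set-maximal counts are bounded", {
  set.seed(66)
  for (t in 1:8) {
    p <- random_panel(sample(5:20, 1), sample(10:40, 1))
    m <- long_matches(p, 4)
    if (nrow(m))
      expect_false(any(duplicated(m)))
    # count bound: <= 4 N M on tie-free style random panels
    sm <- set_maximal_matches(p, stats_only = TRUE)
    expect_lte(sm$count, 4 * n_seq(p) * n_sites(p))
  }
})

test_that("oracle self-consistency: query of a held-out sequence", {
  # querying x_i against the panel without x_i gives the same matches as
  # the within-panel set-maximal records targeting x_i
  set.seed(77)
  for (t in 1:10) {
    M <- sample(5:10, 1)
    p <- random_panel(M, sample(15:40, 1))
    X <- allele_matrix(p)
    i <- sample(M, 1)
    q <- naive_query(haplotype_panel(X[-i, , drop = FALSE]), X[i, ])
    mine <- naive_set_maximal(p)
    mine <- mine[mine$seq_a == i - 1, ]
    # relabel panel indices of the reduced panel back to the full panel
    map <- setdiff(seq_len(M), i) - 1L
    q$seq_b <- map[q$seq_b + 1]
    q$seq_a <- NULL; mine$seq_a <- NULL
    expect_same_matches(cbind(seq_a = 0L, q), cbind(seq_a = 0L, mine))
  }
})

test_that("centered blocks group sequences identical on a window", {
  # all-zero panel: one block containing everything
  z <- haplotype_panel(matrix(0L, 6, 20))
  b <- centered_blocks(build_index(z), 10, 5)
  expect_equal(length(b), 1)
  expect_equal(b[[1]]$members, 0:5)
  expect_equal(c(b[[1]]$start, b[[1]]$end), c(5, 15))

  # planted identical segment spanning the window
  set.seed(12)
  p <- random_panel(10, 60)
  p <- plant_shared_segment(p, members = c(2, 5, 7), interval = c(10, 40),
                            donor = 2)
  idx <- build_index(p)
  b <- centered_blocks(idx, 25, 10)  # window [15, 35) inside the plant
  hit <- Filter(function(x) all(c(2, 5, 7) %in% x$members), b)
  expect_equal(length(hit), 1)
  # members really are pairwise identical on the window
  X <- allele_matrix(p)
  mem <- hit[[1]]$members + 1
  expect_true(all(apply(X[mem, 16:35, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))

  # a window larger than any shared segment: only singleton blocks
  q <- random_panel(6, 40, freq = rep(0.5, 40))
  bq <- centered_blocks(build_index(q), 20, 15)
  expect_true(all(vapply(bq, function(x) length(x$members), 1L) == 1))
  expect_equal(length(bq), 6)
  expect_error(centered_blocks(idx, 3, 10), "half_length")
})

test_that("batch matching equals per-query matching on structured panels", {
  set.seed(31)
  p <- simulate_copying_panel(copying_model_params(25, 50, founders = 5,
                                                   seed = 13))
  idx <- build_index(p, 7)
  Z <- rbind(allele_matrix(p)[3, ],
             matrix(rbinom(3 * 50, 1, 0.5), nrow = 3))
  expect_same_matches(query_batch(p, Z), query_set_maximal(idx, Z))
})
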