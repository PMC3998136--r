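# shared fixtures and independent oracles for the test suite

# the 4 x 4 worked example used throughout: x0=0101 x1=1100 x2=0010 x3=1101
p4 <- function() {
  haplotype_panel(rbind(c(0, 1, 0, 1),
                        c(1, 1, 0, 0),
                        c(0, 0, 1, 0),
                        c(1, 1, 0, 1)))
}

random_panel <- function(M, N, freq = NULL) {
  if (is.null(freq)) freq <- stats::runif(N, 0.05, 0.95)
  X <- matrix(stats::rbinom(M * N, 1, rep(freq, each = M)), nrow = M)
  haplotype_panel(X)
}

# brute-force positional prefix array at position k: stable sort of the
# reversed prefixes x[, k:1] as strings, ties by original index
oracle_prefix <- function(X, k) {
  M <- nrow(X)
  if (k == 0) return(0:(M - 1))
  key <- apply(X[, k:1, drop = FALSE], 1, paste0, collapse = "")
  order(key, seq_len(M)) - 1L
}

# brute-force divergence: first position from which sorted neighbours
# agree through k (scan backwards from k - 1); d[0] = k by convention
oracle_divergence <- function(X, k, a) {
  M <- nrow(X)
  k <- as.integer(k)
  d <- integer(M)
  d[1] <- k
  if (M > 1) for (i in 2:M) {
    u <- X[a[i - 1] + 1, ]
    v <- X[a[i] + 1, ]
    j <- k
    while (j > 0L && u[j] == v[j]) j <- j - 1L
    d[i] <- j
  }
  as.integer(d)
}

# independent bit-level decoder for the run-length codec, pure integer
# arithmetic on the byte layout (never calls the package codec)
bit_decode_rle <- function(payload) {
  out <- integer(0)
  for (b in as.integer(payload)) {
    value <- b %/% 128L
    ucode <- (b %/% 32L) %% 4L
    count <- b %% 32L
    stopifnot(ucode != 3L, count > 0L)
    unit <- c(1L, 64L, 2048L)[ucode + 1L]
    out <- c(out, rep(value, unit * count))
  }
  out
}

# canonical form for multiset comparison of match frames
canon <- function(m) {
  m <- as.data.frame(lapply(m, as.integer))
  m <- m[order(m$seq_a, m$seq_b, m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  m
}

expect_same_matches <- function(got, want, info = NULL) {
  expect_identical(canon(got), canon(want), info = info)
}

# every match record must satisfy its own invariants on the panel
check_match_invariants <- function(m, panel, queries = NULL) {
  X <- allele_matrix(panel)
  Z <- if (is.null(queries)) X else {
    q <- hapbwt:::as_query_matrix(queries, n_sites(panel))
    matrix(as.integer(q), nrow = nrow(q))
  }
  N <- ncol(X)
  for (r in seq_len(nrow(m))) {
    za <- Z[m$seq_a[r] + 1, ]
    xb <- X[m$seq_b[r] + 1, ]
    s <- m$start[r]; e <- m$end[r]
    expect_true(s >= 0 && e <= N && s < e)
    expect_true(all(za[(s + 1):e] == xb[(s + 1):e]))
    expect_true(s == 0 || za[s] != xb[s])
    expect_true(e == N || za[e + 1] != xb[e + 1])
  }
}
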