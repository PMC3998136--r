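test_that("worked byte sequences match the independent bit-level oracle", {
  # a run of 200 zeros: 3 x 64-unit + 8 x 1-unit tokens = 2 bytes
  p200 <- rle_encode(rep(0L, 200))
  expect_identical(p200, as.raw(c(0x23, 0x08)))
  expect_equal(bit_decode_rle(p200), rep(0L, 200))

  # a run of 1000 zeros: 15 x 64 + 31 x 1 + 9 x 1 = 3 bytes
  p1000 <- rle_encode(rep(0L, 1000))
  expect_identical(p1000, as.raw(c(0x2F, 0x1F, 0x09)))
  expect_equal(bit_decode_rle(p1000), rep(0L, 1000))

  # alternating 01010101: eight single-unit tokens, values alternating
  alt <- rep(c(0L, 1L), 4)
  palt <- rle_encode(alt)
  expect_identical(palt, as.raw(rep(c(0x01, 0x81), 4)))
  expect_equal(bit_decode_rle(palt), alt)
})

test_that("encode/decode round-trip on random and adversarial columns", {
  set.seed(11)
  for (t in 1:60) {
    M <- sample(c(1:10, 50, 64, 65, 2048, 2049, sample(5000, 3)), 1)
    col <- switch(1 + t %% 4,
                  rbinom(M, 1, runif(1)),
                  rep(0L, M),                     # single run
                  rep_len(c(0L, 1L), M),          # alternating
                  rbinom(M, 1, 0.02))             # long runs
    pay <- rle_encode(col)
    expect_identical(rle_decode(pay, M), as.integer(col))
    expect_equal(bit_decode_rle(pay), as.integer(col))
  }
  expect_equal(rle_decode(as.raw(0x81), 1), 1L)
})

test_that("malformed payloads raise errors rather than corrupt columns", {
  expect_error(rle_decode(as.raw(0x00), 1), "zero unit count")
  expect_error(rle_decode(as.raw(0x61), 2048), "reserved")   # unit code 11
  expect_error(rle_decode(as.raw(0x02), 5), "2 of 5")        # too short
  expect_error(rle_decode(as.raw(c(0x02, 0x81)), 2), "more than")
  expect_error(rle_encode(c(0L, 2L)), "0 or 1")
})

test_that("greedy run cost follows the canonical size law", {
  # cost of a run r: ceil over 2048/64/1 units with 5-bit counts
  greedy_cost <- function(r) {
    n2 <- r %/% 2048; r <- r %% 2048
    n1 <- r %/% 64;   r <- r %% 64
    ceiling(n2 / 31) + ceiling(n1 / 31) + ceiling(r / 31)
  }
  rs <- 65:1984
  costs <- vapply(rs, function(r) length(rle_encode(rep(0L, r))), 1L)
  expect_equal(costs, vapply(rs, greedy_cost, 1))
  # the typical such run needs 2 bytes: runs whose residue modulo 64 fits
  # one 5-bit count (about half) take exactly 2; none exceeds 4
  expect_gte(mean(costs <= 2), 0.5)
  expect_equal(max(costs), 4)
  expect_equal(min(costs), 1)
})

test_that("container write/read round-trips bit-exactly", {
  set.seed(5)
  tmp <- tempfile(fileext = ".pbwt")
  on.exit(unlink(tmp))
  for (t in 1:12) {
    p <- random_panel(sample(2:25, 1), sample(2:40, 1))
    if (t %% 2 == 0)
      p$sites <- data.frame(chrom = "7", pos = sort(sample(1e6, n_sites(p))),
                            ref = "A", alt = "G",
                            stringsAsFactors = FALSE)
    idx <- build_index(p, checkpoint_interval = sample(c(1, 3, 64), 1))
    write_pbwt(idx, tmp)
    back <- read_pbwt(tmp)
    for (f in c("M", "N", "payloads", "c", "C", "cp_pos", "cp_a", "cp_d"))
      expect_identical(back[[f]], idx[[f]], info = f)
    if (!is.null(idx$sites))
      expect_equal(back$sites$pos, idx$sites$pos)
    expect_identical(allele_matrix(decode_panel(back)), allele_matrix(p))
  }
})

test_that("container integrity failures are detected", {
  p <- p4()
  tmp <- tempfile(fileext = ".pbwt")
  on.exit(unlink(tmp))
  write_pbwt(build_index(p), tmp)

  bytes <- readBin(tmp, "raw", file.size(tmp))
  bad <- bytes; bad[2] <- as.raw(0x58)          # corrupt magic
  writeBin(bad, tmp)
  expect_error(read_pbwt(tmp), "magic")

  bad <- bytes; bad[30] <- xor(bad[30], as.raw(0xFF))  # corrupt body
  writeBin(bad, tmp)
  expect_error(read_pbwt(tmp), "checksum")
})

test_that("checkpoint interval does not change the decoded panel", {
  set.seed(8)
  p <- random_panel(12, 50)
  tmp1 <- tempfile(); tmp64 <- tempfile()
  on.exit(unlink(c(tmp1, tmp64)))
  write_pbwt(build_index(p, 1), tmp1)
  write_pbwt(build_index(p, 64), tmp64)
  p1 <- decode_panel(read_pbwt(tmp1))
  p64 <- decode_panel(read_pbwt(tmp64))
  expect_identical(allele_matrix(p1), allele_matrix(p64))
  expect_identical(allele_matrix(p1), allele_matrix(p))
})

test_that("size stats account payload and baseline deterministically", {
  # all-zero 1000 x 100 panel: one 3-byte run token block per column
  p <- haplotype_panel(matrix(0L, 1000, 100))
  idx <- build_index(p)
  ss <- size_stats(idx, p)
  expect_equal(ss$payload_bytes, 300)
  expect_lte(ss$bytes_per_site, 3)
  expect_equal(ss$raw_text_bytes, 1000 * 101)
  expect_true(ss$gzip_bytes > 0)

  e <- build_index(haplotype_panel(matrix(0L, 0, 0)))
  expect_equal(size_stats(e)$payload_bytes, 0)
})
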