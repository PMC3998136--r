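#' One step of the positional prefix-array sweep
#'
#' Given the positional prefix array `a` at position `k` and the alleles of
#' the sorted sequences at site `k` (i.e. `y[i]` is the allele of sequence
#' `a[i]`), returns the prefix array at `k + 1`: a stable partition that
#' lists all sequences carrying allele 0 first, in their previous order,
#' followed by those carrying allele 1.  Sequence indices are 0-based.
#'
#' @param a integer permutation of `0:(M-1)`.
#' @param y integer vector of 0/1 alleles in `a`-sorted order.
#' @return integer permutation of `0:(M-1)` valid at the next position.
#' @seealso [pbwt_step_divergence()] for the joint update of the
#'   divergence array.
#' @export
pbwt_step <- function(a, y) {
  if (length(y) != length(a))
    stop("column has ", length(y), " values, prefix array has ", length(a))
  y <- as.integer(y)
  if (anyNA(y) || any(y < 0L | y > 1L)) stop("alleles must be 0 or 1")
  c(a[y == 0L], a[y == 1L])
}

#' One step of the joint prefix/divergence sweep
#'
#' Advances both the positional prefix array `a` and the divergence array
#' `d` from position `k` to `k + 1`.  `d[i]` (0-based `i`, stored 1-based
#' in R) is the smallest `j` such that the sorted neighbours at `i - 1`
#' and `i` agree on all sites in `[j, k)`; `d[0] == k` by the sentinel
#' convention.  The update keeps, for each allele class, the running
#' maximum of divergence values seen since the last member of that class:
#' that maximum is exactly the first disagreement position of the two
#' class members that become neighbours at `k + 1`.
#'
#' @param a integer permutation of `0:(M-1)` at position `k`.
#' @param d integer divergence values at position `k`.
#' @param y integer 0/1 alleles at site `k`, in `a`-sorted order.
#' @param k current position (0-based site index).
#' @return list with elements `a` and `d`, valid at position `k + 1`.
#' @export
pbwt_step_divergence <- function(a, d, y, k) {
  M <- length(a)
  if (length(y) != M)
    stop("column has ", length(y), " values, prefix array has ", M)
  if (length(d) != M) stop("divergence array has wrong length")
  y <- as.integer(y)
  if (anyNA(y) || any(y < 0L | y > 1L)) stop("alleles must be 0 or 1")
  a0 <- integer(M); d0 <- integer(M); n0 <- 0L
  a1 <- integer(M); d1 <- integer(M); n1 <- 0L
  p <- k + 1L; q <- k + 1L
  for (i in seq_len(M)) {
    if (d[i] > p) p <- d[i]
    if (d[i] > q) q <- d[i]
    if (y[i] == 0L) {
      n0 <- n0 + 1L; a0[n0] <- a[i]; d0[n0] <- p; p <- 0L
    } else {
      n1 <- n1 + 1L; a1[n1] <- a[i]; d1[n1] <- q; q <- 0L
    }
  }
  list(a = c(a0[seq_len(n0)], a1[seq_len(n1)]),
       d = c(d0[seq_len(n0)], d1[seq_len(n1)]))
}

#' Zero/one rank arrays of a PBWT column
#'
#' For a column of `M` alleles in sorted order, `u[i]` / `v[i]` count the
#' 0 / 1 alleles among the first `i` entries (`i = 0..M`, so both arrays
#' have `M + 1` entries and `u[i] + v[i] == i`); `c = u[M]` is the total
#' number of zeros.  These are the FM-index-style rank values that drive
#' the boundary extension function.
#'
#' @param y integer 0/1 alleles in sorted order.
#' @return list with integer vectors `u`, `v` (length `M + 1`) and scalar
#'   `c`.
#' @export
column_ranks <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || any(y < 0L | y > 1L)) stop("alleles must be 0 or 1")
  v <- c(0L, cumsum(y))
  u <- seq_along(v) - 1L - v
  list(u = u, v = v, c = u[length(u)])
}

#' Boundary extension through one PBWT column
#'
#' Maps a sorted boundary `i` (`0 <= i <= M`) at position `k`, together
#' with an allele, to the corresponding boundary at position `k + 1`:
#' `u[i]` for allele 0 and `c + v[i]` for allele 1.  This is the
#' rank-based extension used to advance query intervals without touching
#' the underlying sequences; it is monotone non-decreasing in `i` for a
#' fixed allele.
#'
#' @param ranks rank arrays for the column, as returned by
#'   [column_ranks()].
#' @param i sorted boundary index, `0..M`.
#' @param allele 0 or 1.
#' @return boundary index at the next position.
#' @export
pbwt_extend <- function(ranks, i, allele) {
  M <- length(ranks$u) - 1L
  if (length(i) != 1L || is.na(i) || i < 0L || i > M)
    stop("boundary index must be in 0..", M)
  if (!allele %in% c(0L, 1L)) stop("allele must be 0 or 1")
  if (allele == 0L) ranks$u[i + 1L] else ranks$c + ranks$v[i + 1L]
}
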