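#' @name matching
#' @title Exact haplotype matching
#'
#' @description
#' All matching functions return a data frame of match records with
#' columns `seq_a`, `seq_b`, `start`, `end`: 0-based sequence indices and
#' a half-open 0-based site interval `[start, end)` on which the two
#' sequences agree, with a mismatch (or the panel boundary) immediately on
#' either side.  For query matching `seq_a` is the 0-based query index and
#' `seq_b` the panel sequence index.  Matches are emitted ordered by
#' ending position, then by sorted-block position; consumers should not
#' rely on more than that.
#'
#' The `naive_*` functions implement the match definitions literally by
#' per-pair scans; they are the correctness reference for the sweep-based
#' algorithms (and the "naive" timing baseline), intended for small
#' inputs.
NULL

stat_fields <- c("count", "n_events", "sum_sites", "sum_bp",
                 "event_sum_sites", "event_sum_bp", "n_ops", "state_ints")

match_frame <- function(r) {
  data.frame(seq_a = r$seq_a, seq_b = r$seq_b, start = r$start,
             end = r$end)
}

panel_positions <- function(panel) {
  if (is.null(panel$sites)) NULL else as.numeric(panel$sites$pos)
}

#' Find all long matches within a panel
#'
#' Reports every locally maximal match between distinct panel sequences
#' of length at least `L` sites, each unordered pair/interval exactly
#' once, via a single forward sweep: at each position the sorted sequences
#' are grouped into blocks whose divergence values stay at or below
#' `k - L`, and matches ending at `k` are read off pairs with different
#' alleles at `k` (matches reaching the end of the panel are flushed at
#' the final boundary).
#'
#' @param panel a [haplotype_panel()].
#' @param L minimum match length in sites, `1 <= L <= N`.
#' @param stats_only if `TRUE`, return only match count and length sums
#'   instead of materialising every record.
#' @return a match data frame (see [matching]); for `stats_only` a list
#'   with `count`, `sum_sites`, `sum_bp` (when site positions are
#'   available) and the instrumentation fields `n_ops`, `state_ints`.
#' @export
long_matches <- function(panel, L, stats_only = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > n_sites(panel))
    stop("L must be between 1 and the number of sites (", n_sites(panel),
         ")")
  r <- cpp_long_matches(panel$alleles, L, !stats_only,
                        panel_positions(panel))
  if (stats_only) r[stat_fields]
  else match_frame(r)
}

#' Find all set-maximal matches within a panel
#'
#' For every target sequence, reports every set-maximal match to the rest
#' of the panel: a locally maximal match not properly contained in any
#' longer match of that sequence.  Matches are directional (each tied
#' partner of a target yields one record), so a pair of identical
#' sequences reports twice, once per target.  The sweep inspects, for
#' each sorted sequence at each position, the contiguous neighbour block
#' achieving the longest match ending there, and reports it when no block
#' member can extend the match.
#'
#' @param panel a [haplotype_panel()] with at least 2 sequences.
#' @param stats_only if `TRUE`, return only counts and length sums.
#' @return a match data frame, or a stats list (see [long_matches()]).
#' @export
set_maximal_matches <- function(panel, stats_only = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_seq(panel) < 2L)
    stop("set-maximal matching needs at least 2 sequences")
  r <- cpp_set_maximal(panel$alleles, !stats_only,
                       panel_positions(panel))
  if (stats_only) r[stat_fields]
  else match_frame(r)
}

#' Set-maximal matches of new query sequences against an indexed panel
#'
#' Sweeps each query through the indexed panel maintaining the triple
#' `(e, f, g)`: the start of the longest current match and the half-open
#' interval of sorted panel positions sharing it.  The interval is
#' advanced through each column by the rank-based boundary extension
#' ([pbwt_extend()]); when it empties, the matches ending there are
#' set-maximal and are reported for every sorted index in `[f, g)`, and
#' the state restarts from whichever sorted neighbour of the query's
#' insertion point matches it furthest back.
#'
#' @param index a [build_index()] result.
#' @param z query alleles: a vector of length `N`, a 0/1 matrix with one
#'   query per row, or a [haplotype_panel()] on the same site list.
#' @return a match data frame with `seq_a` the 0-based query row index.
#' @export
query_set_maximal <- function(index, z) {
  stopifnot(inherits(index, "pbwt_index"))
  M <- index$M; N <- index$N
  Z <- as_query_matrix(z, N)
  X <- decode_panel(index)$alleles # for backward comparisons on restart
  out_a <- integer(0); out_b <- integer(0)
  out_s <- integer(0); out_e <- integer(0)
  for (qi in seq_len(nrow(Z))) {
    zq <- as.integer(Z[qi, ])
    rep_block <- function(a, e, k, f, g) {
      idx <- f:(g - 1L) + 1L
      out_a <<- c(out_a, rep(qi - 1L, g - f))
      out_b <<- c(out_b, a[idx])
      out_s <<- c(out_s, rep(e, g - f))
      out_e <<- c(out_e, rep(k, g - f))
    }
    a <- seq_len(M) - 1L; d <- integer(M)
    e <- 0L; f <- 0L; g <- M
    for (k in seq_len(N) - 1L) {
      y <- as.integer(cpp_rle_decode(index$payloads[[k + 1L]], M))
      rk <- column_ranks(y)
      nxt <- pbwt_step_divergence(a, d, y, k)
      f1 <- pbwt_extend(rk, f, zq[k + 1L])
      g1 <- pbwt_extend(rk, g, zq[k + 1L])
      if (f1 < g1) {
        f <- f1; g <- g1
      } else {
        if (k > e && g > f) rep_block(a, e, k, f, g)
        tt <- f1
        elow <- eup <- k + 1L
        if (tt > 0L) {
          s <- nxt$a[tt] # 0-based id of lower neighbour (sorted tt - 1)
          j <- k
          while (j >= 0L && X[s + 1L, j + 1L] == as.raw(zq[j + 1L]))
            j <- j - 1L
          elow <- j + 1L
        }
        if (tt < M) {
          s <- nxt$a[tt + 1L]
          j <- k
          while (j >= 0L && X[s + 1L, j + 1L] == as.raw(zq[j + 1L]))
            j <- j - 1L
          eup <- j + 1L
        }
        e <- min(elow, eup)
        # the new block spans the neighbour(s) that match z from e,
        # extended while the divergence chain stays at or below e
        f <- g <- tt
        if (tt > 0L && elow <= e) {
          f <- tt - 1L
          while (f > 0L && nxt$d[f + 1L] <= e) f <- f - 1L
        }
        if (tt < M && eup <= e) {
          g <- tt + 1L
          while (g < M && nxt$d[g + 1L] <= e) g <- g + 1L
        }
      }
      a <- nxt$a; d <- nxt$d
    }
    if (N > e && g > f) rep_block(a, e, N, f, g)
  }
  ord <- order(out_e, out_s, out_b)
  data.frame(seq_a = out_a[ord], seq_b = out_b[ord], start = out_s[ord],
             end = out_e[ord])
}

#' Batch query matching by a joint sweep
#'
#' Passes once, jointly, through the panel and the combined set of query
#' sequences, reporting only set-maximal matches of queries to panel
#' sequences (query-query matches are ignored; other queries never mask a
#' panel match).  The output multiset equals running
#' [query_set_maximal()] on each query, but the joint sweep keeps only
#' O(M + Q) working state per position.
#'
#' @param panel a [haplotype_panel()].
#' @param queries query alleles: vector, 0/1 matrix (one query per row)
#'   or [haplotype_panel()] on the same site list.
#' @param stats_only if `TRUE`, return only counts and length sums.
#' @return a match data frame with `seq_a` the 0-based query row index.
#' @export
query_batch <- function(panel, queries, stats_only = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  Z <- as_query_matrix(queries, n_sites(panel))
  if (nrow(Z) == 0L) {
    if (stats_only) return(list(count = 0, n_events = 0, sum_sites = 0,
                                sum_bp = 0, event_sum_sites = 0,
                                event_sum_bp = 0, n_ops = 0,
                                state_ints = 0))
    return(data.frame(seq_a = integer(0), seq_b = integer(0),
                      start = integer(0), end = integer(0)))
  }
  r <- cpp_query_batch(panel$alleles, Z, !stats_only,
                       panel_positions(panel))
  if (stats_only) r[stat_fields]
  else match_frame(r)
}

#' Blocks of sequences identical on a window centered at a site
#'
#' At sweep position `k + half_length`, groups the sorted sequences into
#' maximal blocks whose internal divergence values are at most
#' `k - half_length`: the members of a block are pairwise identical on
#' the centered window `[k - half_length, k + half_length)`.  Unlike the
#' long-match sweep there is no split by the current allele, and
#' singleton blocks are reported too.
#'
#' @param index a [build_index()] result.
#' @param k center site, `half_length <= k <= N - half_length`.
#' @param half_length window half-length in sites (L/2 for windows of
#'   total length L).
#' @return list of blocks, each a list with `start`, `end` (the window,
#'   half-open) and `members` (0-based sequence indices).
#' @export
centered_blocks <- function(index, k, half_length) {
  stopifnot(inherits(index, "pbwt_index"))
  L2 <- as.integer(half_length); k <- as.integer(k)
  if (is.na(L2) || L2 < 1L) stop("half_length must be >= 1")
  if (is.na(k) || k < L2 || k > index$N - L2)
    stop("need half_length <= k <= N - half_length")
  st <- state_at(index, k + L2)
  thresh <- k - L2
  out <- list()
  bs <- 1L
  for (i in seq_len(index$M + 1L)) {
    if (i > index$M || (i > 1L && st$d[i] > thresh)) {
      out[[length(out) + 1L]] <-
        list(start = thresh, end = k + L2,
             members = sort(st$a[bs:(i - 1L)]))
      bs <- i
    }
  }
  out
}

# naive reference implementations -------------------------------------------

# locally maximal agreement intervals between two 0/1 integer vectors
maximal_agreements <- function(u, v) {
  agree <- u == v
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep] - 1L, end = ends[keep]) # 0-based half-open
}

#' @rdname matching
#' @param panel a [haplotype_panel()].
#' @param L minimum length in sites.
#' @export
naive_long_matches <- function(panel, L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > n_sites(panel))
    stop("L must be between 1 and the number of sites")
  X <- allele_matrix(panel)
  M <- nrow(X)
  out <- list()
  for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
    iv <- maximal_agreements(X[i, ], X[j, ])
    iv <- iv[iv[, 2] - iv[, 1] >= L, , drop = FALSE]
    if (nrow(iv))
      out[[length(out) + 1L]] <-
        data.frame(seq_a = i - 1L, seq_b = j - 1L, start = iv[, 1],
                   end = iv[, 2])
  }
  rbind_matches(out)
}

#' @rdname matching
#' @export
naive_set_maximal <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_seq(panel) < 2L)
    stop("set-maximal matching needs at least 2 sequences")
  X <- allele_matrix(panel)
  M <- nrow(X)
  out <- list()
  for (i in seq_len(M)) {
    cand <- list()
    for (j in seq_len(M)) {
      if (j == i) next
      iv <- maximal_agreements(X[i, ], X[j, ])
      if (nrow(iv))
        cand[[length(cand) + 1L]] <-
          data.frame(seq_b = j - 1L, start = iv[, 1], end = iv[, 2])
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand)) next
    len <- cand$end - cand$start
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      !any(cand$start <= cand$start[r] & cand$end >= cand$end[r] &
             len > len[r])
    }, TRUE)
    if (any(keep))
      out[[length(out) + 1L]] <-
        data.frame(seq_a = i - 1L, cand[keep, , drop = FALSE])
  }
  rbind_matches(out)
}

#' @rdname matching
#' @param z query alleles (vector, matrix with one query per row, or
#'   panel).
#' @export
naive_query <- function(panel, z) {
  stopifnot(inherits(panel, "haplotype_panel"))
  Z <- as_query_matrix(z, n_sites(panel))
  X <- allele_matrix(panel)
  out <- list()
  for (qi in seq_len(nrow(Z))) {
    zq <- as.integer(Z[qi, ])
    cand <- list()
    for (j in seq_len(nrow(X))) {
      iv <- maximal_agreements(zq, X[j, ])
      if (nrow(iv))
        cand[[length(cand) + 1L]] <-
          data.frame(seq_b = j - 1L, start = iv[, 1], end = iv[, 2])
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand)) next
    len <- cand$end - cand$start
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      !any(cand$start <= cand$start[r] & cand$end >= cand$end[r] &
             len > len[r])
    }, TRUE)
    if (any(keep))
      out[[length(out) + 1L]] <-
        data.frame(seq_a = qi - 1L, cand[keep, , drop = FALSE])
  }
  rbind_matches(out)
}

rbind_matches <- function(lst) {
  if (!length(lst))
    return(data.frame(seq_a = integer(0), seq_b = integer(0),
                      start = integer(0), end = integer(0)))
  m <- do.call(rbind, lst)
  m <- m[, c("seq_a", "seq_b", "start", "end")]
  m <- m[order(m$end, m$start, m$seq_a, m$seq_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}
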