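#' Build a run-length-compressed PBWT index of a panel
#'
#' Performs a single O(NM) forward sweep over the panel, producing for
#' every site the PBWT column (the alleles at that site in reversed-prefix
#' sorted order) as a canonical run-length byte payload together with its
#' zero count, and storing full prefix (`a`) and divergence (`d`) array
#' snapshots every `checkpoint_interval` positions (always including
#' positions 0 and N).  The index is lossless: [decode_panel()] inverts
#' it exactly, and [state_at()] reconstructs the sweep state at any
#' position by replaying at most `checkpoint_interval` columns from the
#' nearest checkpoint.
#'
#' @param panel a [haplotype_panel()].
#' @param checkpoint_interval positions between stored `a`/`d` snapshots
#'   (default 64).
#' @return an object of class `pbwt_index`.
#' @examples
#' p <- haplotype_panel(matrix(rbinom(80, 1, 0.4), nrow = 8))
#' idx <- build_index(p)
#' idx
#' @export
build_index <- function(panel, checkpoint_interval = 64L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  C <- as.integer(checkpoint_interval)
  if (is.na(C) || C < 1L) stop("checkpoint_interval must be >= 1")
  M <- n_seq(panel); N <- n_sites(panel)
  if (M == 0L || N == 0L) {
    return(structure(list(M = M, N = N, sites = panel$sites,
                          sample_names = panel$sample_names,
                          payloads = vector("list", N),
                          c = integer(N), C = C,
                          cp_pos = 0L,
                          cp_a = list(seq_len(M) - 1L),
                          cp_d = list(integer(M)),
                          n_ops = 0),
                     class = "pbwt_index"))
  }
  r <- cpp_build_index(panel$alleles, C)
  structure(list(M = M, N = N, sites = panel$sites,
                 sample_names = panel$sample_names,
                 payloads = r$payloads, c = r$c, C = C,
                 cp_pos = r$cp_pos, cp_a = r$cp_a, cp_d = r$cp_d,
                 n_ops = r$n_ops),
            class = "pbwt_index")
}

#' @export
print.pbwt_index <- function(x, ...) {
  pb <- sum(vapply(x$payloads, length, 1L))
  cat("pbwt_index: ", x$M, " haplotypes x ", x$N, " sites\n",
      "  payload ", pb, " bytes (",
      if (x$N > 0) signif(pb / x$N, 3) else 0, " bytes/site), ",
      length(x$cp_pos), " checkpoints every ", x$C, " sites\n", sep = "")
  invisible(x)
}

#' Reconstruct the sweep state at an arbitrary position
#'
#' Returns the positional prefix array `a` and divergence array `d` at
#' position `k` (0-based; `k = N` gives the final boundary), equal to the
#' values an uninterrupted sweep would produce.  The state is taken from
#' the nearest checkpoint at or before `k` and advanced by replaying the
#' stored columns with [pbwt_step_divergence()].  When `k < N` the rank
#' arrays of column `k` are included.
#'
#' @param index a [build_index()] result.
#' @param k position in `0..N`.
#' @return list of class `pbwt_state` with elements `k`, `a`, `d` and,
#'   for `k < N`, `y`, `u`, `v`, `c`.
#' @export
state_at <- function(index, k) {
  stopifnot(inherits(index, "pbwt_index"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > index$N)
    stop("position must be in 0..", index$N)
  icp <- findInterval(k, index$cp_pos)
  a <- as.integer(index$cp_a[[icp]])
  d <- as.integer(index$cp_d[[icp]])
  j <- index$cp_pos[icp]
  while (j < k) {
    y <- as.integer(cpp_rle_decode(index$payloads[[j + 1L]], index$M))
    st <- pbwt_step_divergence(a, d, y, j)
    a <- st$a; d <- st$d
    j <- j + 1L
  }
  out <- list(k = k, a = a, d = d)
  if (k < index$N) {
    y <- as.integer(cpp_rle_decode(index$payloads[[k + 1L]], index$M))
    out$y <- y
    out[c("u", "v", "c")] <- column_ranks(y)
  }
  structure(out, class = "pbwt_state")
}

#' @export
print.pbwt_state <- function(x, ...) {
  cat("pbwt_state at k = ", x$k, " (M = ", length(x$a), ")\n", sep = "")
  invisible(x)
}

#' Invert a PBWT index back to the original panel
#'
#' Decodes every column and scatters it through the running prefix
#' permutation, reproducing the encoded panel exactly.
#'
#' @param index a [build_index()] or [read_pbwt()] result.
#' @return a [haplotype_panel()] identical to the one encoded.
#' @export
decode_panel <- function(index) {
  stopifnot(inherits(index, "pbwt_index"))
  M <- index$M; N <- index$N
  X <- matrix(as.raw(0L), nrow = M, ncol = N)
  if (M == 0L || N == 0L)
    return(haplotype_panel(X, sites = index$sites,
                           sample_names = index$sample_names))
  a <- seq_len(M) - 1L
  for (k in seq_len(N)) {
    y <- tryCatch(cpp_rle_decode(index$payloads[[k]], M),
                  error = function(e)
                    stop("corrupt payload for column ", k - 1L, ": ",
                         conditionMessage(e), call. = FALSE))
    yi <- as.integer(y)
    if (sum(yi == 0L) != index$c[k])
      stop("corrupt payload for column ", k - 1L,
           ": zero count does not match stored c")
    X[a + 1L, k] <- y
    a <- c(a[yi == 0L], a[yi == 1L])
  }
  haplotype_panel(X, sites = index$sites,
                  sample_names = index$sample_names)
}

#' Storage accounting for a PBWT index
#'
#' Reports the run-length payload size, checkpoint and site-table
#' overheads, and bytes per site, optionally against a gzip baseline of
#' the raw sequence-major 0/1 text of the same panel (the dialect written
#' by [write_matrix_text()], compressed at the default gzip level).
#' Payload and total container bytes are reported separately.
#'
#' @param index a [build_index()] result.
#' @param panel optional [haplotype_panel()]; when supplied, the gzip
#'   baseline is measured on its raw text rendering.
#' @return list of class `pbwt_size_stats`.
#' @export
size_stats <- function(index, panel = NULL) {
  stopifnot(inherits(index, "pbwt_index"))
  payload <- sum(vapply(index$payloads, length, 1L))
  ncp <- length(index$cp_pos)
  cp_bytes <- ncp * (4 + 8L * index$M)
  out <- list(M = index$M, N = index$N,
              payload_bytes = payload,
              checkpoint_bytes = cp_bytes,
              total_bytes = payload + cp_bytes,
              bytes_per_site = if (index$N > 0) payload / index$N else 0)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "haplotype_panel"))
    txt <- cpp_matrix_text(panel$alleles)
    out$raw_text_bytes <- length(txt)
    out$gzip_bytes <- length(memCompress(txt, "gzip"))
    out$gzip_ratio <- out$gzip_bytes / max(1, out$payload_bytes)
  }
  structure(out, class = "pbwt_size_stats")
}

#' @export
print.pbwt_size_stats <- function(x, ...) {
  cat("PBWT storage for ", x$M, " x ", x$N, " panel\n",
      "  column payloads: ", x$payload_bytes, " bytes (",
      signif(x$bytes_per_site, 3), " bytes/site)\n",
      "  checkpoints:     ", x$checkpoint_bytes, " bytes\n",
      "  total:           ", x$total_bytes, " bytes\n", sep = "")
  if (!is.null(x$gzip_bytes))
    cat("  gzip of raw text: ", x$gzip_bytes, " bytes (gzip/PBWT payload = ",
        signif(x$gzip_ratio, 3), ")\n", sep = "")
  invisible(x)
}
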