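#' Phased binary haplotype panel
#'
#' A haplotype panel holds `M` phased haplotype sequences over `N` ordered
#' bi-allelic sites, with alleles coded 0 (reference) and 1 (alternate).
#' Internally the alleles are a raw `M x N` matrix (one byte per allele),
#' which keeps even large simulated panels affordable in memory.  Missing
#' or multi-allelic values are rejected at construction: exact matching is
#' the premise of every algorithm in this package.
#'
#' Sequence indices in match records produced from a panel are 0-based,
#' matching the on-disk match dialect; R-level subsetting with `[` uses the
#' usual 1-based R conventions.
#'
#' @param alleles matrix of 0/1 values (integer, numeric, logical or raw),
#'   haplotypes in rows, sites in columns.
#' @param sites optional data frame describing the sites, with columns
#'   `chrom`, `pos` (base-pair coordinate, strictly increasing within a
#'   chromosome) and optionally `ref`, `alt`.
#' @param sample_names optional character vector of haplotype labels, one
#'   per row (two haplotypes per diploid sample).
#' @return an object of class `haplotype_panel` with elements `alleles`
#'   (raw matrix), `sites` and `sample_names`.
#' @examples
#' p <- haplotype_panel(rbind(c(0, 1, 0, 1),
#'                            c(1, 1, 0, 0),
#'                            c(0, 0, 1, 0),
#'                            c(1, 1, 0, 1)))
#' p
#' @export
haplotype_panel <- function(alleles, sites = NULL, sample_names = NULL) {
  if (!is.matrix(alleles))
    stop("'alleles' must be a matrix")
  if (is.raw(alleles)) {
    x <- alleles
    if (length(x) && cpp_max_byte(x) > 1L)
      stop("alleles must be 0 or 1; found value ", cpp_max_byte(x))
  } else {
    v <- as.integer(alleles)
    if (anyNA(v))
      stop("missing allele values are not representable in a haplotype panel")
    if (length(v) && (min(v) < 0L || max(v) > 1L))
      stop("alleles must be 0 or 1; found value ", v[v < 0L | v > 1L][1])
    x <- as.raw(v)
    dim(x) <- dim(alleles)
  }
  dimnames(x) <- NULL
  M <- nrow(x); N <- ncol(x)
  if (!is.null(sites)) {
    sites <- as.data.frame(sites)
    if (nrow(sites) != N)
      stop("site table has ", nrow(sites), " rows but the panel has ", N,
           " sites")
    if (is.null(sites$pos))
      stop("site table must have a 'pos' column")
    if (is.null(sites$chrom)) sites$chrom <- "0"
    for (ch in unique(sites$chrom)) {
      p <- sites$pos[sites$chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0))
        stop("site positions must be strictly increasing within chromosome ",
             ch)
    }
  }
  if (!is.null(sample_names)) {
    sample_names <- as.character(sample_names)
    if (length(sample_names) != M)
      stop("need one sample_name per haplotype row")
  }
  structure(list(alleles = x, sites = sites, sample_names = sample_names),
            class = "haplotype_panel")
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

#' Number of haplotype sequences in a panel
#' @param panel a [haplotype_panel()]
#' @return integer count
#' @export
n_seq <- function(panel) nrow(panel$alleles)

#' Number of sites in a panel
#' @param panel a [haplotype_panel()]
#' @return integer count
#' @export
n_sites <- function(panel) ncol(panel$alleles)

#' Allele matrix of a panel as integers
#' @param panel a [haplotype_panel()]
#' @return integer M x N matrix of 0/1
#' @export
allele_matrix <- function(panel) {
  x <- as.integer(panel$alleles)
  dim(x) <- dim(panel$alleles)
  x
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel: ", n_seq(x), " haplotypes x ", n_sites(x),
      " bi-allelic sites\n", sep = "")
  if (!is.null(x$sites))
    cat("  positions ", format(min(x$sites$pos), big.mark = ","), " .. ",
        format(max(x$sites$pos), big.mark = ","), " on ",
        length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  if (!is.null(x$sample_names))
    cat("  haplotypes: ", x$sample_names[1],
        if (n_seq(x) > 1) paste0(" ... ", x$sample_names[n_seq(x)]), "\n",
        sep = "")
  if (n_sites(x) > 0) {
    f <- as.integer(cpp_col_ones(x$alleles)) / max(1L, n_seq(x))
    cat("  mean alt-allele frequency ", signif(mean(f), 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
`[.haplotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_seq(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  haplotype_panel(x$alleles[i, j, drop = FALSE],
                  sites = if (!is.null(x$sites)) x$sites[j, , drop = FALSE],
                  sample_names = if (!is.null(x$sample_names))
                    x$sample_names[i])
}

# internal: coerce a query vector/matrix to a raw matrix with N columns
as_query_matrix <- function(z, N) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (inherits(z, "haplotype_panel")) z <- z$alleles
  if (ncol(z) != N)
    stop("query has ", ncol(z), " sites, panel has ", N)
  if (is.raw(z)) return(z)
  v <- as.integer(z)
  if (anyNA(v) || any(v < 0L | v > 1L))
    stop("query alleles must be 0 or 1")
  out <- as.raw(v)
  dim(out) <- dim(z)
  out
}
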