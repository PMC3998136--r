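#' Read a phased VCF into a haplotype panel
#'
#' Loads phased, bi-allelic SNVs from a VCF and returns two haplotype
#' rows per diploid sample, in sample order, labelled `<sample>_h1` /
#' `<sample>_h2` (order within the GT field defines h1/h2).
#' Multi-allelic and non-SNV records are skipped with a message; unphased
#' or missing genotypes abort by default, because exact matching assumes
#' complete phased data.
#'
#' @param source path to a VCF (optionally gzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction
#'   (1-based, inclusive).
#' @param drop_unphased if `TRUE`, drop sites containing unphased or
#'   missing genotypes instead of failing.
#' @return a [haplotype_panel()] with a populated site table.
#' @export
read_vcf <- function(source, region = NULL, drop_unphased = FALSE) {
  vcf <- vcfR::read.vcfR(source, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in '", source, "'")
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  nskip <- sum(!keep)
  if (nskip > 0)
    message("skipping ", nskip, " multi-allelic or non-SNV record(s)")
  if (!is.null(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(m)) stop("malformed region '", region, "'")
    keep <- keep & fix$CHROM == m[2]
    if (m[3] != "") {
      pos <- as.numeric(fix$POS)
      keep <- keep & pos >= as.numeric(m[3]) & pos <= as.numeric(m[4])
    }
  }
  if (!any(keep)) stop("no bi-allelic SNV records retained")
  gt <- vcfR::extract.gt(vcf, "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("no samples with GT in '",
                                          source, "'")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)
  ok <- grepl("^[01]\\|[01]$", gt)
  dim(ok) <- dim(gt)
  if (!all(ok)) {
    if (drop_unphased) {
      bad <- apply(ok, 1, function(r) !all(r))
      message("dropping ", sum(bad),
              " site(s) with unphased or missing genotypes")
      gt <- gt[!bad, , drop = FALSE]
      fix <- fix[!bad, , drop = FALSE]
      if (nrow(gt) == 0L) stop("no fully phased sites left")
    } else {
      w <- which(!ok, arr.ind = TRUE)[1, ]
      stop("unphased or missing genotype '", gt[w[1], w[2]],
           "' at ", fix$CHROM[w[1]], ":", fix$POS[w[1]], " sample ",
           samples[w[2]], " (use drop_unphased = TRUE to drop such sites)")
    }
  }
  h1 <- substr(gt, 1L, 1L) == "1"
  h2 <- substr(gt, 3L, 3L) == "1"
  N <- nrow(gt); S <- length(samples)
  X <- matrix(as.raw(0L), nrow = 2L * S, ncol = N)
  X[seq(1L, 2L * S, by = 2L), ] <- as.raw(t(h1))
  X[seq(2L, 2L * S, by = 2L), ] <- as.raw(t(h2))
  haplotype_panel(
    X,
    sites = data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                       ref = fix$REF, alt = fix$ALT,
                       stringsAsFactors = FALSE),
    sample_names = paste0(rep(samples, each = 2L), "_h",
                          rep(1:2, times = S)))
}

#' Read a site-major 0/1 text panel
#'
#' One line per site: optional leading fields, of which the last numeric
#' one before the allele string is taken as the site position, followed by
#' `M` contiguous characters in `{0,1}` (the MaCS-style dialect).  Other
#' leading fields are ignored.
#'
#' @param source file path.
#' @return a [haplotype_panel()]; a site table is attached when positions
#'   were present.
#' @export
read_sitemajor_text <- function(source) {
  r <- cpp_read_sitemajor(path.expand(source))
  sites <- NULL
  if (length(r$pos)) {
    if (anyNA(r$pos))
      stop("some site lines carry positions and others do not")
    sites <- data.frame(chrom = "0", pos = r$pos, ref = "0", alt = "1",
                        stringsAsFactors = FALSE)
  }
  haplotype_panel(r$X, sites = sites)
}

#' Read a sequence-major 0/1 text panel
#'
#' One line of `N` characters per haplotype sequence -- the raw-text
#' dialect used as the gzip compression baseline.
#'
#' @param source file path.
#' @return a [haplotype_panel()].
#' @export
read_matrix_text <- function(source) {
  lines <- readLines(source)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no haplotype data found in '", source, "'")
  n <- unique(nchar(lines))
  if (length(n) != 1L)
    stop("ragged sequence lines: lengths ", paste(n, collapse = ", "))
  bad <- grep("[^01]", lines)
  if (length(bad))
    stop("illegal character on line ", bad[1])
  X <- matrix(as.raw(0L), nrow = length(lines), ncol = n)
  for (i in seq_along(lines))
    X[i, ] <- as.raw(utf8ToInt(lines[i]) - utf8ToInt("0"))
  haplotype_panel(X)
}

#' Write a panel as sequence-major 0/1 text
#'
#' Emits one line of `N` characters per haplotype (UTF-8, LF line
#' endings): the exact dialect measured by the gzip baseline in
#' [size_stats()].
#'
#' @param panel a [haplotype_panel()].
#' @param destination file path.
#' @return `destination`, invisibly.
#' @export
write_matrix_text <- function(panel, destination) {
  stopifnot(inherits(panel, "haplotype_panel"))
  writeBin(cpp_matrix_text(panel$alleles), destination)
  invisible(destination)
}

#' Site filtering specification
#'
#' Describes the thinning used to emulate genotyping-array data from
#' sequence-density panels: among sites whose minor-allele frequency
#' exceeds `min_maf`, a random fraction `keep_fraction` is retained.
#'
#' @param keep_fraction proportion of passing sites kept, in (0, 1].
#' @param min_maf minor-allele frequency threshold, in \[0, 0.5).
#' @param seed optional integer sampling seed (the caller's RNG state is
#'   left untouched).
#' @return an object of class `site_filter_spec`.
#' @export
site_filter_spec <- function(keep_fraction = 1, min_maf = 0, seed = NULL) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 ||
      keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf >= 0.5)
    stop("min_maf must be in [0, 0.5)")
  structure(list(keep_fraction = keep_fraction, min_maf = min_maf,
                 seed = seed),
            class = "site_filter_spec")
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Thin a panel's sites by frequency and random subsampling
#'
#' Keeps each site whose minor-allele frequency (computed on the loaded
#' panel) exceeds `spec$min_maf` with probability `spec$keep_fraction`,
#' preserving site order.  Reproducible for a fixed `spec$seed` and
#' independent of sequence order.
#'
#' @param panel a [haplotype_panel()].
#' @param spec a [site_filter_spec()].
#' @return the filtered [haplotype_panel()] (possibly with zero sites).
#' @export
filter_sites <- function(panel, spec) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(spec, "site_filter_spec"))
  M <- n_seq(panel)
  f <- as.integer(cpp_col_ones(panel$alleles)) / max(1L, M)
  maf <- pmin(f, 1 - f)
  pass <- maf > spec$min_maf
  keep <- pass & with_seed(spec$seed,
                           stats::runif(n_sites(panel)) <
                             spec$keep_fraction)
  panel[, which(keep)]
}

#' Write match records as tab-separated text
#'
#' The shared dialect for every match class: tab-separated
#' `seq_a seq_b start end` (0-based indices, half-open interval), one
#' line per match, in the order produced.  With `labels`, sequence
#' indices are replaced by the corresponding haplotype labels.
#'
#' @param matches a match data frame (see [matching]).
#' @param destination file path.
#' @param labels optional character vector of haplotype labels indexed by
#'   `seq + 1`; applied to `seq_b` always and to `seq_a` when in range.
#' @param header write a header line (default `FALSE`).
#' @return `destination`, invisibly.
#' @export
write_matches <- function(matches, destination, labels = NULL,
                          header = FALSE) {
  m <- matches
  if (!is.null(labels)) {
    lab <- function(idx) {
      bad <- is.na(idx) | idx < 0 | idx >= length(labels)
      if (any(bad))
        stop("unknown label index ", idx[bad][1])
      labels[idx + 1]
    }
    m$seq_a <- lab(m$seq_a)
    m$seq_b <- lab(m$seq_b)
  }
  con <- file(destination, "wb") # LF endings on every platform
  on.exit(close(con))
  if (header)
    writeLines("seq_a\tseq_b\tstart\tend", con)
  if (nrow(m))
    writeLines(paste(m$seq_a, m$seq_b, m$start, m$end, sep = "\t"), con)
  invisible(destination)
}
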