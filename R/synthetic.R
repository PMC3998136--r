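#' Parameters of the built-in copying-model panel simulator
#'
#' The built-in generator is a Li--Stephens-style copying mosaic: a small
#' set of founder haplotypes is drawn first, and every subsequent
#' haplotype copies an already-generated one left to right, switching
#' template at a per-site rate and flipping the copied allele at a
#' per-site mutation rate.  Template switching produces the local
#' haplotype sharing (linkage disequilibrium) that makes PBWT columns
#' run-length compressible; the mutation rate controls how quickly exact
#' matches break up.
#'
#' Defaults model a densely genotyped population sample: 10 founders,
#' a 1% per-site switch rate (LD blocks of about a hundred sites), a
#' 0.2% per-site flip rate, and exponentially spaced sites averaging
#' 100 bp apart.
#'
#' @param M number of haplotypes.
#' @param N number of sites.
#' @param founders number of independent founder haplotypes
#'   (`<= M`; default 10, reduced to `M` for small panels).
#' @param switch_rate per-site probability of changing copy template.
#' @param mut_rate per-site probability of flipping the copied allele.
#' @param site_spacing mean base pairs between adjacent sites.
#' @param seed integer generator seed; panels are byte-identical across
#'   runs for a fixed seed.
#' @return an object of class `copying_model_params`.
#' @export
copying_model_params <- function(M, N, founders = NULL,
                                 switch_rate = 0.01, mut_rate = 0.002,
                                 site_spacing = 100, seed = 1L) {
  M <- as.integer(M); N <- as.integer(N)
  founders <- as.integer(if (is.null(founders)) min(10L, M) else founders)
  if (is.na(M) || M < 1L || is.na(N) || N < 1L)
    stop("M and N must be positive")
  if (is.na(founders) || founders < 1L || founders > M)
    stop("founders must be in 1..M")
  for (r in c(switch_rate, mut_rate))
    if (!is.numeric(r) || r < 0 || r > 1)
      stop("rates must be in [0, 1]")
  if (!is.numeric(site_spacing) || site_spacing <= 0)
    stop("site_spacing must be positive")
  structure(list(M = M, N = N, founders = founders,
                 switch_rate = switch_rate, mut_rate = mut_rate,
                 site_spacing = site_spacing, seed = as.integer(seed)),
            class = "copying_model_params")
}

#' Simulate an LD-structured haplotype panel
#'
#' Draws founder haplotypes with per-site alternate-allele frequencies
#' from a discretised neutral-like spectrum (derived-allele count `j`
#' among founders weighted proportional to `1/j`), then generates each
#' further haplotype as a copying mosaic of the previously generated ones
#' (see [copying_model_params()]).  Site positions are cumulative
#' exponential gaps with the requested mean spacing, rounded up to keep
#' them strictly increasing.
#'
#' @param params a [copying_model_params()].
#' @return a [haplotype_panel()] with a site table.
#' @export
simulate_copying_panel <- function(params) {
  stopifnot(inherits(params, "copying_model_params"))
  p <- params
  with_seed(p$seed, {
    X <- matrix(0L, nrow = p$M, ncol = p$N)
    K <- p$founders
    if (K == 1L) {
      X[1L, ] <- stats::rbinom(p$N, 1L, 0.5)
    } else {
      w <- 1 / seq_len(K - 1L)
      cnt <- sample(K - 1L, p$N, replace = TRUE, prob = w / sum(w))
      for (k in seq_len(p$N))
        X[sample(K, cnt[k]), k] <- 1L
    }
    if (p$M > K) {
      for (i in (K + 1L):p$M) {
        # segments between template switches copy from a single source
        sw <- stats::runif(p$N) < p$switch_rate
        seg <- cumsum(sw) + 1L
        tpl <- sample.int(i - 1L, max(seg), replace = TRUE)
        X[i, ] <- X[cbind(tpl[seg], seq_len(p$N))]
        fl <- stats::runif(p$N) < p$mut_rate
        X[i, fl] <- 1L - X[i, fl]
      }
    }
    gaps <- ceiling(stats::rexp(p$N, rate = 1 / p$site_spacing))
    pos <- cumsum(pmax(1, gaps))
    haplotype_panel(X, sites = data.frame(chrom = "sim", pos = pos,
                                          ref = "0", alt = "1",
                                          stringsAsFactors = FALSE))
  })
}

#' Overwrite an interval with a donor's alleles
#'
#' Copies the donor haplotype's alleles over `[start, end)` (0-based,
#' half-open) in every member sequence, guaranteeing a known shared
#' segment -- the standard way to build planted-match fixtures.
#'
#' @param panel a [haplotype_panel()].
#' @param members 0-based sequence indices to overwrite.
#' @param interval length-2 vector `c(start, end)`, 0-based half-open,
#'   within `[0, N)`.
#' @param donor 0-based index of the donor sequence.
#' @return a modified copy of the panel.
#' @export
plant_shared_segment <- function(panel, members, interval, donor) {
  stopifnot(inherits(panel, "haplotype_panel"))
  N <- n_sites(panel); M <- n_seq(panel)
  members <- as.integer(members); donor <- as.integer(donor)
  if (length(interval) != 2L || interval[1] < 0L || interval[2] > N ||
      interval[1] >= interval[2])
    stop("interval must be half-open within [0, ", N, ")")
  if (anyNA(members) || any(members < 0L | members >= M) ||
      is.na(donor) || donor < 0L || donor >= M)
    stop("sequence indices must be in 0..", M - 1L)
  cols <- (interval[1] + 1L):interval[2]
  x <- panel$alleles
  for (m in setdiff(members, donor))
    x[m + 1L, cols] <- x[donor + 1L, cols]
  haplotype_panel(x, sites = panel$sites,
                  sample_names = panel$sample_names)
}

#' Load coalescent-simulator output as a haplotype panel
#'
#' Adapter for site-major 0/1 text written by a sequentially Markovian or
#' exact coalescent simulator.  The canonical acceptance configuration is
#' a 20 Mb region with scaled mutation and recombination rates of 0.001
#' per base pair; any simulator producing site-major text with positions
#' can be used.  Positions on a unit interval (all in `[0, 1]`, as some
#' simulators emit) are rescaled to base pairs over `region_length`.
#'
#' @param source path to site-major text output.
#' @param region_length region length in base pairs used for unit-interval
#'   rescaling (default 2e7).
#' @return a [haplotype_panel()].
#' @export
coalescent_panel_adapter <- function(source, region_length = 2e7) {
  panel <- read_sitemajor_text(source)
  if (n_sites(panel) == 0L)
    stop("empty simulation output in '", source, "'")
  if (!is.null(panel$sites) && all(panel$sites$pos >= 0) &&
      max(panel$sites$pos) <= 1) {
    panel$sites$pos <- panel$sites$pos * region_length
    if (any(diff(panel$sites$pos) <= 0))
      stop("rescaled positions are not strictly increasing")
  }
  panel
}
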