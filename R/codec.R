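#' Run-length encode one PBWT column
#'
#' Encodes a binary column as single-byte tokens: bit 7 carries the allele
#' value, bits 6--5 select the run unit (1, 64 or 2048; the fourth code is
#' reserved), bits 4--0 give the unit count (1..31).  Each maximal run is
#' decomposed greedily, largest unit first, so the encoding is canonical:
#' a run of 200 zeros becomes `0x23 0x08` (3 x 64 + 8 x 1) and a run of
#' 1000 zeros `0x2F 0x1F 0x09` (15 x 64 + 31 x 1 + 9 x 1).
#'
#' @param column integer or raw vector of 0/1 alleles.
#' @return raw payload vector.
#' @export
rle_encode <- function(column) {
  if (!is.raw(column)) {
    v <- as.integer(column)
    if (anyNA(v) || any(v < 0L | v > 1L)) stop("alleles must be 0 or 1")
    column <- as.raw(v)
  }
  cpp_rle_encode(column)
}

#' Decode a run-length payload back to a column
#'
#' Exact inverse of [rle_encode()].  The decoded length must equal `M`;
#' payloads containing the reserved unit code, a zero count, or runs that
#' over- or under-shoot `M` raise an error rather than returning a
#' corrupted column.
#'
#' @param payload raw vector produced by [rle_encode()].
#' @param M expected column length.
#' @return integer vector of 0/1 alleles, length `M`.
#' @export
rle_decode <- function(payload, M) {
  as.integer(cpp_rle_decode(as.raw(payload), M))
}

# container format ----------------------------------------------------------
#
# magic "PBWT1" (5 bytes), then a little-endian header of four uint32:
# M, N, checkpoint interval C, flags (bit 0: site table present, bit 1:
# divergence checkpoints present).  The body holds the site table, N column
# records (uint32 c_k, uint32 payload length, payload bytes), the
# checkpoint block (uint32 count, then per checkpoint uint32 position,
# M x int32 a and, if flagged, M x int32 d), and a trailing CRC-32 of the
# whole body.

pbwt_magic <- function() charToRaw("PBWT1")

#' Write a PBWT index to its binary container
#'
#' @param index a [build_index()] result.
#' @param destination file path.
#' @return `destination`, invisibly.
#' @seealso [read_pbwt()]
#' @export
write_pbwt <- function(index, destination) {
  stopifnot(inherits(index, "pbwt_index"))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  has_sites <- !is.null(index$sites)
  if (has_sites) {
    st <- index$sites
    writeBin(as.integer(nrow(st)), con, size = 4, endian = "little")
    chrom <- as.character(st$chrom)
    ref <- if (is.null(st$ref)) rep("0", nrow(st)) else as.character(st$ref)
    alt <- if (is.null(st$alt)) rep("1", nrow(st)) else as.character(st$alt)
    for (i in seq_len(nrow(st))) {
      for (s in c(chrom[i], ref[i], alt[i])) {
        b <- charToRaw(s)
        writeBin(length(b), con, size = 4, endian = "little")
        writeBin(b, con)
      }
      writeBin(as.double(st$pos[i]), con, size = 8, endian = "little")
    }
  }
  for (k in seq_len(index$N)) {
    pl <- index$payloads[[k]]
    writeBin(as.integer(index$c[k]), con, size = 4, endian = "little")
    writeBin(length(pl), con, size = 4, endian = "little")
    writeBin(pl, con)
  }
  writeBin(length(index$cp_pos), con, size = 4, endian = "little")
  for (i in seq_along(index$cp_pos)) {
    writeBin(as.integer(index$cp_pos[i]), con, size = 4, endian = "little")
    writeBin(as.integer(index$cp_a[[i]]), con, size = 4, endian = "little")
    writeBin(as.integer(index$cp_d[[i]]), con, size = 4, endian = "little")
  }
  body <- rawConnectionValue(con)
  out <- file(destination, "wb")
  on.exit(close(out), add = TRUE)
  writeBin(pbwt_magic(), out)
  writeBin(as.integer(c(index$M, index$N, index$C,
                        bitwOr(as.integer(has_sites), 2L))),
           out, size = 4, endian = "little")
  writeBin(body, out)
  writeBin(cpp_crc32(body), out, size = 4, endian = "little")
  invisible(destination)
}

#' Read a PBWT index from its binary container
#'
#' Validates the magic bytes and the trailing CRC-32 before parsing;
#' `read_pbwt(write_pbwt(x))` reproduces `x` bit-exactly.
#'
#' @param source file path.
#' @return a `pbwt_index`.
#' @export
read_pbwt <- function(source) {
  sz <- file.size(source)
  if (is.na(sz) || sz < 25)
    stop("'", source, "' is not a PBWT container (too short)")
  con <- file(source, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 5)
  if (!identical(magic, pbwt_magic()))
    stop("'", source, "' is not a PBWT container, or is an unsupported ",
         "version (bad magic)")
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  M <- hdr[1]; N <- hdr[2]; C <- hdr[3]; flags <- hdr[4]
  body <- readBin(con, "raw", sz - 21 - 4)
  crc <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(crc) != 1 || crc != cpp_crc32(body))
    stop("checksum failure reading '", source, "'")
  bc <- rawConnection(body, "rb")
  on.exit(close(bc), add = TRUE)
  rd_int <- function(n) readBin(bc, "integer", n, size = 4, endian = "little")
  sites <- NULL
  if (bitwAnd(flags, 1L)) {
    ns <- rd_int(1)
    chrom <- character(ns); ref <- character(ns); alt <- character(ns)
    pos <- numeric(ns)
    for (i in seq_len(ns)) {
      s <- character(3)
      for (j in 1:3) s[j] <- rawToChar(readBin(bc, "raw", rd_int(1)))
      chrom[i] <- s[1]; ref[i] <- s[2]; alt[i] <- s[3]
      pos[i] <- readBin(bc, "double", 1, size = 8, endian = "little")
    }
    sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  }
  payloads <- vector("list", N)
  cvec <- integer(N)
  for (k in seq_len(N)) {
    cvec[k] <- rd_int(1)
    payloads[[k]] <- readBin(bc, "raw", rd_int(1))
  }
  has_d <- bitwAnd(flags, 2L) != 0L
  ncp <- rd_int(1)
  cp_pos <- integer(ncp)
  cp_a <- vector("list", ncp); cp_d <- vector("list", ncp)
  for (i in seq_len(ncp)) {
    cp_pos[i] <- rd_int(1)
    cp_a[[i]] <- rd_int(M)
    cp_d[[i]] <- if (has_d) rd_int(M) else integer(M)
  }
  structure(list(M = M, N = N, sites = sites, sample_names = NULL,
                 payloads = payloads, c = cvec, C = C,
                 cp_pos = cp_pos, cp_a = cp_a, cp_d = cp_d,
                 n_ops = NA_real_),
            class = "pbwt_index")
}
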