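# Minimal PLINK 1 bed/bim/fam reader and writer (SNP-major, the only
# layout modern tools emit). Genotypes are returned as counts of the .bim
# A1 allele; the 2-bit code 01 is missing.

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix path prefix (reads prefix.bed, prefix.bim, prefix.fam).
#' @return list with \code{genotypes} (n x m integer matrix of A1 counts,
#'   NA for missing; rows named by IID, columns by variant id), \code{map}
#'   (data.table variant_id, chrom, pos, a1, a2) and \code{fam}.
#' @export
read_plink_bed <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE)
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE)
  m <- nrow(bim); n <- nrow(fam)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  bpv <- ceiling(n / 4)
  raw <- readBin(con, "raw", bpv * m)
  if (length(raw) < bpv * m) stop("truncated .bed file")
  codes <- plink_code_table()
  # decode: each byte holds 4 samples, low bits first
  bytes <- as.integer(raw)
  dim(bytes) <- c(bpv, m)
  X <- matrix(NA_integer_, n, m)
  for (s in 0:3) {
    rows <- seq.int(s + 1L, by = 4L, length.out = bpv)
    rows <- rows[rows <= n]
    if (!length(rows)) next
    X[rows, ] <- codes[bytes[seq_along(rows), , drop = FALSE] + 1L, s + 1L]
  }
  map <- data.table::data.table(variant_id = as.character(bim$V2),
                                chrom = as.integer(bim$V1), pos = as.integer(bim$V4),
                                a1 = toupper(bim$V5), a2 = toupper(bim$V6))
  rownames(X) <- as.character(fam$V2)
  colnames(X) <- map$variant_id
  list(genotypes = X, map = map, fam = fam)
}

plink_code_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # 2-bit genotype codes: 00 = 2 copies of A1, 01 = missing,
      # 10 = 1 copy, 11 = 0 copies
      dec <- c(2L, NA_integer_, 1L, 0L)
      tb <- matrix(NA_integer_, 256L, 4L)
      for (b in 0:255) for (s in 0:3)
        tb[b + 1L, s + 1L] <- dec[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
      cache <<- tb
    }
    cache
  }
})

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' @param genotypes n x m matrix of A1 counts (0/1/2, NA = missing).
#' @param map data.frame with variant_id, chrom, pos, a1, a2.
#' @param prefix output path prefix.
#' @param iids optional individual ids (defaults to rownames).
#' @return the prefix, invisibly.
#' @export
write_plink_bed <- function(genotypes, map, prefix, iids = NULL) {
  X <- as.matrix(genotypes)
  n <- nrow(X); m <- ncol(X)
  stopifnot(nrow(map) == m)
  iids <- iids %||% rownames(X) %||% sprintf("id%05d", seq_len(n))
  enc <- c(`2` = 0L, miss = 1L, `1` = 2L, `0` = 3L)
  code <- matrix(1L, n, m)                 # missing by default
  code[which(X == 2)] <- 0L
  code[which(X == 1)] <- 2L
  code[which(X == 0)] <- 3L
  pad <- (4L - n %% 4L) %% 4L
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  q <- nrow(code) / 4L
  shifted <- code[seq(1, nrow(code), 4), , drop = FALSE] +
    bitwShiftL(code[seq(2, nrow(code), 4), , drop = FALSE], 2L) +
    bitwShiftL(code[seq(3, nrow(code), 4), , drop = FALSE], 4L) +
    bitwShiftL(code[seq(4, nrow(code), 4), , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(shifted), con)
  close(con)
  bim <- data.frame(map$chrom, map$variant_id, 0L, map$pos, map$a1, map$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  fam <- data.frame(iids, iids, 0L, 0L, 0L, -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  invisible(prefix)
}
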