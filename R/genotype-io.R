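# PLINK 1 binary and TSV dosage input/output.
#
# .bed layout (SNP-major): magic bytes 0x6C 0x1B, mode byte 0x01, then for
# each SNP ceil(n/4) bytes; each byte packs four samples, two bits each,
# least-significant pair first.  Two-bit codes: 00 = homozygous A1
# (dosage 2), 01 = missing, 10 = heterozygote (dosage 1), 11 = homozygous
# A2 (dosage 0).  Dosage counts the .bim A1 allele.  Padding bits in the
# final byte of each SNP record are written as zero.

.BED_MAGIC <- as.raw(c(0x6C, 0x1B))

# dosage value for each 2-bit code 0..3 (NA = missing)
.CODE2DOSE <- c(2, NA, 1, 0)

#' Read a PLINK 1 binary fileset
#'
#' Decodes a SNP-major \code{.bed}/\code{.bim}/\code{.fam} triple into a
#' \linkS4class{GenotypeMatrix}.  Dosage counts copies of the \code{.bim}
#' A1 allele (PLINK convention, typically the minor allele).
#' Individual-major files (mode byte 0x00) are rejected.
#'
#' @param pathPrefix path without extension; \code{<prefix>.bed},
#'   \code{.bim} and \code{.fam} must all exist
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readPlinkBed <- function(pathPrefix) {
  paths <- paste0(pathPrefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = 3 + p * bytesPerSnp + 1)
  if (length(raw) < 3 || !identical(raw[1:2], .BED_MAGIC))
    stop("not a PLINK 1 .bed file (bad magic bytes)")
  if (raw[3] == as.raw(0))
    stop("individual-major .bed (mode 0x00) is not supported; ",
         "re-export in SNP-major mode")
  if (raw[3] != as.raw(1))
    stop("unknown .bed mode byte: ", as.integer(raw[3]))
  body <- raw[-(1:3)]
  if (length(body) != p * bytesPerSnp)
    stop("truncated .bed: expected ", p * bytesPerSnp, " data bytes, got ",
         length(body))
  # split each byte into four 2-bit codes, least-significant pair first
  b <- as.integer(body)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                 b %/% 64L)                    # 4 x (bytesPerSnp * p)
  dim(codes) <- c(4L * bytesPerSnp, p)
  codes <- codes[seq_len(n), , drop = FALSE]   # drop padding slots
  d <- matrix(.CODE2DOSE[codes + 1L], n, p)
  snpInfo <- bim[, c("id", "chrom", "pos", "a1", "a2")]
  GenotypeMatrix(d, snpInfo, as.character(fam[[2]]))
}

#' Write a PLINK 1 binary fileset
#'
#' Writes SNP-major \code{.bed} (padding bits zero) plus \code{.bim} and
#' \code{.fam}.  Round-trips exactly through \code{\link{readPlinkBed}}.
#'
#' @param G a \linkS4class{GenotypeMatrix}; dosages must be 0/1/2/NA
#' @param pathPrefix output path without extension
#' @return \code{pathPrefix}, invisibly
#' @export
writePlinkBed <- function(G, pathPrefix) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- dosages(G)
  n <- nrow(d); p <- ncol(d)
  if (n == 0 || p == 0) stop("cannot write an empty genotype matrix")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages outside {0, 1, 2, NA}")
  # dosage -> 2-bit code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  codes <- matrix(c(3L, 2L, 0L)[as.integer(d) + 1L], n, p)
  codes[is.na(d)] <- 1L
  bytesPerSnp <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bytesPerSnp, p)
  padded[seq_len(n), ] <- codes
  dim(padded) <- c(4L, bytesPerSnp * p)
  bytes <- padded[1L, ] + 4L * padded[2L, ] + 16L * padded[3L, ] +
    64L * padded[4L, ]
  writeBin(c(.BED_MAGIC, as.raw(1L), as.raw(bytes)),
           paste0(pathPrefix, ".bed"))
  si <- snpInfo(G)
  bim <- data.frame(si$chrom, si$id, 0, si$pos, si$a1, si$a2)
  write.table(bim, paste0(pathPrefix, ".bim"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- sampleIds(G)
  fam <- data.frame(ids, ids, 0, 0, 0, -9)
  write.table(fam, paste0(pathPrefix, ".fam"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(pathPrefix)
}

#' Read / write a TSV dosage matrix
#'
#' Text interchange format: header row of SNP ids with \code{sample_id}
#' first, one row per sample, missing dosages encoded \code{NA}.  The
#' round trip is lossless for dosages and identifiers (TSV carries no SNP
#' positions; defaults are regenerated on read).
#'
#' @param path TSV file path
#' @return \code{readDosageTsv}: a \linkS4class{GenotypeMatrix}
#' @export
readDosageTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
  if (names(tab)[1] != "sample_id")
    stop("first column must be 'sample_id'")
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage cells must be 0, 1, 2 or NA")
  snpInfo <- data.frame(id = colnames(d), chrom = "1",
                        pos = 10000L * seq_len(ncol(d)),
                        a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  GenotypeMatrix(d, snpInfo, ids)
}

#' @rdname readDosageTsv
#' @param G a \linkS4class{GenotypeMatrix}
#' @export
writeDosageTsv <- function(G, path) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- dosages(G)
  out <- data.frame(sample_id = sampleIds(G), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
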