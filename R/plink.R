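PLINK_MAGIC <- as.raw(c(0x6C, 0x1B, 0x01))

# two-bit code per A1 dosage: 2 -> 00 (hom A1), NA -> 01, 1 -> 10 (het),
# 0 -> 11 (hom A2); bytes pack four individuals, LSB pair first
.code_from_dosage <- c(`2` = 0L, `1` = 2L, `0` = 3L)

#' Write genotypes as a PLINK .bed/.bim/.fam file set
#'
#' The .bed is variant-major with the standard three magic bytes; trailing
#' bits of the last byte per variant are zero. The .bim carries chromosome,
#' SNP id, 0 cM, position, allele1, allele2; the .fam uses sample ids for
#' both family and individual id with missing parents, sex and phenotype.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosage)
  m <- ncol(g$dosage)
  code <- matrix(1L, n, m)  # default: missing (01)
  for (d in c(0L, 1L, 2L)) code[which(g$dosage == d)] <- .code_from_dosage[[as.character(d)]]
  n_pad <- (4L - n %% 4L) %% 4L
  if (n_pad > 0) code <- rbind(code, matrix(0L, n_pad, m))
  dim(code) <- c(4L, length(code) / 4L)
  bytes <- code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  bim <- data.frame(
    chr = g$snp_map$chr, snp = g$snp_map$snp, cm = 0,
    pos = g$snp_map$pos, a1 = g$snp_map$allele1, a2 = g$snp_map$allele2
  )
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  fam <- data.frame(
    fid = g$sample_ids, iid = g$sample_ids, pat = 0, mat = 0, sex = 0, phe = -9
  )
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam file set
#'
#' Decodes the variant-major two-bit encoding into an A1-dosage matrix with
#' missing calls preserved as `NA`.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      abort(paste0("Missing PLINK file: ", prefix, ext))
    }
  }
  bim <- read.table(paste0(prefix, ".bim"), sep = "", header = FALSE,
                    col.names = c("chr", "snp", "cm", "pos", "allele1", "allele2"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), sep = "", header = FALSE,
                    colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], PLINK_MAGIC)) {
    abort("Not a variant-major PLINK .bed file (bad magic bytes).")
  }
  bpf <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpf * m) {
    abort(sprintf(
      ".bed size mismatch: expected %d data bytes for %d samples x %d variants, found %d.",
      bpf * m, n, m, length(body)
    ))
  }
  # 256 x 4 lookup: byte value -> four A1 dosages (NA for the missing code)
  codes <- as.integer(body)
  lut <- sapply(0:3, function(s) bitwAnd(bitwShiftR(0:255, 2L * s), 3L))
  dos_map <- c(2L, NA_integer_, 1L, 0L)
  dosage <- matrix(dos_map[lut[codes + 1L, ] + 1L], nrow = bpf * m, ncol = 4L)
  # rows: bytes in variant-major order; unfold to (4 x bpf) per variant
  dosage <- matrix(t(dosage), nrow = 4L * bpf)[seq_len(n), , drop = FALSE]
  genotype_matrix(
    dosage,
    tibble::as_tibble(bim[, c("snp", "chr", "pos", "allele1", "allele2")]),
    fam[[2]]
  )
}
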