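#' Write a genotype dataset as PLINK bed/bim/fam
#'
#' Standard variant-major binary layout: magic bytes `6c 1b 01`, then one
#' block per variant of 2-bit codes (00 = two copies of allele1, 10 = one,
#' 11 = zero, 01 = missing), individuals packed 4 per byte. bim columns:
#' chrom, id, cm (0), pos, allele1, allele2; fam columns: FID, IID, 0, 0,
#' sex, -9.
#'
#' @param dataset a `genotype_dataset`.
#' @param prefix path prefix (files `<prefix>.bed/.bim/.fam` are written).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  dos <- dataset$dosages
  n <- nrow(dos); m <- ncol(dos)
  # 2-bit codes per dosage of allele1
  code <- matrix(3L, n, m)              # 0 copies -> 11
  code[dos == 1] <- 2L                  # het -> 10
  code[dos == 2] <- 0L                  # 2 copies -> 00
  code[is.na(dos)] <- 1L                # missing -> 01

  bytes_per_var <- ceiling(n / 4)
  pad <- bytes_per_var * 4 - n
  out <- raw(3 + bytes_per_var * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  shift <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(0L, pad))
    q <- matrix(cj, nrow = 4)
    b <- as.integer(shift %*% q)
    out[(3 + (j - 1) * bytes_per_var + 1):(3 + j * bytes_per_var)] <- as.raw(b)
  }
  writeBin(out, paste0(prefix, ".bed"))

  v <- dataset$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ind <- dataset$individuals
  sex <- if ("sex" %in% names(ind)) ind$sex else 0
  utils::write.table(
    data.frame(ind$id, ind$id, 0, 0, sex, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam file set
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` files.
#' @return a `genotype_dataset` (dosage = count of bim allele1).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           col.names = c("fid", "id", "pat", "mat", "sex",
                                         "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw_all <- readBin(paste0(prefix, ".bed"), what = "raw",
                     n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw_all[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a variant-major PLINK bed file")
  body <- as.integer(raw_all[-(1:3)])
  bytes_per_var <- ceiling(n / 4)
  # unpack 2-bit fields
  codes <- matrix(0L, 4 * bytes_per_var, m)
  bmat <- matrix(body, bytes_per_var, m)
  codes[seq(1, 4 * bytes_per_var, by = 4), ] <- bmat %% 4L
  codes[seq(2, 4 * bytes_per_var, by = 4), ] <- (bmat %/% 4L) %% 4L
  codes[seq(3, 4 * bytes_per_var, by = 4), ] <- (bmat %/% 16L) %% 4L
  codes[seq(4, 4 * bytes_per_var, by = 4), ] <- (bmat %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  rownames(dos) <- fam$id
  colnames(dos) <- bim$id
  genotype_dataset(dos, data.frame(id = fam$id, sex = fam$sex),
                   bim[, c("id", "chrom", "pos", "allele1", "allele2")])
}
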