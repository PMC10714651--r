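#' Write a genotype matrix as a PLINK-1 bed/bim/fam triplet
#'
#' SNP-major two-bit encoding (magic bytes `6c 1b 01`); `.bim` columns are
#' chromosome, id, cM (0), bp, allele1 (= the counted effect allele),
#' allele2. Dosages are stored as counts of allele1.
#'
#' @param G a [genotype_matrix()].
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  # two-bit codes, per PLINK-1: 00 hom allele1 (dosage 2), 10 het,
  # 11 hom allele2 (dosage 0), 01 missing
  code <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    d <- G$dosages[, j]
    cc <- ifelse(is.na(d), 1L, code[as.character(d)])
    cc <- c(cc, rep(0L, pad))
    mat <- matrix(cc, nrow = 4)
    byte <- mat[1, ] + mat[2, ] * 4L + mat[3, ] * 16L + mat[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  v <- G$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0L, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  s <- G$samples
  sex_code <- ifelse(s$sex == "M", 1L, ifelse(s$sex == "F", 2L, 0L))
  utils::write.table(
    data.frame(s$iid, s$iid, 0L, 0L, sex_code, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK-1 bed/bim/fam triplet
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` files.
#' @return A [genotype_matrix()]; dosages count the `.bim` allele1.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bytes_per_snp * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b)
    stop("not a PLINK-1 bed file: ", prefix, ".bed")
  if (raw[3] != 0x01) stop("only SNP-major bed files are supported")
  body <- as.integer(raw[-(1:3)])
  # unpack two-bit fields; dosage of allele1: 00->2, 10->1, 11->0, 01->NA
  decode <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    b <- body[((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    q <- as.vector(rbind(b %% 4L, (b %/% 4L) %% 4L,
                         (b %/% 16L) %% 4L, (b %/% 64L) %% 4L))
    dos[, j] <- decode[q[seq_len(n)] + 1L]
  }
  genotype_matrix(dos,
                  data.frame(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                             a1 = bim$a1, a2 = bim$a2,
                             stringsAsFactors = FALSE),
                  data.frame(iid = fam$iid,
                             sex = c("M", "F")[match(fam$sex, 1:2)],
                             stringsAsFactors = FALSE))
}

#' Write / read a genotype matrix as a plain dosage TSV
#'
#' Long header block: first five columns are variant metadata
#' (`CHR BP SNP A1 A2`), remaining columns one per sample holding the
#' effect-allele dosage (`NA` for missing).
#' @param G a [genotype_matrix()].
#' @param path file path.
#' @return `path` invisibly; for the reader, a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- cbind(data.frame(CHR = G$variants$chrom, BP = G$variants$pos,
                         SNP = G$variants$id, A1 = G$variants$a1,
                         A2 = G$variants$a2, stringsAsFactors = FALSE),
              as.data.frame(t(G$dosages)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- df[, 1:5]
  dos <- t(as.matrix(df[, -(1:5), drop = FALSE]))
  genotype_matrix(dos,
                  data.frame(chrom = as.character(meta$CHR), pos = meta$BP,
                             id = meta$SNP, a1 = meta$A1, a2 = meta$A2,
                             stringsAsFactors = FALSE),
                  data.frame(iid = rownames(dos),
                             sex = NA_character_, stringsAsFactors = FALSE))
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns `CHR BP SNP A1 A2 BETA SE P FRQ INFO` (A1 = effect allele).
#' @param sumstats a `gwas_summary` data.frame.
#' @param path file path.
#' @return `path` invisibly; for the reader, a `gwas_summary`.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(
    data.frame(CHR = sumstats$chrom, BP = sumstats$pos, SNP = sumstats$id,
               A1 = sumstats$a1, A2 = sumstats$a2, BETA = sumstats$beta,
               SE = sumstats$se, P = sumstats$p, FRQ = sumstats$freq,
               INFO = sumstats$info),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df$CHR), pos = df$BP, id = df$SNP,
                    a1 = df$A1, a2 = df$A2, beta = df$BETA, se = df$SE,
                    p = df$P, freq = df$FRQ, info = df$INFO,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Write / read a cohort table as TSV
#' @param cohort a `cohort_table` (see [sim_recall_cohort()]).
#' @param path file path.
#' @return `path` invisibly; for the reader, a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read a kinship table
#'
#' TSV with columns `ID1`, `ID2`, `PI_HAT` (proportion of genome shared
#' identical-by-descent), as produced by standard relatedness estimators.
#' @param path file path.
#' @return data.frame with columns `id1`, `id2`, `pi_hat`.
#' @export
read_kinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(id1 = as.character(df$ID1), id2 = as.character(df$ID2),
             pi_hat = df$PI_HAT, stringsAsFactors = FALSE)
}
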