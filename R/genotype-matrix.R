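#' Construct a genotype matrix
#'
#' The central container for genotype data: an `n_samples x n_variants`
#' integer dosage matrix (counts of the effect allele, 0/1/2, `NA` for
#' missing) together with per-variant and per-sample metadata.
#'
#' @param dosages integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp,
#'   strictly increasing within a chromosome), `id`, `a1` (effect allele,
#'   the allele counted by `dosages`) and `a2` (other allele).
#' @param samples data.frame with columns `iid` and `sex` (`"F"`/`"M"`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  need_v <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("iid") %in% names(samples)))
    stop("samples must have an 'iid' column")
  if (nrow(variants) != ncol(dosages))
    stop("nrow(variants) != ncol(dosages)")
  if (nrow(samples) != nrow(dosages))
    stop("nrow(samples) != nrow(dosages)")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be in {0, 1, 2, NA}")
  if (any(!nzchar(variants$a1)) || any(!nzchar(variants$a2)))
    stop("allele strings must be non-empty")
  if (any(variants$a1 == variants$a2))
    stop("a1 and a2 must differ for every variant")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(dosages) <- samples$iid
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param G a [genotype_matrix()].
#' @param samples,variants logical/integer/character index into samples and
#'   variants respectively; missing means keep all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(G$dosages)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(G$dosages)) else variants
  if (is.character(si)) si <- match(si, G$samples$iid)
  if (is.character(vi)) vi <- match(vi, G$variants$id)
  genotype_matrix(G$dosages[si, vi, drop = FALSE],
                  G$variants[vi, , drop = FALSE],
                  G$samples[si, , drop = FALSE])
}

#' Per-variant effect-allele frequency
#'
#' Computed on non-missing dosages; `NA` for all-missing variants.
#'
#' @param G a [genotype_matrix()].
#' @return Numeric vector, one frequency per variant.
#' @export
allele_freq <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  colMeans(G$dosages, na.rm = TRUE) / 2
}

#' Per-variant minor allele frequency
#' @param G a [genotype_matrix()].
#' @return Numeric vector; `NA` where undefined (all dosages missing).
#' @export
maf <- function(G) {
  f <- allele_freq(G)
  pmin(f, 1 - f)
}
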