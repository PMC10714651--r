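#' QC thresholds
#'
#' Container for the sample- and variant-level quality-control thresholds:
#' minimum call rates (0.95), Hardy-Weinberg exact-test alpha (1e-6),
#' minimum minor allele frequency (0.01), heterozygosity-outlier width in
#' SD units of the inbreeding coefficient (3), and the relatedness cutoff
#' (pi-hat 0.2, i.e. third-degree or closer).
#'
#' @param min_sample_call_rate,min_variant_call_rate minimum non-missing
#'   fraction per sample / per variant.
#' @param hwe_alpha HWE exact-test exclusion level.
#' @param min_maf minimum minor allele frequency (strict `<` removes).
#' @param het_sd heterozygosity-outlier width, in SDs of F.
#' @param max_pi_hat relatedness threshold (strict `>` flags a pair).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.95,
                          min_variant_call_rate = 0.95,
                          hwe_alpha = 1e-6, min_maf = 0.01,
                          het_sd = 3, max_pi_hat = 0.2) {
  stopifnot(min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_variant_call_rate >= 0, min_variant_call_rate <= 1,
            hwe_alpha > 0, hwe_alpha < 1, min_maf >= 0, min_maf <= 0.5,
            het_sd > 0, max_pi_hat >= 0, max_pi_hat <= 1)
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_variant_call_rate = min_variant_call_rate,
                 hwe_alpha = hwe_alpha, min_maf = min_maf,
                 het_sd = het_sd, max_pi_hat = max_pi_hat),
            class = "qc_thresholds")
}

#' Call-rate filter
#'
#' Removes samples, then variants, whose non-missing fraction falls below
#' the threshold (samples first; recomputing variant call rates on the
#' reduced sample set).
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return Filtered `genotype_matrix`; attributes `removed_samples` and
#'   `removed_variants` record the dropped ids.
#' @export
call_rate_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$dosages) == 0 || ncol(G$dosages) == 0) stop("empty genotype matrix")
  scr <- rowMeans(!is.na(G$dosages))
  keep_s <- scr >= thresholds$min_sample_call_rate
  if (!any(keep_s)) stop("call_rate_filter removed every sample")
  G2 <- subset_genotypes(G, samples = which(keep_s))
  vcr <- colMeans(!is.na(G2$dosages))
  keep_v <- vcr >= thresholds$min_variant_call_rate
  out <- subset_genotypes(G2, variants = which(keep_v))
  attr(out, "removed_samples") <- G$samples$iid[!keep_s]
  attr(out, "removed_variants") <- G2$variants$id[!keep_v]
  out
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of genotype counts against Hardy-Weinberg
#' proportions, conditioning on the observed allele counts: all
#' heterozygote counts of the correct parity are enumerated, and the
#' p-value is the sum of probabilities no greater than that of the observed
#' configuration (the Wigginton exact test, without mid-p correction).
#' Vectorized over configurations.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectors recycle).
#' @return Exact p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  k <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  n_hom_ref <- rep_len(n_hom_ref, k)
  n_het <- rep_len(n_het, k)
  n_hom_alt <- rep_len(n_hom_alt, k)
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be >= 0")
  vapply(seq_len(k), function(i)
    hwe_exact_one(n_hom_ref[i], n_het[i], n_hom_alt[i]), numeric(1))
}

hwe_exact_one <- function(aa, ab, bb) {
  n <- aa + ab + bb
  if (n < 1) stop("total genotype count must be >= 1")
  na <- 2 * aa + ab                       # count of the rarer allele side
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  # log P(het = h | allele counts) up to a constant
  lp <- h_lp(hets, n, na)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[match(ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

h_lp <- function(h, n, na) {
  aa <- (na - h) / 2
  bb <- n - aa - h
  h * log(2) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1)
}

#' Hardy-Weinberg filter
#'
#' Removes variants whose exact HWE p-value (on non-missing genotype
#' counts) falls below `hwe_alpha`.
#' @inheritParams call_rate_filter
#' @return Filtered `genotype_matrix` with attribute `removed_variants`.
#' @export
hwe_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"))
  counts <- apply(G$dosages, 2, function(d) {
    d <- d[!is.na(d)]
    c(sum(d == 0), sum(d == 1), sum(d == 2))
  })
  keep <- vapply(seq_len(ncol(counts)), function(j) {
    if (sum(counts[, j]) == 0) return(FALSE)  # untestable, drop
    hwe_exact_test(counts[1, j], counts[2, j], counts[3, j]) >=
      thresholds$hwe_alpha
  }, logical(1))
  out <- subset_genotypes(G, variants = which(keep))
  attr(out, "removed_variants") <- G$variants$id[!keep]
  out
}

#' Minor-allele-frequency filter
#'
#' Removes variants with MAF strictly below `min_maf` (MAF computed on
#' non-missing dosages; a MAF exactly at the threshold is retained).
#' All-missing variants have undefined MAF and are removed.
#' @inheritParams call_rate_filter
#' @return Filtered `genotype_matrix` with attribute `removed_variants`.
#' @export
maf_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- maf(G)
  keep <- !is.na(m) & m >= thresholds$min_maf
  out <- subset_genotypes(G, variants = which(keep))
  attr(out, "removed_variants") <- G$variants$id[!keep]
  out
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' `F = (O_hom - E_hom) / (n_typed - E_hom)`, where `O_hom` is the observed
#' homozygote count over the sample's typed variants and `E_hom` the HWE
#' expectation `sum(1 - 2 p_j (1 - p_j))` from the per-variant allele
#' frequencies of the whole matrix. A fully homozygous sample has F = 1;
#' excess heterozygosity drives F negative.
#'
#' @param G a [genotype_matrix()].
#' @return Numeric vector of F, one per sample.
#' @export
inbreeding_f <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- allele_freq(G)
  e_hom_j <- 1 - 2 * p * (1 - p)
  typed <- !is.na(G$dosages)
  o_hom <- rowSums((G$dosages != 1L) & typed, na.rm = TRUE)
  e_hom <- typed %*% e_hom_j
  n_typed <- rowSums(typed)
  as.vector((o_hom - e_hom) / (n_typed - e_hom))
}

#' Heterozygosity-outlier filter
#'
#' Removes samples whose inbreeding coefficient F deviates from the sample
#' mean by more than `het_sd` standard deviations. `tail = "both"` (the
#' default) removes deviations in either direction; `"upper"` removes only
#' excess-heterozygosity outliers (strongly negative F).
#'
#' @inheritParams call_rate_filter
#' @param tail `"both"` or `"upper"` (excess heterozygosity only).
#' @return Filtered `genotype_matrix` with attribute `removed_samples`.
#' @export
het_outlier_filter <- function(G, thresholds = qc_thresholds(),
                               tail = c("both", "upper")) {
  stopifnot(inherits(G, "genotype_matrix"), nrow(G$dosages) >= 2)
  tail <- match.arg(tail)
  f <- inbreeding_f(G)
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) {
    out <- G
    attr(out, "removed_samples") <- character(0)
    attr(out, "note") <- "zero variance in F; no removals"
    return(out)
  }
  dev <- (f - mean(f)) / s
  keep <- if (tail == "both") abs(dev) <= thresholds$het_sd
          else dev >= -thresholds$het_sd
  out <- subset_genotypes(G, samples = which(keep))
  attr(out, "removed_samples") <- G$samples$iid[!keep]
  out
}

#' Relatedness filter
#'
#' Greedy exclusion from a precomputed kinship table: while any pair
#' exceeds `max_pi_hat`, drop the individual involved in the most such
#' pairs (ties broken by the lexicographically smaller id). Kinship
#' estimation itself is upstream; this consumes its output.
#'
#' @param kinship data.frame with columns `id1`, `id2`, `pi_hat`.
#' @param thresholds a [qc_thresholds()].
#' @return Character vector of excluded ids (possibly empty).
#' @export
relatedness_filter <- function(kinship, thresholds = qc_thresholds()) {
  stopifnot(all(c("id1", "id2", "pi_hat") %in% names(kinship)))
  if (any(kinship$pi_hat < 0 | kinship$pi_hat > 1))
    stop("pi_hat must be in [0, 1]")
  if (any(kinship$id1 == kinship$id2))
    stop("self-pairs are not allowed in the kinship table")
  viol <- kinship[kinship$pi_hat > thresholds$max_pi_hat, , drop = FALSE]
  excluded <- character(0)
  while (nrow(viol) > 0) {
    ids <- c(viol$id1, viol$id2)
    tab <- table(ids)
    top <- max(tab)
    drop_id <- min(names(tab)[tab == top])   # lexicographic tie-break
    excluded <- c(excluded, drop_id)
    viol <- viol[viol$id1 != drop_id & viol$id2 != drop_id, , drop = FALSE]
  }
  excluded
}

#' Run the full genotype QC pipeline
#'
#' Applies, in order: sample call rate, relatedness (if a kinship table is
#' supplied), variant call rate, HWE, MAF, heterozygosity outliers. The
#' order follows the conventional narrative (sample-level first) and is
#' overridable.
#'
#' @param G a [genotype_matrix()].
#' @param kinship optional kinship data.frame (`id1`, `id2`, `pi_hat`).
#' @param thresholds a [qc_thresholds()].
#' @param steps character vector of steps, a subset of
#'   `c("call_rate", "relatedness", "hwe", "maf", "het")`, in order.
#' @return A `qc_report`: list with `steps` (data.frame: step, samples and
#'   variants removed/remaining) and `genotypes` (the filtered matrix).
#' @export
qc_pipeline <- function(G, kinship = NULL, thresholds = qc_thresholds(),
                        steps = c("call_rate", "relatedness", "hwe",
                                  "maf", "het")) {
  stopifnot(inherits(G, "genotype_matrix"))
  log <- list()
  note <- function(step, before, after) {
    data.frame(step = step,
               samples_removed = nrow(before$dosages) - nrow(after$dosages),
               samples_remaining = nrow(after$dosages),
               variants_removed = ncol(before$dosages) - ncol(after$dosages),
               variants_remaining = ncol(after$dosages))
  }
  for (st in steps) {
    before <- G
    G <- switch(st,
      call_rate = call_rate_filter(G, thresholds),
      relatedness = {
        if (is.null(kinship)) before else {
          drop <- relatedness_filter(kinship, thresholds)
          subset_genotypes(before,
                           samples = which(!(before$samples$iid %in% drop)))
        }
      },
      hwe = hwe_filter(G, thresholds),
      maf = maf_filter(G, thresholds),
      het = het_outlier_filter(G, thresholds),
      stop("unknown QC step: ", st))
    log[[st]] <- note(st, before, G)
  }
  structure(list(steps = do.call(rbind, log), genotypes = G),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}
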