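#' Clumping / pruning configuration
#'
#' Defaults are the score-construction settings (window 1000 kb, r-squared
#' 0.2, p-value threshold 0.5); [prune()] reuses the same machinery with
#' its own defaults (r-squared 0.01, window 10 Mb).
#'
#' @param window_kb window half-width in kb.
#' @param r2_threshold pairwise r-squared above which a neighbour of a
#'   retained index variant is discarded.
#' @param p_threshold variants with p above this are never retained.
#' @return A list of class `clump_config`.
#' @export
clump_config <- function(window_kb = 1000, r2_threshold = 0.2,
                         p_threshold = 0.5) {
  stopifnot(window_kb > 0, r2_threshold > 0, r2_threshold <= 1,
            p_threshold > 0, p_threshold <= 1)
  structure(list(window_kb = window_kb, r2_threshold = r2_threshold,
                 p_threshold = p_threshold), class = "clump_config")
}

#' Genomic region masks
#'
#' Half-open `[start, end)` base-pair intervals to exclude from scoring:
#' the APOE locus (chr 19: 44,400-46,500 kb), whose single-locus effect
#' would dominate the score, and the MHC (chr 6: 26,000-34,000 kb), whose
#' long-range LD distorts clumping.
#'
#' @param regions character subset of `c("apoe", "mhc")`.
#' @return data.frame with columns `region`, `chrom`, `start`, `end`.
#' @export
region_mask <- function(regions = c("apoe", "mhc")) {
  all <- data.frame(
    region = c("apoe", "mhc"),
    chrom = c("19", "6"),
    start = c(44400000, 26000000),
    end = c(46500000, 34000000),
    stringsAsFactors = FALSE)
  out <- all[all$region %in% regions, , drop = FALSE]
  stopifnot(all(out$start < out$end))
  out
}

#' Remove variants inside masked regions
#'
#' Intervals are half-open `[start, end)`: a variant at exactly `end` is
#' retained. Chromosome labels absent from the mask pass through.
#'
#' @param variants data.frame with `chrom` and `pos` columns (e.g. a
#'   `gwas_summary` or a `variants` slot).
#' @param mask a [region_mask()]-style data.frame.
#' @return `variants` with masked rows removed; attribute `n_masked`.
#' @export
exclude_regions <- function(variants, mask = region_mask()) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  inside <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(mask))) {
    inside <- inside | (as.character(variants$chrom) == mask$chrom[i] &
                          variants$pos >= mask$start[i] &
                          variants$pos < mask$end[i])
  }
  out <- variants[!inside, , drop = FALSE]
  attr(out, "n_masked") <- sum(inside)
  out
}

strand_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonize summary-statistic weights to a genotype panel
#'
#' Matches variants by id; where the panel's counted allele is the summary
#' statistics' other allele, the beta sign is flipped (and the frequency
#' complemented) so that all weights refer to the panel's counted allele.
#' Strand-ambiguous (A/T, C/G) variants and allele-incompatible or
#' unmatched variants are dropped and counted.
#'
#' @param variants data.frame with `id`, `a1`, `a2` (the panel coding),
#'   e.g. `G$variants`.
#' @param sumstats a `gwas_summary`.
#' @return Aligned weight table: `gwas_summary` rows re-expressed in the
#'   panel's allele coding, with attributes `n_flipped`, `n_ambiguous`,
#'   `n_unmatched`, `n_mismatched`.
#' @export
harmonize <- function(variants, sumstats) {
  m <- match(variants$id, sumstats$id)
  matched <- !is.na(m)
  if (!any(matched)) stop("no overlapping variants between panel and sumstats")
  v <- variants[matched, , drop = FALSE]
  s <- sumstats[m[matched], , drop = FALSE]
  amb <- strand_ambiguous(s$a1, s$a2)
  same <- v$a1 == s$a1 & v$a2 == s$a2
  swap <- v$a1 == s$a2 & v$a2 == s$a1
  ok <- !amb & (same | swap)
  out <- s[ok, , drop = FALSE]
  sw <- swap[ok]
  out$beta[sw] <- -out$beta[sw]
  if (!is.null(out$freq)) out$freq[sw] <- 1 - out$freq[sw]
  tmp <- out$a1[sw]; out$a1[sw] <- out$a2[sw]; out$a2[sw] <- tmp
  attr(out, "n_flipped") <- sum(sw)
  attr(out, "n_ambiguous") <- sum(amb)
  attr(out, "n_unmatched") <- sum(!matched)
  attr(out, "n_mismatched") <- sum(!amb & !(same | swap))
  out
}

# pairwise r2 between one variant and a set, from whatever LD source:
# a genotype_matrix (computed on the fly), a square r2 matrix with variant
# ids as dimnames, or a data.frame (id1, id2, r2). Unknown pairs are 0.
ld_r2 <- function(ld, id_i, ids_j) {
  if (length(ids_j) == 0) return(numeric(0))
  if (inherits(ld, "genotype_matrix")) {
    i <- match(id_i, ld$variants$id)
    j <- match(ids_j, ld$variants$id)
    out <- numeric(length(ids_j))
    known <- !is.na(j)
    if (!is.na(i) && any(known)) {
      r <- suppressWarnings(
        stats::cor(ld$dosages[, i], ld$dosages[, j[known], drop = FALSE],
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      out[known] <- as.vector(r)^2
    }
    return(out)
  }
  if (is.matrix(ld)) {
    out <- numeric(length(ids_j))
    if (id_i %in% rownames(ld)) {
      j <- match(ids_j, colnames(ld))
      out[!is.na(j)] <- ld[id_i, j[!is.na(j)]]
    }
    return(out)
  }
  if (is.data.frame(ld)) {
    out <- numeric(length(ids_j))
    hit <- (ld$id1 == id_i & ld$id2 %in% ids_j) |
           (ld$id2 == id_i & ld$id1 %in% ids_j)
    sub <- ld[hit, , drop = FALSE]
    other <- ifelse(sub$id1 == id_i, sub$id2, sub$id1)
    out[match(other, ids_j)] <- sub$r2
    return(out)
  }
  stop("unsupported LD source")
}

#' Greedy LD clumping
#'
#' P-value-ordered greedy thinning: repeatedly retain the remaining variant
#' with the smallest p (ties broken by position, then id), then discard all
#' unretained same-chromosome variants within `window_kb` whose r-squared
#' with it exceeds `r2_threshold`. Variants with p above `p_threshold`
#' are never retained. Pairs with no LD information are treated as
#' r-squared 0.
#'
#' @param sumstats a `gwas_summary` (needs `chrom`, `pos`, `id`, `p`).
#' @param ld LD source: a [genotype_matrix()], a square r-squared matrix
#'   with variant-id dimnames, or a data.frame (`id1`, `id2`, `r2`).
#' @param config a [clump_config()].
#' @return Character vector of retained variant ids.
#' @export
clump <- function(sumstats, ld, config = clump_config()) {
  s <- sumstats[sumstats$p <= config$p_threshold, , drop = FALSE]
  if (nrow(s) == 0) return(character(0))
  ord <- order(s$p, s$pos, s$id)
  s <- s[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(s))
  retained <- character(0)
  win <- config$window_kb * 1000
  for (i in seq_len(nrow(s))) {
    if (!alive[i]) next
    retained <- c(retained, s$id[i])
    alive[i] <- FALSE
    near <- which(alive & s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= win)
    if (length(near)) {
      r2 <- ld_r2(ld, s$id[i], s$id[near])
      alive[near[r2 > config$r2_threshold]] <- FALSE
    }
  }
  retained
}

#' Greedy LD pruning for summary-statistic analyses
#'
#' Identical algorithm to [clump()] with the pruning defaults
#' (r-squared 0.01 within 10 Mb, no p-value gate).
#'
#' @inheritParams clump
#' @param r2 pairwise r-squared threshold.
#' @param window_mb window half-width in Mb.
#' @return Character vector of retained variant ids.
#' @export
prune <- function(sumstats, ld, r2 = 0.01, window_mb = 10) {
  clump(sumstats, ld,
        clump_config(window_kb = window_mb * 1000, r2_threshold = r2,
                     p_threshold = 1))
}

#' Compute polygenic risk scores
#'
#' Raw score = sum over weights of beta times effect-allele dosage.
#' Missing dosages are mean-imputed as `2 * freq` (default) or omitted
#' with the raw sum rescaled by the ratio of total to observed weight
#' count. Scores are standardized over the scored population (mean 0,
#' SD 1) and binned into rank-based deciles with ties assigned to the
#' lower decile.
#'
#' @param G a [genotype_matrix()].
#' @param weights aligned weight table from [harmonize()] (columns `id`,
#'   `beta`, and `freq` for mean imputation), already in `G`'s allele
#'   coding.
#' @param missing_policy `"mean_impute"` or `"omit"`.
#' @return A `score_set` data.frame: `iid`, `raw`, `z`, `decile`;
#'   attribute `n_variants` = number of variants scored.
#' @export
compute_prs <- function(G, weights,
                        missing_policy = c("mean_impute", "omit")) {
  stopifnot(inherits(G, "genotype_matrix"))
  missing_policy <- match.arg(missing_policy)
  if (NROW(weights) == 0) stop("empty weight set")
  j <- match(weights$id, G$variants$id)
  if (anyNA(j)) stop("weights contain variants absent from the panel")
  D <- G$dosages[, j, drop = FALSE]
  beta <- weights$beta
  if (missing_policy == "mean_impute") {
    if (is.null(weights$freq)) stop("mean imputation needs a freq column")
    miss <- is.na(D)
    if (any(miss)) {
      imp <- matrix(rep(2 * weights$freq, each = nrow(D)), nrow(D))
      D[miss] <- imp[miss]
    }
    raw <- as.vector(D %*% beta)
  } else {
    obs <- !is.na(D)
    D0 <- D; D0[!obs] <- 0
    raw <- as.vector(D0 %*% beta)
    n_obs <- rowSums(obs)
    if (any(n_obs == 0)) stop("sample with no scored variants under 'omit'")
    raw <- raw * length(beta) / n_obs
  }
  z <- (raw - mean(raw)) / stats::sd(raw)
  out <- data.frame(iid = G$samples$iid, raw = raw, z = z,
                    decile = decile_bin(raw), stringsAsFactors = FALSE)
  attr(out, "n_variants") <- length(beta)
  class(out) <- c("score_set", "data.frame")
  out
}

# rank-based deciles, ties to the lower decile; bin sizes differ by <= 1
# before ties
decile_bin <- function(x) {
  r <- rank(x, ties.method = "min")
  as.integer(floor((r - 1) * 10 / length(x)) + 1)
}

#' Select the recall sample from the score tails
#'
#' Takes the `k_low` lowest and `k_high` highest standardized scores.
#' Every selected individual must lie at least `min_sd` SDs from the
#' population mean and in the matching extreme decile (1 or 10); a
#' shortfall is an error, never silently relaxed.
#'
#' @param scores a `score_set` from [compute_prs()].
#' @param k_low,k_high group sizes.
#' @param min_sd minimum |standardized score|.
#' @return data.frame `iid`, `group` (`"low"`/`"high"`), `z`, `decile`.
#' @export
select_recall <- function(scores, k_low = 10, k_high = 6, min_sd = 2) {
  stopifnot(inherits(scores, "data.frame"),
            all(c("iid", "z", "decile") %in% names(scores)))
  if (k_low < 1 || k_high < 1) stop("k_low and k_high must be >= 1")
  if (k_low + k_high > nrow(scores))
    stop("requested sample exceeds population size")
  ord <- order(scores$z)
  low <- scores[ord[seq_len(k_low)], , drop = FALSE]
  high <- scores[rev(ord)[seq_len(k_high)], , drop = FALSE]
  n_low_ok <- sum(scores$z <= -min_sd & scores$decile == 1)
  n_high_ok <- sum(scores$z >= min_sd & scores$decile == 10)
  if (n_low_ok < k_low || n_high_ok < k_high)
    stop(sprintf(paste0("recall shortfall: %d qualifying low-tail and %d ",
                        "high-tail individuals for a %d/%d design"),
                 n_low_ok, n_high_ok, k_low, k_high))
  data.frame(iid = c(low$iid, high$iid),
             group = rep(c("low", "high"), c(k_low, k_high)),
             z = c(low$z, high$z),
             decile = c(low$decile, high$decile),
             stringsAsFactors = FALSE)
}
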