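#' Harmonize an exposure / outcome GWAS pair
#'
#' Intersects the two panels on variant id and re-expresses the outcome in
#' the exposure's effect-allele coding: swapped-allele variants have their
#' outcome beta sign-flipped (and frequency complemented); strand-ambiguous
#' (A/T, C/G) and allele-incompatible variants are dropped.
#'
#' @param exposure,outcome `gwas_summary` data.frames.
#' @return data.frame with the exposure columns plus `beta_out`, `se_out`,
#'   `p_out`; attributes `n_flipped`, `n_ambiguous`, `n_mismatched`.
#' @export
harmonize_pair <- function(exposure, outcome) {
  m <- match(exposure$id, outcome$id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no overlapping variants between exposure and outcome")
  e <- exposure[keep, , drop = FALSE]
  o <- outcome[m[keep], , drop = FALSE]
  amb <- strand_ambiguous(e$a1, e$a2)
  same <- e$a1 == o$a1 & e$a2 == o$a2
  swap <- e$a1 == o$a2 & e$a2 == o$a1
  ok <- !amb & (same | swap)
  e <- e[ok, , drop = FALSE]
  sgn <- ifelse(swap[ok], -1, 1)
  e$beta_out <- o$beta[ok] * sgn
  e$se_out <- o$se[ok]
  e$p_out <- o$p[ok]
  attr(e, "n_flipped") <- sum(swap[ok])
  attr(e, "n_ambiguous") <- sum(amb)
  attr(e, "n_mismatched") <- sum(!amb & !(same | swap))
  e
}

#' Summary-statistic QC filter
#'
#' Applied in order, with per-filter removal counts logged in the
#' `filter_log` attribute: minor allele frequency >= `min_maf`, imputation
#' quality >= `min_info`, region mask (MHC + APOE by default), then the
#' p-value threshold `p <= p_threshold`.
#'
#' @param sumstats a `gwas_summary`.
#' @param min_maf minimum minor allele frequency.
#' @param min_info minimum imputation quality.
#' @param mask a [region_mask()]-style data.frame (or `NULL` to skip).
#' @param p_threshold inclusion p-value threshold.
#' @return Filtered `gwas_summary` with attribute `filter_log`.
#' @export
sumstats_qc_filter <- function(sumstats, min_maf = 0.01, min_info = 0.9,
                               mask = region_mask(c("mhc", "apoe")),
                               p_threshold = 0.5) {
  need <- c("chrom", "pos", "freq", "info", "p")
  absent <- setdiff(need, names(sumstats))
  if (length(absent))
    stop("missing column(s): ", paste(absent, collapse = ", "))
  log <- c()
  n0 <- nrow(sumstats)
  sumstats <- sumstats[pmin(sumstats$freq, 1 - sumstats$freq) >= min_maf, ,
                       drop = FALSE]
  log["maf"] <- n0 - nrow(sumstats); n0 <- nrow(sumstats)
  sumstats <- sumstats[sumstats$info >= min_info, , drop = FALSE]
  log["info"] <- n0 - nrow(sumstats); n0 <- nrow(sumstats)
  if (!is.null(mask)) sumstats <- exclude_regions(sumstats, mask)
  log["region"] <- n0 - nrow(sumstats); n0 <- nrow(sumstats)
  sumstats <- sumstats[sumstats$p <= p_threshold, , drop = FALSE]
  log["p_threshold"] <- n0 - nrow(sumstats)
  attr(sumstats, "filter_log") <- log
  sumstats
}

#' Inverse-variance-weighted summary-statistic association
#'
#' The gtx-style estimator: for exposure betas `bx`, outcome betas `by`
#' and outcome standard errors `se_y`,
#' `beta = sum(bx by / se_y^2) / sum(bx^2 / se_y^2)` with
#' `se = 1 / sqrt(sum(bx^2 / se_y^2))` — algebraically the
#' weighted-least-squares regression of `by` on `bx` through the origin
#' with weights `1/se_y^2` and residual variance fixed at 1. Exposure
#' standard errors do not enter the weights (first-order IVW).
#'
#' @param bx exposure betas.
#' @param by outcome betas (same allele coding as `bx`).
#' @param se_y outcome standard errors (> 0).
#' @return An `ivw_result`: list with `beta`, `se`, `z`, `p`,
#'   `n_variants`.
#' @export
ivw <- function(bx, by, se_y) {
  if (!(length(bx) == length(by) && length(by) == length(se_y)))
    stop("bx, by and se_y must have equal length")
  if (length(bx) < 1) stop("need at least one variant")
  if (any(se_y <= 0)) stop("se_y must be > 0")
  if (all(bx == 0)) stop("all exposure betas are zero; estimate undefined")
  w <- 1 / se_y^2
  denom <- sum(bx^2 * w)
  beta <- sum(bx * by * w) / denom
  se <- 1 / sqrt(denom)
  z <- beta / se
  structure(list(beta = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), n_variants = length(bx)),
            class = "ivw_result")
}

#' @export
print.ivw_result <- function(x, ...) {
  cat(sprintf("IVW: beta = %.4g (SE %.3g), z = %.2f, p = %.3g, %d variants\n",
              x$beta, x$se, x$z, x$p, x$n_variants))
  invisible(x)
}

#' Full summary-statistic PRS-association pipeline
#'
#' QC-filters the exposure panel, harmonizes the outcome onto it, prunes
#' for LD, and runs the IVW estimator.
#'
#' @param exposure,outcome `gwas_summary` data.frames.
#' @param ld LD source for [prune()] (or `NULL` for none, treating all
#'   pairs as independent).
#' @param prune_r2,prune_mb pruning parameters.
#' @param ... passed to [sumstats_qc_filter()].
#' @return An `ivw_result` with attribute `n_stages` (variant counts per
#'   stage).
#' @export
ivw_analysis <- function(exposure, outcome, ld = NULL, prune_r2 = 0.01,
                         prune_mb = 10, ...) {
  filt <- sumstats_qc_filter(exposure, ...)
  pair <- harmonize_pair(filt, outcome)
  keep <- if (is.null(ld)) pair$id else prune(pair, ld, prune_r2, prune_mb)
  pair <- pair[pair$id %in% keep, , drop = FALSE]
  res <- ivw(pair$beta, pair$beta_out, pair$se_out)
  attr(res, "n_stages") <- c(input = nrow(exposure), qc = nrow(filt),
                             harmonized = NA_integer_, pruned = nrow(pair))
  res
}
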