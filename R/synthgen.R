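#' Simulate genotypes with block linkage disequilibrium
#'
#' Draws Hardy-Weinberg genotypes via a Gaussian copula: each haplotype's
#' latent liabilities follow an AR(1) process with correlation `ld_rho`
#' between adjacent variants inside a block, independent across blocks, and
#' are thresholded at the variant's allele frequency. Marginally every
#' variant is in HWE at its drawn MAF; within a block adjacent dosages are
#' positively correlated, which is enough structure to exercise LD clumping
#' and pruning.
#'
#' @param n_samples,n_variants counts (>= 1).
#' @param maf_range length-2 interval in (0, 0.5]; per-variant MAFs are
#'   drawn uniformly from it.
#' @param ld_block_size number of variants per LD block.
#' @param ld_rho latent AR(1) correlation between adjacent variants within a
#'   block, in `[0, 1)`.
#' @param missing_rate completely-at-random missingness proportion in `[0, 1)`.
#' @param chrom chromosome label for all variants.
#' @param bp_spacing base pairs between adjacent variants.
#' @param seed integer seed; the generator is deterministic given a seed.
#'
#' @return A [genotype_matrix()].
#' @export
sim_genotypes <- function(n_samples, n_variants, maf_range = c(0.05, 0.5),
                          ld_block_size = 10, ld_rho = 0,
                          missing_rate = 0, chrom = "1",
                          bp_spacing = 5000L, seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  mafs <- stats::runif(n_variants, maf_range[1], maf_range[2])
  thr <- stats::qnorm(mafs)               # latent < thr  =>  effect allele

  # one AR(1) latent matrix per haplotype, restarted at block boundaries
  latent <- function() {
    z <- matrix(stats::rnorm(n_samples * n_variants), n_samples, n_variants)
    if (ld_rho > 0 && n_variants > 1) {
      w <- sqrt(1 - ld_rho^2)
      for (j in 2:n_variants) {
        if ((j - 1) %% ld_block_size == 0) next  # new block
        z[, j] <- ld_rho * z[, j - 1] + w * z[, j]
      }
    }
    z
  }
  h1 <- sweep(latent(), 2, thr, `<`)
  h2 <- sweep(latent(), 2, thr, `<`)
  dos <- h1 + h2
  if (missing_rate > 0)
    dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_

  variants <- data.frame(
    chrom = chrom,
    pos = as.integer(bp_spacing) * seq_len(n_variants),
    id = sprintf("rs%06d", seq_len(n_variants)),
    a1 = "A", a2 = "G",
    stringsAsFactors = FALSE)
  samples <- data.frame(
    iid = sprintf("S%05d", seq_len(n_samples)),
    sex = rep_len(c("F", "M"), n_samples),
    stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples)
}

#' Simulate exposure GWAS summary statistics
#'
#' A `causal_fraction` subset of variants receives true effects drawn from
#' `Normal(0, effect_sd^2)`; observed betas add estimation noise with the
#' standard error implied by the GWAS sample size and allele frequency
#' (`se = 1 / sqrt(2 f (1 - f) n)`, the slope SE for a standardized trait).
#' P-values are the two-sided normal tail of beta/se.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `a1`, `a2`
#'   and optionally `freq` (effect-allele frequency; drawn U(0.05, 0.95) if
#'   absent), e.g. the `variants` slot of a [genotype_matrix()].
#' @param causal_fraction proportion in (0, 1] of variants with a nonzero
#'   true effect.
#' @param effect_sd SD of true causal effects.
#' @param gwas_n training GWAS sample size.
#' @param info_range interval for simulated imputation-quality scores.
#' @param seed integer seed.
#'
#' @return A `gwas_summary` data.frame with columns `chrom`, `pos`, `id`,
#'   `a1`, `a2`, `beta`, `se`, `p`, `freq`, `info` and an attribute
#'   `true_beta`.
#' @export
sim_gwas <- function(variants, causal_fraction = 0.1, effect_sd = 0.05,
                     gwas_n = 50000, info_range = c(0.95, 1), seed = NULL) {
  if (NROW(variants) == 0) stop("variants is empty")
  if (causal_fraction <= 0 || causal_fraction > 1)
    stop("causal_fraction must be in (0, 1]")
  if (effect_sd < 0) stop("effect_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(variants)
  freq <- if ("freq" %in% names(variants)) variants$freq else
    stats::runif(m, 0.05, 0.95)
  freq <- pmin(pmax(freq, 1e-3), 1 - 1e-3)
  true_beta <- numeric(m)
  n_causal <- max(1L, round(causal_fraction * m))
  causal <- sample.int(m, n_causal)
  true_beta[causal] <- stats::rnorm(n_causal, 0, effect_sd)
  se <- 1 / sqrt(2 * freq * (1 - freq) * gwas_n)
  beta <- true_beta + stats::rnorm(m, 0, se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    id = variants$id, a1 = variants$a1, a2 = variants$a2,
                    beta = beta, se = se, p = pmax(p, .Machine$double.xmin),
                    freq = freq,
                    info = stats::runif(m, info_range[1], info_range[2]),
                    stringsAsFactors = FALSE)
  attr(out, "true_beta") <- true_beta
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Simulate outcome GWAS summary statistics from an exposure GWAS
#'
#' Outcome effects follow `by_j = true_beta * bx_j + e_j` with
#' `e_j ~ Normal(0, se_j^2)` and `se_j` jittered around `se_scale`. Alleles
#' are copied from the exposure panel (pre-harmonized pair).
#'
#' @param exposure a `gwas_summary` (see [sim_gwas()]).
#' @param true_beta the planted exposure-outcome coefficient.
#' @param se_scale positive typical outcome standard error.
#' @param seed integer seed.
#' @return A `gwas_summary` for the outcome trait.
#' @export
sim_outcome_gwas <- function(exposure, true_beta, se_scale, seed = NULL) {
  if (NROW(exposure) == 0) stop("exposure is empty")
  if (se_scale <= 0) stop("se_scale must be > 0")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(exposure)
  se <- se_scale * stats::runif(m, 0.8, 1.2)
  by <- true_beta * exposure$beta + stats::rnorm(m, 0, se)
  out <- exposure
  out$beta <- by
  out$se <- se
  out$p <- pmax(2 * stats::pnorm(-abs(by / se)), .Machine$double.xmin)
  attr(out, "true_beta") <- true_beta
  out
}

# Table-1 demographic structure of the recall sample, used as the default
# covariate model: exact sex / APOE / qualification counts, normal age.
recall_demographics <- function(n_low, n_high) {
  scale_counts <- function(counts, n) {
    k <- round(counts / sum(counts) * n)
    while (sum(k) > n) k[which.max(k)] <- k[which.max(k)] - 1L
    while (sum(k) < n) k[which.max(counts - k)] <- k[which.max(counts - k)] + 1L
    k
  }
  lowsex <- scale_counts(c(F = 7, M = 3), n_low)
  highsex <- scale_counts(c(F = 4, M = 2), n_high)
  lowapoe <- scale_counts(c("e2e3" = 0, "e3e3" = 8, "e3e4" = 2), n_low)
  highapoe <- scale_counts(c("e2e3" = 1, "e3e3" = 5, "e3e4" = 0), n_high)
  lowq <- scale_counts(c("2" = 2, "3" = 1, "6" = 5, "7" = 2), n_low)
  highq <- scale_counts(c("2" = 1, "3" = 1, "6" = 3, "7" = 1), n_high)
  list(
    sex = c(rep(names(lowsex), lowsex), rep(names(highsex), highsex)),
    apoe = c(rep(names(lowapoe), lowapoe), rep(names(highapoe), highapoe)),
    qual = as.integer(c(rep(names(lowq), lowq), rep(names(highq), highq))),
    age_mean = c(rep(69.2, n_low), rep(64.3, n_high)),
    age_sd = c(rep(6.01, n_low), rep(6.62, n_high)))
}

# plausible natural units per outcome (location, scale); linear, so every
# reported statistic (t, d, chi-square) is invariant to them
outcome_units <- function() {
  rbind(
    sam_total           = c(95, 15),
    sam_episodic        = c(48, 8),
    sam_semantic        = c(50, 9),
    sam_spatial         = c(47, 8),
    sam_future          = c(49, 8),
    frontal_thickness   = c(2.55, 0.10),
    parietal_thickness  = c(2.30, 0.10),
    temporal_thickness  = c(2.75, 0.11),
    occipital_thickness = c(2.05, 0.09),
    cingulate_thickness = c(2.50, 0.12),
    hippocampal_volume  = c(7800, 700),
    icv                 = c(1.5e6, 1.4e5),
    global_thickness    = c(2.45, 0.08))
}

#' Default planted group effects for the recall cohort
#'
#' Standardized high-minus-low differences: strong deficits in total and
#' semantic autobiographical memory and cingulate thickness, a null
#' hippocampal effect, zero elsewhere.
#' @return Named numeric vector of Cohen's d values.
#' @export
default_group_effects <- function() {
  c(sam_total = -1.66, sam_semantic = -1.99,
    cingulate_thickness = -1.55, hippocampal_volume = 0)
}

#' Simulate a recall-by-genotype cohort
#'
#' Participants are the extreme tails of a polygenic score distribution
#' (`n_low` lowest, `n_high` highest of a simulated population of
#' `population_n` standard-normal scores, unless `scores` is supplied).
#' Each outcome is generated on the standardized liability scale as
#' `z = b*y + x` (`y` the score, `x` standard-normal noise) plus a
#' high-group shift calibrated against the drawn scores so that the
#' expected total standardized group difference equals the requested
#' Cohen's d; the result is then mapped to plausible natural units.
#' Demographics (sex, APOE isoform, qualification level, age distributions)
#' follow the recall sample's descriptive table.
#'
#' @param n_low,n_high group sizes (defaults 10 low / 6 high).
#' @param group_effects named vector, outcome -> Cohen's d (high minus low);
#'   unnamed outcomes get d = 0. Unknown names are an error.
#' @param b score-phenotype coefficient on the liability scale
#'   (default `sqrt(0.095)`, the variance in case/control status explained
#'   by the score).
#' @param population_n size of the population the tails are drawn from.
#' @param scores optional numeric vector of standardized scores to select
#'   tails from instead of simulating a population.
#' @param age_effects named vector, outcome -> slope per year of (centered)
#'   age on the standardized scale; default plants a negative age slope on
#'   hippocampal volume only.
#' @param seed integer seed.
#'
#' @return A `cohort_table` data.frame: `iid`, `group` (`"low"`/`"high"`),
#'   `prs_z`, `age`, `sex`, `apoe`, `qualification`, and one column per
#'   outcome (see [default_group_effects()] for the planted defaults).
#' @export
sim_recall_cohort <- function(n_low = 10, n_high = 6,
                              group_effects = default_group_effects(),
                              b = sqrt(0.095), population_n = 4504,
                              scores = NULL,
                              age_effects = c(hippocampal_volume = -0.08),
                              seed = NULL) {
  units <- outcome_units()
  outcomes <- rownames(units)
  if (length(group_effects) && is.null(names(group_effects)))
    stop("group_effects must be named")
  unknown <- setdiff(names(group_effects), outcomes)
  if (length(unknown))
    stop("unknown outcome in group_effects: ", paste(unknown, collapse = ", "))
  unknown_a <- setdiff(names(age_effects), outcomes)
  if (length(unknown_a))
    stop("unknown outcome in age_effects: ", paste(unknown_a, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- n_low + n_high

  if (is.null(scores)) scores <- stats::rnorm(population_n)
  o <- order(scores)
  y <- c(scores[o[seq_len(n_low)]],
         scores[rev(o)[seq_len(n_high)]])
  group <- rep(c("low", "high"), c(n_low, n_high))
  hi <- group == "high"

  demo <- recall_demographics(n_low, n_high)
  age <- stats::rnorm(n, demo$age_mean, demo$age_sd)
  age_c <- age - mean(age)

  d_all <- stats::setNames(numeric(length(outcomes)), outcomes)
  d_all[names(group_effects)] <- group_effects
  a_all <- stats::setNames(numeric(length(outcomes)), outcomes)
  a_all[names(age_effects)] <- age_effects

  # shift calibration from the drawn y and ages: the requested d is the
  # TOTAL standardized group difference, so the b*y and age pathways
  # (which both carry group information: tail scores, Table-1 age gap)
  # are subtracted from the target gap, and the within-group SD includes
  # their within-group variance contributions
  pooled_var <- function(v) ((n_low - 1) * stats::var(v[!hi]) +
                               (n_high - 1) * stats::var(v[hi])) / (n - 2)
  vw_y <- pooled_var(y)
  vw_age <- pooled_var(age_c)
  dy <- mean(y[hi]) - mean(y[!hi])
  dage <- mean(age_c[hi]) - mean(age_c[!hi])

  out <- data.frame(iid = sprintf("R%03d", seq_len(n)), group = group,
                    prs_z = y, age = age, sex = demo$sex, apoe = demo$apoe,
                    qualification = demo$qual, stringsAsFactors = FALSE)
  for (nm in outcomes) {
    a <- a_all[nm]
    sd_w <- sqrt(b^2 * vw_y + 1 + a^2 * vw_age)
    shift <- d_all[nm] * sd_w - b * dy - a * dage
    z <- b * y + stats::rnorm(n) + shift * hi + a * age_c
    out[[nm]] <- units[nm, 1] + units[nm, 2] * z
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}
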