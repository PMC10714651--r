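#' Two-sample t-test from raw data
#'
#' Thin wrapper over [stats::t.test()] returning the triple `(t, df, p)`;
#' `variant = "welch"` (default, unequal variances) or `"pooled"`.
#'
#' @param x1,x2 numeric samples (n >= 2 each).
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `t`, `df`, `p`.
#' @export
group_t_test <- function(x1, x2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x1) < 2 || length(x2) < 2) stop("each group needs n >= 2")
  if (stats::var(x1) == 0 && stats::var(x2) == 0)
    stop("zero variance in both groups")
  ht <- stats::t.test(x1, x2, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample t-test from printed summary statistics
#'
#' Computes the identical statistic from `(mean, sd, n)` per group, for
#' reproducing tests reported in descriptive tables.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `t`, `df`, `p`.
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 == 0 && sd2 == 0) stop("zero variance in both groups")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (variant == "welch") {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tt <- (mean1 - mean2) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Pearson chi-square test for contingency tables
#'
#' `correction = "auto"` (default) applies the Yates continuity correction
#' for 2x2 tables only — the convention that reproduces descriptive-table
#' statistics; `"yates"` forces it (it only applies to 2x2), `"none"`
#' disables it. The correction truncates each `|O - E| - 0.5` at zero.
#'
#' @param table matrix of non-negative counts, at least 2x2.
#' @param correction `"auto"`, `"yates"` or `"none"`.
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_test <- function(table, correction = c("auto", "yates", "none")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  correct <- switch(correction,
                    auto = nrow(table) == 2 && ncol(table) == 2,
                    yates = TRUE, none = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Residualize an outcome on covariates
#'
#' Ordinary-least-squares residuals of `y` on an intercept plus the given
#' covariates. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param y numeric outcome.
#' @param covariates data.frame or matrix of covariates (factors allowed;
#'   expanded via [stats::model.matrix()]).
#' @return Numeric residuals, same length as `y`.
#' @export
adjust_covariates <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  if (length(y) < ncol(covariates) + 2)
    stop("need at least ncol(covariates) + 2 observations")
  X <- stats::model.matrix(~ ., data = covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  stats::lm.fit(X, y)$residuals
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(x1) - mean(x2)) / s_p` with the
#' pooled SD `s_p^2 = (SS1 + SS2) / df`. The default `df = n1 + n2 - 2`;
#' when the inputs are OLS residuals on `p` covariates, passing
#' `df = n1 + n2 - 2 - p` keeps the pooled variance unbiased.
#' `hedges = TRUE` applies the exact small-sample bias correction
#' `J(df) = Gamma(df/2) / (sqrt(df/2) Gamma((df-1)/2))`.
#'
#' @param x1,x2 numeric samples; by reporting convention `x1` is the
#'   high-score group, so negative d means a deficit in that group.
#' @param df pooled-variance degrees of freedom.
#' @param hedges apply the unbiasing correction.
#' @return Cohen's d (scalar).
#' @export
cohens_d <- function(x1, x2, df = length(x1) + length(x2) - 2,
                     hedges = FALSE) {
  if (length(x1) < 2 || length(x2) < 2) stop("each group needs n >= 2")
  ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  sp <- sqrt(ss / df)
  if (sp == 0) stop("zero pooled SD")
  d <- (mean(x1) - mean(x2)) / sp
  if (hedges) d <- d * hedges_j(df)
  d
}

hedges_j <- function(df) {
  exp(lgamma(df / 2) - lgamma((df - 1) / 2)) / sqrt(df / 2)
}

#' Confidence interval for Cohen's d
#'
#' `method = "nct"` (default) pivots the noncentral-t CDF on the
#' noncentrality parameter of `t = d * sqrt(n1 n2 / (n1 + n2))` and maps
#' back to the d scale; `"normal"` uses the large-sample
#' `d +/- z * sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param d observed Cohen's d.
#' @param n1,n2 group sizes (>= 2).
#' @param level confidence level in (0, 1).
#' @param method `"nct"` or `"normal"`.
#' @param df degrees of freedom for the nct pivot (default `n1 + n2 - 2`).
#' @return Numeric `c(lo, hi)`.
#' @export
d_confint <- function(d, n1, n2, level = 0.95,
                      method = c("nct", "normal"), df = n1 + n2 - 2) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  a <- (1 - level) / 2
  f <- sqrt(n1 * n2 / (n1 + n2))
  if (method == "normal") {
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
    return(d + c(-1, 1) * stats::qnorm(1 - a) * se)
  }
  tt <- d * f
  wide <- abs(tt) + 20
  # pnt warns about its ~1e-12 precision limit; far below the CI tolerance
  pivot <- function(target)
    stats::uniroot(function(ncp)
      suppressWarnings(stats::pt(tt, df, ncp)) - target,
      interval = c(-wide, wide), tol = 1e-10)$root
  c(pivot(1 - a), pivot(a)) / f
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' via [stats::p.adjust()].
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Default outcome families for [compare_groups()]
#'
#' Two FDR families mirroring the two outcome panels: the autobiographical
#' memory battery (total + four sub-domains, adjusted for age and sex) and
#' the structural MRI panel (five lobar thicknesses + hippocampal volume,
#' adjusted for age, sex and global mean thickness).
#' @return Named list; each element has `outcomes` and `covariates`.
#' @export
default_families <- function() {
  list(
    SAM = list(
      outcomes = c("sam_total", "sam_episodic", "sam_semantic",
                   "sam_spatial", "sam_future"),
      covariates = c("age", "sex")),
    MRI = list(
      outcomes = c("frontal_thickness", "parietal_thickness",
                   "temporal_thickness", "occipital_thickness",
                   "cingulate_thickness", "hippocampal_volume"),
      covariates = c("age", "sex", "global_thickness")))
}

#' Group comparison across outcome families
#'
#' For every outcome: residualize on the family's covariates, compute
#' Cohen's d (high minus low, pooled SD with residual degrees of freedom),
#' its confidence interval, and a two-sample t-test on the residuals;
#' then BH-FDR within each family.
#'
#' @param cohort a `cohort_table` with a `group` column (`"low"`/`"high"`).
#' @param families named list as from [default_families()].
#' @param ci_method passed to [d_confint()].
#' @param hedges apply the small-sample correction to d.
#' @param t_variant passed to [group_t_test()].
#' @return data.frame of class `comparison_result`: `family`, `outcome`,
#'   `d`, `ci_lo`, `ci_hi`, `t`, `df`, `p`, `p_fdr`, `covariates`.
#' @export
compare_groups <- function(cohort, families = default_families(),
                           ci_method = c("nct", "normal"), hedges = FALSE,
                           t_variant = c("welch", "pooled")) {
  ci_method <- match.arg(ci_method)
  t_variant <- match.arg(t_variant)
  stopifnot("group" %in% names(cohort),
            all(cohort$group %in% c("low", "high")))
  hi <- cohort$group == "high"
  n1 <- sum(hi); n2 <- sum(!hi)
  rows <- list()
  for (fam in names(families)) {
    f <- families[[fam]]
    missing_out <- setdiff(f$outcomes, names(cohort))
    if (length(missing_out))
      stop("outcomes absent from cohort: ", paste(missing_out, collapse = ", "))
    ps <- numeric(0)
    fam_rows <- list()
    for (out in f$outcomes) {
      y <- cohort[[out]]
      if (length(f$covariates)) {
        res <- adjust_covariates(y, cohort[f$covariates])
        p_cov <- ncol(stats::model.matrix(~ ., cohort[f$covariates])) - 1
      } else {
        res <- y - mean(y)
        p_cov <- 0
      }
      dfd <- n1 + n2 - 2 - p_cov
      d <- cohens_d(res[hi], res[!hi], df = dfd, hedges = hedges)
      ci <- d_confint(d, n1, n2, method = ci_method, df = dfd)
      tt <- group_t_test(res[hi], res[!hi], variant = t_variant)
      fam_rows[[out]] <- data.frame(
        family = fam, outcome = out, d = d, ci_lo = ci[1], ci_hi = ci[2],
        t = tt$t, df = tt$df, p = tt$p, p_fdr = NA_real_,
        covariates = paste(f$covariates, collapse = "+"),
        stringsAsFactors = FALSE)
      ps <- c(ps, tt$p)
    }
    fr <- do.call(rbind, fam_rows)
    fr$p_fdr <- bh_fdr(fr$p)
    rows[[fam]] <- fr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Covariate-adjusted association between two outcomes
#'
#' t-statistic and p-value of the `y2` slope in the OLS regression of `y1`
#' on an intercept, `y2` and the covariates.
#'
#' @param y1,y2 numeric outcomes (paired).
#' @param covariates optional data.frame of covariates.
#' @return list with `t`, `p`, `estimate` (the slope), `df`.
#' @export
association <- function(y1, y2, covariates = NULL) {
  dat <- data.frame(.y1 = y1, .y2 = y2)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  if (nrow(dat) < ncol(dat) + 2) stop("too few complete observations")
  fit <- stats::lm(.y1 ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)$coefficients
  list(t = sm[".y2", "t value"], p = sm[".y2", "Pr(>|t|)"],
       estimate = sm[".y2", "Estimate"], df = fit$df.residual)
}

#' Pool regional brain measures into lobes
#'
#' Thickness regions are averaged (optionally surface-area-weighted);
#' volume regions are summed. Every region named in the map must be a
#' column of the table; table columns not in the map are left untouched
#' only if non-regional (`id` etc.) — unmapped regional columns are
#' reported in the error.
#'
#' @param region_table data.frame: one row per participant, an `id`
#'   column plus one numeric column per region.
#' @param lobe_map data.frame with columns `region`, `lobe`, `measure`
#'   (`"thickness"` or `"volume"`) and, for area weighting, `area`.
#' @param weighting `"unweighted"` or `"area"` (thickness only).
#' @return data.frame: `id` plus one column per lobe.
#' @export
pool_regions <- function(region_table, lobe_map,
                         weighting = c("unweighted", "area")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("region", "lobe", "measure") %in% names(lobe_map)))
  missing_r <- setdiff(lobe_map$region, names(region_table))
  if (length(missing_r))
    stop("mapped regions absent from table: ",
         paste(missing_r, collapse = ", "))
  regional <- setdiff(names(region_table), c("id", lobe_map$region))
  regional <- regional[vapply(region_table[regional], is.numeric, logical(1))]
  if (length(regional))
    stop("unmapped regional columns: ", paste(regional, collapse = ", "))
  out <- data.frame(id = region_table$id, stringsAsFactors = FALSE)
  for (lb in unique(lobe_map$lobe)) {
    rows <- lobe_map[lobe_map$lobe == lb, , drop = FALSE]
    vals <- as.matrix(region_table[rows$region])
    if (all(rows$measure == "volume")) {
      out[[lb]] <- rowSums(vals)
    } else {
      w <- if (weighting == "area") {
        if (is.null(rows$area)) stop("area weighting needs an 'area' column")
        rows$area / sum(rows$area)
      } else rep(1 / nrow(rows), nrow(rows))
      out[[lb]] <- as.vector(vals %*% w)
    }
  }
  out
}
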