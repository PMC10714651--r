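#' Selection rules for the power simulation
#'
#' `extreme_selection(k_low, k_high)`: the k_low lowest and k_high highest
#' scores of the whole simulated population (how the recall sample's 10/6
#' design is modelled by default). `threshold_selection()`: k random draws
#' per tail among individuals beyond `min_sd` SDs, emulating recruitment
#' from a tail pool rather than taking the very most extreme.
#' `random_selection(n)`: a simple random sample (the opportunistic
#' design).
#'
#' @param k_low,k_high tail sizes.
#' @param min_sd tail cutoff in SD units (threshold rule).
#' @param n sample size (random rule).
#' @return A list of class `rbg_selection`.
#' @name selection_rules
NULL

#' @rdname selection_rules
#' @export
extreme_selection <- function(k_low = 10, k_high = 6) {
  stopifnot(k_low >= 0, k_high >= 0, k_low + k_high >= 4)
  structure(list(type = "extreme", k_low = k_low, k_high = k_high),
            class = "rbg_selection")
}

#' @rdname selection_rules
#' @export
threshold_selection <- function(k_low = 10, k_high = 6, min_sd = 2) {
  stopifnot(k_low >= 0, k_high >= 0, k_low + k_high >= 4, min_sd > 0)
  structure(list(type = "threshold", k_low = k_low, k_high = k_high,
                 min_sd = min_sd), class = "rbg_selection")
}

#' @rdname selection_rules
#' @export
random_selection <- function(n) {
  stopifnot(n >= 4)
  structure(list(type = "random", n = n), class = "rbg_selection")
}

#' Design specification for the recall-by-genotype power analysis
#'
#' The generative model is `z = b*y + x` with `y` (the standardized
#' polygenic score) and `x` independent standard normals; `b^2` is the
#' phenotype variance explained by the score, so the population
#' correlation between score and phenotype is `b / sqrt(1 + b^2)`.
#' The default `b = sqrt(0.095)` is the square root of the variance in
#' case/control status explained by the AD polygenic score in under-80s
#' (AUC 0.677, R-squared 0.095).
#'
#' @param b score-phenotype coefficient (>= 0).
#' @param population_n size of the population each replicate simulates.
#' @param selection a selection rule, see [selection_rules].
#' @param alpha two-sided test level.
#' @param reps Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(b = sqrt(0.095), population_n = 4504,
                        selection = extreme_selection(10, 6),
                        alpha = 0.05, reps = 1000, seed = NULL) {
  stopifnot(b >= 0, alpha > 0, alpha < 1, reps >= 1, population_n >= 4,
            inherits(selection, "rbg_selection"))
  n_sel <- switch(selection$type, random = selection$n,
                  selection$k_low + selection$k_high)
  if (n_sel > population_n) stop("selection size exceeds population_n")
  structure(list(b = b, population_n = population_n, selection = selection,
                 alpha = alpha, reps = reps, seed = seed),
            class = "design_spec")
}

#' Simulate one population under the design's generative model
#'
#' @param spec a [design_spec()].
#' @return list with numeric vectors `y` (scores) and `z` (phenotypes),
#'   each of length `population_n`.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  y <- stats::rnorm(spec$population_n)
  x <- stats::rnorm(spec$population_n)
  list(y = y, z = spec$b * y + x)
}

select_indices <- function(sel, y) {
  switch(sel$type,
    extreme = {
      o <- order(y)
      c(o[seq_len(sel$k_low)], rev(o)[seq_len(sel$k_high)])
    },
    threshold = {
      lo <- which(y <= -sel$min_sd)
      hi <- which(y >= sel$min_sd)
      c(sample_safe(lo, sel$k_low), sample_safe(hi, sel$k_high))
    },
    random = sample.int(length(y), sel$n))
}

# sample k without replacement, or everything if the pool is smaller
sample_safe <- function(pool, k) {
  if (length(pool) <= k) pool else pool[sample.int(length(pool), k)]
}

# two-sided Pearson correlation test rejection at level alpha, exact t
# reference with df = n - 2 (avoids cor.test overhead inside tight loops)
pearson_reject <- function(a, b, alpha) {
  n <- length(a)
  r <- stats::cor(a, b)
  if (is.na(r)) return(FALSE)
  if (abs(r) >= 1) return(TRUE)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), n - 2) < alpha
}

#' Monte-Carlo power of a recall or opportunistic design
#'
#' Per replicate: simulate the population, apply the selection rule, and
#' run a two-sided Pearson correlation test of score versus phenotype in
#' the selected sample at level alpha. Power is the rejection proportion;
#' its binomial Monte-Carlo standard error is reported alongside.
#'
#' @param spec a [design_spec()].
#' @return A `power_estimate`: list with `power`, `mc_se`, `reps`, `spec`.
#' @export
estimate_power <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sel <- spec$selection
  n_sel <- switch(sel$type, random = sel$n, sel$k_low + sel$k_high)
  if (n_sel < 4) stop("selected sample must have >= 4 individuals")
  rej <- logical(spec$reps)
  for (r in seq_len(spec$reps)) {
    y <- stats::rnorm(spec$population_n)
    z <- spec$b * y + stats::rnorm(spec$population_n)
    idx <- select_indices(sel, y)
    rej[r] <- if (length(idx) >= 4) pearson_reject(y[idx], z[idx], spec$alpha)
              else NA
  }
  power <- mean(rej, na.rm = TRUE)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / sum(!is.na(rej))),
                 reps = sum(!is.na(rej)), spec = spec),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power = %.3f (MC SE %.4f, %d replicates)\n",
              x$power, x$mc_se, x$reps))
  invisible(x)
}

#' Analytic power of a Pearson correlation test (Fisher-z approximation)
#'
#' `power = Phi(sqrt(n-3) atanh(r) - z_{1-alpha/2}) +
#'          Phi(-sqrt(n-3) atanh(r) - z_{1-alpha/2})`.
#'
#' @param r population correlation, |r| < 1.
#' @param n sample size (>= 4).
#' @param alpha two-sided level.
#' @return Power in `[0, 1]`; vectorized over `r` and `n`.
#' @export
analytic_power_corr <- function(r, n, alpha = 0.05) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  if (any(n < 4)) stop("n must be >= 4")
  za <- stats::qnorm(1 - alpha / 2)
  s <- sqrt(n - 3) * atanh(r)
  stats::pnorm(s - za) + stats::pnorm(-s - za)
}

#' Effective opportunistic sample size
#'
#' The smallest simple-random-sample size whose power (same `b`, `alpha`)
#' comes within `tolerance_pts` percentage points of the extreme design's
#' estimated power. The analytic Fisher-z curve brackets the answer, which
#' is then refined by simulation around the bracket.
#'
#' @param spec_extreme a [design_spec()] with an extreme or threshold
#'   selection rule.
#' @param tolerance_pts tolerance, in percentage points (> 0).
#' @param refine_reps Monte-Carlo replicates for the simulation refinement.
#' @param n_max largest n searched (default the population size).
#' @return A list: `n_effective`, `extreme_power`, `target_power`,
#'   `random_power` (simulated power at the returned n).
#' @export
effective_n <- function(spec_extreme, tolerance_pts = 5,
                        refine_reps = 1000, n_max = NULL) {
  stopifnot(inherits(spec_extreme, "design_spec"), tolerance_pts > 0)
  if (spec_extreme$selection$type == "random")
    stop("spec_extreme must use an extreme or threshold selection rule")
  if (is.null(n_max)) n_max <- spec_extreme$population_n
  pe <- estimate_power(spec_extreme)
  target <- pe$power - tolerance_pts / 100
  r <- spec_extreme$b / sqrt(1 + spec_extreme$b^2)
  sim_power <- function(n) {
    sp <- design_spec(b = spec_extreme$b,
                      population_n = spec_extreme$population_n,
                      selection = random_selection(n),
                      alpha = spec_extreme$alpha, reps = refine_reps)
    estimate_power(sp)$power
  }
  if (target <= spec_extreme$alpha)
    return(list(n_effective = 4L, extreme_power = pe$power,
                target_power = target, random_power = sim_power(4)))
  if (analytic_power_corr(r, n_max, spec_extreme$alpha) < target)
    stop("target power unreachable within n_max; b is too small")
  lo <- 4L; hi <- as.integer(n_max)
  while (hi - lo > 1L) {                       # analytic bisection
    mid <- (lo + hi) %/% 2L
    if (analytic_power_corr(r, mid, spec_extreme$alpha) >= target)
      hi <- mid else lo <- mid
  }
  # simulation refinement: walk to the smallest n whose simulated power
  # reaches the target, scanning outwards from the analytic solution
  n <- hi
  p_n <- sim_power(n)
  if (p_n >= target) {
    while (n > 4L) {
      p_dn <- sim_power(n - 1L)
      if (p_dn < target) break
      n <- n - 1L; p_n <- p_dn
    }
  } else {
    while (n < n_max && p_n < target) {
      n <- n + 1L
      p_n <- sim_power(n)
    }
  }
  list(n_effective = n, extreme_power = pe$power, target_power = target,
       random_power = p_n)
}

#' Convert an odds ratio to Cohen's d (logit method)
#'
#' `d = ln(OR) * sqrt(3) / pi`, the standard logistic-distribution
#' conversion. For OR = 30.58 this gives d = 1.886.
#'
#' @param odds_ratio positive odds ratio.
#' @return Cohen's d; vectorized.
#' @export
or_to_d <- function(odds_ratio) {
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0")
  log(odds_ratio) * sqrt(3) / pi
}

#' Two-sample t-test power (noncentral t)
#'
#' `ncp = d * sqrt(n1 n2 / (n1 + n2))`, `df = n1 + n2 - 2`,
#' `power = P(|T'| > t_{1-alpha/2, df})`.
#'
#' @param d Cohen's d.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided level.
#' @return Power; vectorized over `d`.
#' @export
two_sample_t_power <- function(d, n1, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  q <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(q, df, ncp) + stats::pt(-q, df, ncp)
}

#' Decile odds ratio with a Woolf confidence interval
#'
#' Case/control odds ratio contrasting two score deciles:
#' `OR = (cases_high * controls_low) / (cases_low * controls_high)`, CI
#' from `log OR +/- z * sqrt(sum of reciprocal cell counts)`. If any cell
#' is zero, a 0.5 continuity correction is added to every cell (flagged in
#' the result).
#'
#' @param deciles integer decile per sample (1..10).
#' @param status binary outcome per sample (0/1 or logical).
#' @param low,high decile ids to contrast (low = reference).
#' @param level confidence level.
#' @return list: `or`, `ci` (length 2), `log_or`, `se`, `table` (2x2),
#'   `continuity` (logical).
#' @export
decile_or <- function(deciles, status, low = 1, high = 10, level = 0.95) {
  stopifnot(length(deciles) == length(status))
  status <- as.integer(status)
  in_low <- deciles == low; in_high <- deciles == high
  if (!any(in_low) || !any(in_high)) stop("empty decile")
  tab <- matrix(c(sum(status[in_high] == 1), sum(status[in_high] == 0),
                  sum(status[in_low] == 1), sum(status[in_low] == 0)),
                2, 2, dimnames = list(c("case", "control"),
                                      c("high", "low")))
  cc <- any(tab == 0)
  t2 <- tab + if (cc) 0.5 else 0
  log_or <- log(t2["case", "high"] * t2["control", "low"] /
                  (t2["case", "low"] * t2["control", "high"]))
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(log_or), ci = exp(log_or + c(-1, 1) * z * se),
       log_or = log_or, se = se, table = tab, continuity = cc)
}
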