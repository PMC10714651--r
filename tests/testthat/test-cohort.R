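test_that("summary t-test reproduces the descriptive-table statistics", {
  # identical summaries
  same <- summary_t_test(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # qualification level: low 5.1 +/- 1.96 (n=10) vs high 5 +/- 2.00 (n=6);
  # printed -0.09 came from unrounded raw data
  q_w <- summary_t_test(5, 2.00, 6, 5.1, 1.96, 10, variant = "welch")
  q_p <- summary_t_test(5, 2.00, 6, 5.1, 1.96, 10, variant = "pooled")
  expect_lt(abs(q_w$t), 0.15)
  expect_lt(abs(q_p$t), 0.15)
  # age: high 64.3 +/- 6.62 (n=6) vs low 69.2 +/- 6.01 (n=10) -> ~ -1.47
  a <- summary_t_test(64.3, 6.62, 6, 69.2, 6.01, 10, variant = "welch")
  expect_equal(a$t, -1.47, tolerance = 0.05)
  expect_error(summary_t_test(1, 0, 5, 1, 0, 5), "zero variance")
})

test_that("raw-data and summary t-tests agree", {
  set.seed(61)
  x1 <- rnorm(12, 1); x2 <- rnorm(9)
  for (v in c("welch", "pooled")) {
    a <- group_t_test(x1, x2, variant = v)
    b <- summary_t_test(mean(x1), sd(x1), 12, mean(x2), sd(x2), 9,
                        variant = v)
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
  }
})

test_that("chi-square under 'auto' reproduces all three descriptive-table values", {
  sex <- matrix(c(4, 7, 2, 3), 2)            # high/low x F/M
  expect_equal(chisq_test(sex)$chi2, 0, tolerance = 0.005)
  expect_equal(chisq_test(sex)$p, 1, tolerance = 0.005)
  apoe <- matrix(c(1, 0, 5, 8, 0, 2), 2)     # high/low x e2e3,e3e3,e3e4
  expect_equal(chisq_test(apoe)$chi2, 2.87, tolerance = 0.005)
  edu <- matrix(c(1, 2, 1, 1, 3, 5, 1, 2), 2)  # high/low x L2,L3,L6,L7
  expect_equal(chisq_test(edu)$chi2, 0.178, tolerance = 0.005)
  expect_error(chisq_test(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(chisq_test(matrix(c(-1, 1, 1, 2), 2)), "non-negative")
})

test_that("covariate residualization satisfies the normal equations", {
  set.seed(62)
  n <- 40
  cov <- data.frame(age = rnorm(n, 70, 5), sex = sample(c("F", "M"), n, TRUE))
  y <- rnorm(n)
  r <- adjust_covariates(y, cov)
  X <- model.matrix(~ ., cov)
  expect_lt(max(abs(crossprod(X, r))), 1e-10)
  # y exactly linear in a covariate -> residuals ~ 0
  y2 <- 2 * cov$age - 3
  expect_lt(max(abs(adjust_covariates(y2, cov))), 1e-8)
  # orthogonal covariate -> centered y
  ortho <- data.frame(c1 = rep(c(-1, 1), n / 2))
  y3 <- rep(c(5, 5, 7, 7), n / 4)
  expect_equal(adjust_covariates(y3, ortho), y3 - mean(y3) -
                 ortho$c1 * as.vector(coef(lm(y3 ~ ortho$c1))[2]),
               tolerance = 1e-10, ignore_attr = TRUE)
  dup <- data.frame(a = cov$age, b = cov$age)
  expect_error(adjust_covariates(y, dup), "collinear")
})

test_that("Cohen's d matches an independent formula and fixes its conventions", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(rnorm(500, 1, 1), rnorm(500, 0, 1)), 1,
               tolerance = 0.15)
  set.seed(63)
  x1 <- rnorm(8); x2 <- rnorm(11)
  sp <- sqrt(((8 - 1) * var(x1) + (11 - 1) * var(x2)) / (8 + 11 - 2))
  expect_equal(cohens_d(x1, x2), (mean(x1) - mean(x2)) / sp,
               tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("noncentral-t CIs reproduce the reported lower bounds", {
  ci1 <- d_confint(-1.66, 10, 6)
  expect_equal(ci1[1], -2.82, tolerance = 0.05)
  expect_equal(ci1[2], -0.46, tolerance = 0.05)
  ci2 <- d_confint(-1.99, 10, 6)
  expect_equal(ci2[1], -3.21, tolerance = 0.05)
  # nct and normal lower bounds agree within 0.1 for |d| <= 2 at n = (10,6)
  for (d in seq(-2, 2, 0.5)) {
    lo_nct <- d_confint(d, 10, 6, method = "nct")[1]
    lo_norm <- d_confint(d, 10, 6, method = "normal")[1]
    expect_lt(abs(lo_nct - lo_norm), 0.1)
  }
  # symmetric about 0 for d = 0, equal n
  ci0 <- d_confint(0, 8, 8)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-6)
  expect_error(d_confint(1, 10, 6, level = 1.2), "level")
})

test_that("BH adjustment matches the brute-force step-up and its invariances", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(64)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.5)), "p-values")
})

test_that("compare_groups returns coherent families, CIs and FDR", {
  co <- sim_recall_cohort(seed = 65)
  res <- compare_groups(co)
  expect_s3_class(res, "comparison_result")
  expect_equal(nrow(res), 11)
  expect_true(all(res$ci_lo <= res$d & res$d <= res$ci_hi))
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  # d sign matches the high-minus-low mean difference on residuals
  hi <- co$group == "high"
  r <- adjust_covariates(co$sam_total, co[c("age", "sex")])
  expect_equal(sign(res$d[res$outcome == "sam_total"]),
               sign(mean(r[hi]) - mean(r[!hi])))
  expect_error(compare_groups(co, families = list(
    f = list(outcomes = "absent_outcome", covariates = character(0)))),
    "absent")
})

test_that("a null cohort yields roughly uniform p-values from compare_groups", {
  set.seed(66)
  fam <- list(all = list(outcomes = c("sam_total", "cingulate_thickness"),
                         covariates = c("age", "sex")))
  ps <- replicate(150, {
    co <- sim_recall_cohort(group_effects = c(sam_total = 0),
                            age_effects = c(sam_total = 0))
    compare_groups(co, families = fam, ci_method = "normal")$p[1]
  })
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.06)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("planted age slope is recovered while the group effect stays null", {
  set.seed(67)
  hits_group <- hits_age <- logical(120)
  for (i in seq_len(120)) {
    co <- sim_recall_cohort(age_effects = c(hippocampal_volume = -0.15))
    fit <- summary(lm(scale(hippocampal_volume) ~ age + I(group == "high"),
                      data = co))$coefficients
    hits_age[i] <- fit["age", "Pr(>|t|)"] < 0.05 &&
      fit["age", "Estimate"] < 0
    hi <- co$group == "high"
    hits_group[i] <- group_t_test(co$hippocampal_volume[hi],
                                  co$hippocampal_volume[!hi])$p < 0.05
  }
  expect_gt(mean(hits_age), 0.5)     # age signal mostly detected
  expect_lt(mean(hits_group), 0.25)  # raw group difference stays null
})

test_that("association recovers a planted partial relationship", {
  set.seed(68)
  n <- 200
  cov <- data.frame(age = rnorm(n))
  y2 <- rnorm(n) + 0.5 * cov$age
  y1 <- 0.4 * y2 + 0.3 * cov$age + rnorm(n)
  res <- association(y1, y2, cov)
  expect_lt(res$p, 0.001)
  expect_equal(res$estimate, 0.4, tolerance = 0.2)
  # y1 = y2 -> p ~ 0; independent -> uniform-ish p
  expect_lt(association(y2, y2 + rnorm(n, 0, 1e-8))$p, 1e-10)
  p_null <- replicate(100, association(rnorm(30), rnorm(30))$p)
  expect_gt(mean(p_null > 0.05), 0.8)
})

test_that("region pooling averages thickness and sums volume, flagging unmapped columns", {
  tab <- data.frame(id = c("p1", "p2"),
                    r1 = c(2.0, 2.2), r2 = c(2.4, 2.6), r3 = c(3.0, 3.2),
                    hip_l = c(3000, 3100), hip_r = c(3200, 3050))
  map <- data.frame(region = c("r1", "r2", "r3", "hip_l", "hip_r"),
                    lobe = c("cingulate", "cingulate", "frontal",
                             "hippocampus", "hippocampus"),
                    measure = c("thickness", "thickness", "thickness",
                                "volume", "volume"),
                    area = c(100, 300, 200, NA, NA),
                    stringsAsFactors = FALSE)
  out <- pool_regions(tab, map)
  expect_equal(out$cingulate, c(2.2, 2.4))            # plain mean
  expect_equal(out$frontal, c(3.0, 3.2))              # single region
  expect_equal(out$hippocampus, c(6200, 6150))        # volumes summed
  outw <- pool_regions(tab, map, weighting = "area")
  expect_equal(outw$cingulate, (100 * tab$r1 + 300 * tab$r2) / 400)
  expect_error(pool_regions(tab[-2], map), "absent")
  tab$extra <- c(1, 2)
  expect_error(pool_regions(tab, map), "unmapped")
})
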