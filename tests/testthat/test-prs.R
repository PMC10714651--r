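make_weights <- function(G, beta, freq = NULL) {
  data.frame(id = G$variants$id, beta = beta,
             freq = if (is.null(freq)) allele_freq(G) else freq,
             stringsAsFactors = FALSE)
}

test_that("harmonization flips swapped alleles and drops ambiguous variants", {
  v <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                  id = c("s1", "s2", "s3", "s4"),
                  a1 = c("A", "G", "A", "C"), a2 = c("G", "A", "T", "A"),
                  stringsAsFactors = FALSE)
  ss <- data.frame(chrom = "1", pos = v$pos, id = v$id,
                   a1 = c("A", "A", "A", "C"), a2 = c("G", "G", "T", "T"),
                   beta = c(0.5, 0.5, 0.5, 0.5), se = 0.1, p = 0.01,
                   freq = c(0.3, 0.3, 0.3, 0.3), info = 1,
                   stringsAsFactors = FALSE)
  w <- harmonize(v, ss)
  expect_equal(w$id, c("s1", "s2"))        # s3 A/T ambiguous, s4 mismatched
  expect_equal(w$beta, c(0.5, -0.5))       # s2 swapped -> negated
  expect_equal(w$freq, c(0.3, 0.7))
  expect_equal(attr(w, "n_ambiguous"), 1)
  expect_equal(attr(w, "n_mismatched"), 1)
  expect_error(harmonize(v, ss[0, ]), "overlap")
})

test_that("allele-flip invariance: recoding a variant leaves standardized scores unchanged", {
  G <- sim_genotypes(80, 20, maf_range = c(0.1, 0.4), seed = 41)
  w <- make_weights(G, rnorm(20))
  s1 <- compute_prs(G, w)
  # flip variant 5 in the panel: complement dosage, swap alleles
  G2 <- G
  G2$dosages[, 5] <- 2L - G2$dosages[, 5]
  G2$variants[5, c("a1", "a2")] <- G2$variants[5, c("a2", "a1")]
  w2 <- w
  w2$beta[5] <- -w2$beta[5]
  w2$freq[5] <- 1 - w2$freq[5]
  s2 <- compute_prs(G2, w2)
  expect_equal(s1$z, s2$z, tolerance = 1e-10)
  expect_identical(s1$decile, s2$decile)
})

test_that("clumping follows the greedy rule and matches the naive oracle", {
  # two correlated variants 500 kb apart: only the smaller p survives
  ss <- data.frame(chrom = "1", pos = c(1e6, 1.5e6), id = c("a", "b"),
                   a1 = "A", a2 = "G", p = c(1e-8, 1e-4),
                   stringsAsFactors = FALSE)
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_identical(clump(ss, r2), "a")
  # independent variants: everything under the p gate is retained
  r0 <- diag(2); dimnames(r0) <- dimnames(r2)
  expect_setequal(clump(ss, r0), c("a", "b"))
  expect_length(clump(ss, r0, clump_config(p_threshold = 1e-9)), 0)
  # random instances vs the independent naive implementation
  for (seed in 1:20) {
    pan <- random_panel(sample(4:12, 1), seed + 100)
    cfg <- clump_config(window_kb = 1000, r2_threshold = 0.3,
                        p_threshold = 0.6)
    expect_identical(clump(pan$ss, pan$r2, cfg),
                     clump_oracle(pan$ss, pan$r2, 1000, 0.3, 0.6))
  }
})

test_that("no retained clump pair within the window exceeds the r2 threshold", {
  pan <- random_panel(12, 7)
  cfg <- clump_config(window_kb = 1000, r2_threshold = 0.3, p_threshold = 1)
  kept <- clump(pan$ss, pan$r2, cfg)
  sub <- pan$ss[match(kept, pan$ss$id), ]
  for (i in seq_along(kept)) for (j in seq_len(i - 1)) {
    if (sub$chrom[i] == sub$chrom[j] &&
        abs(sub$pos[i] - sub$pos[j]) <= 1e6)
      expect_lte(pan$r2[kept[i], kept[j]], 0.3)
  }
})

test_that("region exclusion is half-open and ignores unknown chromosomes", {
  v <- data.frame(chrom = c("19", "19", "6", "1"),
                  pos = c(45e6, 46.5e6, 30e6, 45e6),
                  id = c("in_apoe", "at_end", "in_mhc", "other_chrom"),
                  stringsAsFactors = FALSE)
  out <- exclude_regions(v, region_mask(c("apoe", "mhc")))
  expect_setequal(out$id, c("at_end", "other_chrom"))
  expect_equal(attr(out, "n_masked"), 2)
})

test_that("region exclusion and clumping commute on non-overlapping regions", {
  pan <- random_panel(12, 8)
  pan$ss$chrom <- "19"
  pan$ss$pos <- sort(sample(c(44e6:44.3e6, 47e6:48e6), 12))
  pan$ss$pos[1:4] <- sort(sample(4.45e7:4.64e7, 4))  # inside APOE
  pan$ss <- pan$ss[order(pan$ss$pos), ]
  pan$ss$id <- sprintf("v%02d", 1:12)
  dimnames(pan$r2) <- list(pan$ss$id, pan$ss$id)
  cfg <- clump_config(window_kb = 100, r2_threshold = 0.3, p_threshold = 1)
  a <- clump(exclude_regions(pan$ss, region_mask("apoe")), pan$r2, cfg)
  b <- clump(pan$ss, pan$r2, cfg)
  b <- b[b %in% exclude_regions(pan$ss, region_mask("apoe"))$id]
  # same retained set when masked variants sit in their own window
  expect_setequal(a, b)
})

test_that("PRS equals a direct dot-product recomputation and standardizes exactly", {
  G <- sim_genotypes(50, 30, maf_range = c(0.1, 0.5), seed = 42)
  beta <- rnorm(30)
  w <- make_weights(G, beta)
  s <- compute_prs(G, w)
  manual <- vapply(seq_len(50), function(i)
    sum(beta * G$dosages[i, ]), numeric(1))
  expect_equal(s$raw, manual, tolerance = 1e-12)
  expect_equal(mean(s$z), 0, tolerance = 1e-8)
  expect_equal(sd(s$z), 1, tolerance = 1e-8)
  expect_equal(attr(s, "n_variants"), 30)
  # all-zero betas give all-zero raw scores
  expect_true(all(compute_prs(G, make_weights(G, rep(0, 30)))$raw == 0))
  # single variant with beta 1: raw scores equal dosages
  s1 <- compute_prs(G, make_weights(G, c(1, rep(0, 29))))
  expect_equal(s1$raw, as.numeric(G$dosages[, 1]))
  expect_error(compute_prs(G, w[0, ]), "empty")
})

test_that("missing-dosage policies: mean imputation and rescaled omission", {
  G <- sim_genotypes(100, 10, maf_range = c(0.2, 0.4), missing_rate = 0.1,
                     seed = 43)
  beta <- rnorm(10)
  w <- make_weights(G, beta)
  s_imp <- compute_prs(G, w, missing_policy = "mean_impute")
  f <- w$freq
  manual <- vapply(seq_len(100), function(i) {
    d <- G$dosages[i, ]
    d[is.na(d)] <- 2 * f[is.na(d)]
    sum(beta * d)
  }, numeric(1))
  expect_equal(s_imp$raw, manual, tolerance = 1e-12)
  s_om <- compute_prs(G, w, missing_policy = "omit")
  manual_om <- vapply(seq_len(100), function(i) {
    d <- G$dosages[i, ]
    obs <- !is.na(d)
    sum(beta[obs] * d[obs]) * 10 / sum(obs)
  }, numeric(1))
  expect_equal(s_om$raw, manual_om, tolerance = 1e-12)
})

test_that("deciles are balanced, ordered, and ties go to the lower bin", {
  x <- data.frame(iid = sprintf("i%03d", 1:100), raw = rnorm(100))
  x$z <- scale(x$raw)[, 1]
  d <- rbgkit:::decile_bin(x$raw)
  expect_equal(as.integer(table(d)), rep(10L, 10))
  expect_equal(d[order(x$raw)][c(1, 100)], c(1L, 10L))
  # tie handling: equal values share the lower decile
  d2 <- rbgkit:::decile_bin(c(rep(1, 15), 2:9))
  expect_true(all(d2[1:15] == 1L))
  # decile 10 mean strictly above decile 1 mean
  G <- sim_genotypes(200, 20, seed = 44)
  s <- compute_prs(G, make_weights(G, rnorm(20)))
  expect_gt(mean(s$z[s$decile == 10]), mean(s$z[s$decile == 1]))
})

test_that("recall selection takes qualifying tails and errors on shortfall", {
  set.seed(45)
  n <- 4504
  scores <- data.frame(iid = sprintf("i%04d", 1:n), raw = rnorm(n))
  scores$z <- (scores$raw - mean(scores$raw)) / sd(scores$raw)
  scores$decile <- rbgkit:::decile_bin(scores$raw)
  sel <- select_recall(scores, k_low = 10, k_high = 6, min_sd = 2)
  expect_equal(as.integer(table(sel$group)[c("low", "high")]), c(10L, 6L))
  expect_true(all(abs(sel$z) >= 2))
  expect_true(all(sel$decile[sel$group == "low"] == 1))
  expect_true(all(sel$decile[sel$group == "high"] == 10))
  # n = 20: the 2-SD tails are almost surely too thin
  small <- scores[1:20, ]
  small$z <- (small$raw - mean(small$raw)) / sd(small$raw)
  small$decile <- rbgkit:::decile_bin(small$raw)
  expect_error(select_recall(small, 10, 6, min_sd = 2), "shortfall")
  expect_error(select_recall(scores, k_low = 0), "k_low")
})
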