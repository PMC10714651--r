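# Independent reference implementations used as oracles. Each deliberately
# takes a different computational path from the package code it checks.

# HWE exact test by direct enumeration with factorial ratios
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * aa + ab
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    a2 <- (na - h) / 2
    b2 <- n - a2 - h
    factorial(n) / (factorial(a2) * factorial(h) * factorial(b2)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == ab]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# naive greedy clump: repeatedly pop the best remaining row, discard
# correlated in-window rows, from a pairwise r2 matrix
clump_oracle <- function(ss, r2mat, window_kb, r2_thr, p_thr) {
  cand <- ss[ss$p <= p_thr, , drop = FALSE]
  cand <- cand[order(cand$p, cand$pos, cand$id), , drop = FALSE]
  retained <- character(0)
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    retained <- c(retained, top$id)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) > 0) {
      r2 <- vapply(cand$id, function(j) r2mat[top$id, j], numeric(1))
      drop <- cand$chrom == top$chrom &
        abs(cand$pos - top$pos) <= window_kb * 1000 & r2 > r2_thr
      cand <- cand[!drop, , drop = FALSE]
    }
  }
  retained
}

# brute-force BH step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive minimum vertex cover of the pi_hat > thr violation graph
min_cover_size <- function(kin, thr) {
  viol <- kin[kin$pi_hat > thr, , drop = FALSE]
  if (nrow(viol) == 0) return(0L)
  ids <- unique(c(viol$id1, viol$id2))
  for (k in 0:length(ids)) {
    sets <- utils::combn(ids, k, simplify = FALSE)
    for (s in sets) {
      if (all(viol$id1 %in% s | viol$id2 %in% s)) return(k)
    }
  }
  length(ids)
}

# random small summary-statistic panel on one or two chromosomes
random_panel <- function(m, seed) {
  set.seed(seed)
  out <- data.frame(
    chrom = sample(c("1", "2"), m, replace = TRUE),
    pos = 0L, id = sprintf("v%02d", seq_len(m)),
    a1 = "A", a2 = "G",
    beta = rnorm(m), se = runif(m, 0.01, 0.1),
    p = runif(m), freq = runif(m, 0.05, 0.95), info = 1,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom), ]
  for (ch in unique(out$chrom)) {
    k <- sum(out$chrom == ch)
    out$pos[out$chrom == ch] <- sort(sample.int(3e6, k)) # within-window sizes
  }
  out$id <- sprintf("v%02d", seq_len(m))
  r2 <- matrix(runif(m * m), m, m, dimnames = list(out$id, out$id))
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  list(ss = out, r2 = r2)
}
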