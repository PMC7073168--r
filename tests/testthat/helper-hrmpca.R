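# Shared builders and independent oracles for the suite.

# small deterministic melt dataset: linearly decaying curves with per-sample
# offsets
toy_dataset <- function(n_reads = 21, n_samples = 3, marker = "toy") {
  tg <- seq(70, 70 + (n_reads - 1) * 0.5, by = 0.5)
  f <- sapply(seq_len(n_samples), function(j)
    seq(3 + j, 1, length.out = n_reads))
  colnames(f) <- paste0("s", seq_len(n_samples))
  melt_dataset(tg, f, marker_id = marker)
}

# noise-free simulation settings (no amplitude jitter, no baseline)
quiet_config <- function(...) {
  simulation_config(noise_sd = 0, amplitude_cv = 0, baseline_slope = 0, ...)
}

# brute-force Pearson chi-square via explicit O/E loops
chisq_oracle <- function(o) {
  rs <- rowSums(o); cs <- colSums(o); n <- sum(o)
  stat <- 0
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (o[i, j] - e)^2 / e
    }
  }
  df <- (nrow(o) - 1) * (ncol(o) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# log-likelihood of 2-locus unphased genotype counts at haplotype
# frequencies f = (f00, f01, f10, f11); codes matrix n x 2, complete
hap2_loglik <- function(f, codes) {
  p_geno <- function(c1, c2) {
    pr <- function(a1, a2) f[a1 * 2 + a2 + 1]
    pairs <- expand.grid(
      a1 = switch(c1 + 1, list(c(0, 0)), list(c(0, 1), c(1, 0)),
                  list(c(1, 1))),
      b1 = switch(c2 + 1, list(c(0, 0)), list(c(0, 1), c(1, 0)),
                  list(c(1, 1))))
    tot <- 0
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$a1[[r]]; b <- pairs$b1[[r]]
      tot <- tot + pr(a[1], b[1]) * pr(a[2], b[2])
    }
    tot
  }
  sum(apply(codes, 1, function(cc) log(p_geno(cc[1], cc[2]))))
}

# best log-likelihood over the 0.005-resolution simplex lattice for 4
# haplotype frequencies, vectorized over (f2, f3) per f1 slice
hap2_grid_max <- function(codes, step = 0.005) {
  counts <- table(factor(paste(codes[, 1], codes[, 2]),
                         levels = as.vector(outer(0:2, 0:2, paste))))
  nvec <- as.numeric(counts)
  grid1 <- seq(0, 1, by = step)
  best <- -Inf
  for (f1 in grid1) {
    rest <- expand.grid(f2 = grid1, f3 = grid1)
    rest <- rest[rest$f2 + rest$f3 <= 1 - f1 + 1e-12, ]
    f2 <- rest$f2; f3 <- rest$f3; f4 <- pmax(1 - f1 - f2 - f3, 0)
    # genotype class probabilities, order (c1,c2) = 00,10,20,01,11,21,02,12,22
    p <- cbind(f1^2, 2 * f1 * f3, f3^2,
               2 * f1 * f2, 2 * (f1 * f4 + f2 * f3), 2 * f3 * f4,
               f2^2, 2 * f2 * f4, f4^2)
    ll <- as.vector(log(pmax(p, 1e-300)) %*% nvec)
    best <- max(best, max(ll))
  }
  best
}
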