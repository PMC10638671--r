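# shared fixtures and independent brute-force oracles

six_modes <- c("conserved", "cis", "trans", "cis_plus_trans",
               "cis_x_trans", "compensatory")
equal_six <- stats::setNames(rep(1 / 6, 6), six_modes)

# one-stage simulated dataset with unit size factors attached
quick_dataset <- function(n_peaks, props, seed, stages = "blastula",
                          ...) {
  tr <- make_truth(n_peaks, props, seed = seed, ...)
  cs <- simulate_counts(tr, simulation_design(stages = stages,
                                              seed = seed + 7777L))
  cs$counts <- set_size_factors(cs$counts,
                                rep(1, ncol(cs$counts$counts)))
  c(cs, list(truth = tr))
}

# exhaustive pairwise interval-overlap scan (0-based half-open)
bf_overlap_counts <- function(reads, peaks) {
  hit <- matrix(FALSE, nrow(reads), nrow(peaks))
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(peaks))) {
      hit[i, j] <- reads$chrom[i] == peaks$chrom[j] &&
        reads$start[i] < peaks$end[j] && peaks$start[j] < reads$end[i]
    }
  }
  list(counts = stats::setNames(colSums(hit), peaks$peak_id),
       assigned = sum(rowSums(hit) > 0))
}

# literal step-up definition of BH, O(n^2)
bf_bh <- function(p) {
  n <- length(p)
  rk <- rank(p, ties.method = "first")
  out <- numeric(n)
  for (i in seq_len(n)) {
    cand <- p >= p[i]
    out[i] <- min(1, min(n * p[cand] / rk[cand]))
  }
  out
}

# textbook chi-squared without continuity correction
bf_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       residuals = (tab - E) / sqrt(E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# Fisher exact two-sided p by full hypergeometric enumeration
bf_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  d <- stats::dhyper(support, c1, N - c1, r1)
  d_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

# O(n*m) nearest-gene scan with lexicographic tie-break
bf_nearest <- function(peaks, genes) {
  cen <- floor((peaks$start + peaks$end) / 2)
  out_g <- character(nrow(peaks)); out_d <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) { out_g[i] <- NA; out_d[i] <- NA; next }
    d <- abs(cen[i] - g$tls)
    cand <- which(d == min(d))
    j <- cand[order(g$gene_id[cand])][1]
    out_g[i] <- g$gene_id[j]; out_d[i] <- d[j]
  }
  data.frame(peak_id = peaks$peak_id, gene_id = out_g,
             distance = out_d, stringsAsFactors = FALSE)
}

# O(n*m) window membership scan (inclusive bound)
bf_window_counts <- function(genes, peaks, window) {
  cen <- floor((peaks$start + peaks$end) / 2)
  vapply(seq_len(nrow(genes)), function(i)
    sum(peaks$chrom == genes$chrom[i] &
          abs(cen - genes$tls[i]) <= window), 0L)
}

random_intervals <- function(n, chrom, max_pos = 500, max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
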