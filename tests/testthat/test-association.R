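test_that("chi-squared matches hand-worked values and textbook formula", {
  tab <- matrix(c(30, 20, 10, 40), 2)
  res <- chi2_independence(tab, continuity = TRUE)
  expect_equal(res$statistic, 15.0417, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_equal(res$residuals[1, 1], (30 - 20) / sqrt(20),
               tolerance = 1e-9)
  expect_equal(res$odds_ratio, (30 * 40) / (10 * 20))

  # perfectly proportional table: independence exactly
  prop <- matrix(c(20, 40, 10, 20), 2)
  res <- chi2_independence(prop)
  expect_equal(res$statistic, 0)
  expect_true(all(res$residuals == 0))
  expect_error(chi2_independence(matrix(c(5, 5, 0, 0), 2)),
               "zero margin")

  set.seed(31)
  for (i in 1:1000) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    tab <- matrix(sample(1:30, r * c, replace = TRUE), r)
    got <- chi2_independence(tab, continuity = FALSE)
    want <- bf_chi2(tab)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(unclass(got$residuals), want$residuals,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(got$df, want$df)
    expect_equal(sum(got$residuals^2), got$statistic, tolerance = 1e-9)
  }
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  res <- category_enrichment(rep(c(TRUE, FALSE), each = 10),
                             rep(c(TRUE, FALSE), 10))
  expect_equal(res$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(res$p.value, 1)
  expect_error(category_enrichment(rep(TRUE, 10),
                                   rep(c(TRUE, FALSE), 5)),
               "zero margin")

  set.seed(32)
  for (i in 1:1000) {
    N <- sample(8:60, 1)
    a <- sample(0:N, 1); b <- N - a
    tab <- matrix(c(sample(0:a, 1), sample(0:b, 1)), 1)
    tab <- rbind(tab, c(a, b) - tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- stats::fisher.test(tab)$p.value
    expect_equal(got, bf_fisher_p(tab), tolerance = 1e-9)
  }
  # the worked 8/2 vs 2/8 table against the same oracle
  tab <- matrix(c(8, 2, 2, 8), 2)
  expect_equal(stats::fisher.test(tab)$p.value, bf_fisher_p(tab),
               tolerance = 1e-12)
})

test_that("nearest-gene links and categories match the brute-force scan", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tls = c(1000, 5000))
  peaks <- data.frame(chrom = "chr1", start = 1300, end = 1700,
                      peak_id = "p1")
  link <- nearest_gene(peaks, genes)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$distance, 500)
  expect_equal(link$category, "proximal")

  # equidistant tie: lexicographically smaller gene id
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      tls = c(2000, 1000))
  peaks <- data.frame(chrom = "chr1", start = 1300, end = 1700,
                      peak_id = "p1")
  expect_equal(nearest_gene(peaks, genes)$gene_id, "gA")

  # no genes on the peak's chromosome: absent link, warning
  genes <- data.frame(gene_id = "gA", chrom = "chr2", tls = 100)
  expect_warning(link <- nearest_gene(peaks, genes), "no genes")
  expect_true(is.na(link$gene_id))

  set.seed(33)
  for (i in 1:50) {
    ng <- sample(1:15, 1); np <- sample(1:30, 1)
    genes <- data.frame(gene_id = paste0("g", sample(100, ng)),
                        chrom = sample(c("c1", "c2"), ng, replace = TRUE),
                        tls = sample(0:2000, ng))
    peaks <- random_intervals(np, sample(c("c1", "c2"), np,
                                         replace = TRUE),
                              max_pos = 2000)
    peaks$peak_id <- paste0("p", seq_len(np))
    got <- suppressWarnings(nearest_gene(peaks, genes))
    want <- bf_nearest(peaks, genes)
    expect_identical(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
    # category partition is exhaustive over linked peaks
    linked <- got[!is.na(got$gene_id), ]
    expect_true(all(linked$category %in%
                      c("proximal", "distal", "beyond")))
    if (nrow(linked) > 0)
      expect_identical(linked$category,
                       ifelse(linked$distance <= 500, "proximal",
                              ifelse(linked$distance <= 25000, "distal",
                                     "beyond")))
  }
})

test_that("window queries are inclusive and match the brute-force scan", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tls = 50000)
  mk <- function(centers) data.frame(
    chrom = rep("chr1", length(centers)), start = centers - 200,
    end = centers + 200, peak_id = paste0("p", seq_along(centers)),
    stringsAsFactors = FALSE)
  # center exactly 25 kb away is included
  links <- peaks_in_window(genes, mk(c(50000 + 25000, 50000 + 25001)))
  expect_equal(links$peak_id, "p1")
  empty_peaks <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), peak_id = character(0),
                            stringsAsFactors = FALSE)
  expect_equal(peaks_in_window(genes, empty_peaks)$gene_id,
               character(0))
  pk <- mk(50000 + c(100, 1000, 10000, 25000, 30000))
  expect_equal(nrow(peaks_in_window(genes, pk)), 4)
  expect_error(peaks_in_window(genes, pk, window = 0), "positive")

  set.seed(34)
  for (i in 1:50) {
    ng <- sample(1:10, 1); np <- sample(1:40, 1)
    genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                        chrom = sample(c("c1", "c2"), ng, replace = TRUE),
                        tls = sample(0:3000, ng))
    peaks <- random_intervals(np, sample(c("c1", "c2"), np,
                                         replace = TRUE),
                              max_pos = 3000)
    peaks$peak_id <- paste0("p", seq_len(np))
    w <- sample(c(100, 400, 1000), 1)
    links <- peaks_in_window(genes, peaks, w)
    got <- as.integer(table(factor(links$gene_id,
                                   levels = genes$gene_id)))
    expect_identical(got, bf_window_counts(genes, peaks, w))
  }
})

test_that("peak density counts every gene, including zero-peak genes", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tls = c(1000, 500000))
  peaks <- data.frame(chrom = "chr1", start = 800, end = 1200,
                      peak_id = "p1")
  d <- peak_density(genes, peaks)
  expect_equal(d$n_peaks, c(1L, 0L))
  d <- peak_density(genes, peaks[0, ])
  expect_equal(d$n_peaks, c(0L, 0L))
  expect_error(peak_density(genes[0, ], peaks), "nonempty")
})

test_that("association tests point the residuals in the built-in direction", {
  # deterministic coupling: DA peaks' nearest genes are DE
  links <- data.frame(peak_id = paste0("p", 1:40),
                      gene_id = paste0("g", 1:40))
  peak_da <- stats::setNames(rep(c(TRUE, FALSE), each = 20),
                             links$peak_id)
  gene_de <- stats::setNames(c(rep(TRUE, 16), rep(FALSE, 4),
                               rep(TRUE, 4), rep(FALSE, 16)),
                             links$gene_id)
  res <- peaks_focused_test(links, peak_da, gene_de)
  expect_lt(res$p.value, 0.05)
  expect_gt(res$residuals["DA", "nearest_DE"], 0)

  genes <- data.frame(gene_id = paste0("g", 1:40), chrom = "chr1",
                      tls = seq(60000, by = 60000, length.out = 40))
  peaks <- data.frame(chrom = "chr1",
                      start = genes$tls + 1000,
                      end = genes$tls + 1400,
                      peak_id = paste0("p", 1:40))
  res <- gene_focused_test(genes, peaks, peak_da, gene_de)
  expect_lt(res$p.value, 0.05)
  expect_gt(res$residuals["DE", "has_DA_peak"], 0)

  expr_mode <- stats::setNames(rep(c("cis", "trans"), 20),
                               genes$gene_id)
  de_all <- stats::setNames(rep(TRUE, 40), genes$gene_id)
  da_cis <- stats::setNames(rep(c(TRUE, FALSE), 20), peaks$peak_id)
  rm_ <- regmode_focused_test(genes, peaks, da_cis, de_all, expr_mode)
  expect_gt(rm_$cis$residuals[1, "has_DA_peak"], 0)
  expect_lt(rm_$trans$residuals[1, "has_DA_peak"], 0)
  expect_error(regmode_focused_test(genes, peaks, da_cis,
                                    stats::setNames(rep(FALSE, 40),
                                                    genes$gene_id),
                                    expr_mode), "no DE genes")
})

test_that("group comparisons handle degenerate and textbook inputs", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  w <- group_compare(c(x, y), rep(c("a", "b"), each = 3), "welch_t")
  expect_equal(w$statistic, 0)
  expect_equal(w$p.value, 1)
  k <- group_compare(c(x, y), rep(c("a", "b"), each = 3), "ks")
  expect_equal(k$statistic, 0)
  k <- group_compare(c(x, x + 10), rep(c("a", "b"), each = 3), "ks")
  expect_equal(k$statistic, 1)
  # constant but different groups
  w <- group_compare(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3),
                     "welch_t")
  expect_equal(w$p.value, 0)

  # three groups with equal means: F = 0, no Scheffe pair fires
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  a <- group_compare(v, g, "anova_scheffe")
  expect_equal(a$statistic, 0, tolerance = 1e-12)
  expect_false(any(a$pairs$significant))
  expect_equal(nrow(a$pairs), 3)
})
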