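peak_centers <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}

#' Nearest gene (by TLS) for each peak
#'
#' Distance is the strand-agnostic |peak center - TLS| on the same
#' chromosome; ties go to the lexicographically smaller gene_id.  Peaks
#' on chromosomes with no genes get an absent link (NA gene) and are
#' reported via a warning.  Category: proximal (distance <=
#' `proximal_bp`), distal (`proximal_bp`+1 .. `distal_bp`), beyond.
#'
#' @param peaks data.frame(chrom, start, end, peak_id).
#' @param genes data.frame(gene_id, chrom, tls).
#' @param proximal_bp,distal_bp Category boundaries (bp, inclusive).
#' @return data.frame(peak_id, gene_id, distance, category).
#' @export
nearest_gene <- function(peaks, genes, proximal_bp = 500,
                         distal_bp = 25000) {
  n <- nrow(peaks)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  centers <- peak_centers(peaks)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) next
    ord <- order(g$tls, g$gene_id)
    g <- g[ord, ]
    cen <- centers[pi]
    # nearest sorted TLS neighbours on each side
    hi <- findInterval(cen, g$tls) + 1L
    lo <- hi - 1L
    lo[lo < 1] <- 1L
    hi[hi > nrow(g)] <- nrow(g)
    d_lo <- abs(cen - g$tls[lo])
    d_hi <- abs(cen - g$tls[hi])
    dmin <- pmin(d_lo, d_hi)
    pick <- ifelse(d_lo <= d_hi, lo, hi)
    # resolve ties (equidistant or duplicated TLS) lexicographically
    tie <- which(d_lo == d_hi & lo != hi | duplicated(g$tls)[pick] |
                 g$tls[pick] %in% g$tls[duplicated(g$tls)])
    for (j in tie) {
      cand <- which(abs(cen[j] - g$tls) == dmin[j])
      pick[j] <- cand[order(g$gene_id[cand])][1]
    }
    gene[pi] <- g$gene_id[pick]
    dist[pi] <- dmin
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)),
            " peak(s) on chromosomes with no genes: link absent")
  category <- ifelse(is.na(dist), NA_character_,
                     ifelse(dist <= proximal_bp, "proximal",
                            ifelse(dist <= distal_bp, "distal", "beyond")))
  data.frame(peak_id = peaks$peak_id, gene_id = gene, distance = dist,
             category = category, stringsAsFactors = FALSE)
}

#' Peaks whose centers lie within a window of each gene's TLS
#'
#' The window bound is inclusive: a center exactly `window` bp away
#' counts.
#'
#' @param genes data.frame(gene_id, chrom, tls).
#' @param peaks data.frame(chrom, start, end, peak_id).
#' @param window Half-width in bp (> 0), default 25,000.
#' @return Link table data.frame(gene_id, peak_id, distance); genes with
#'   no peak in the window simply have no rows.
#' @export
peaks_in_window <- function(genes, peaks, window = 25000) {
  if (window <= 0) stop("window must be positive")
  if (nrow(genes) == 0 || nrow(peaks) == 0)
    return(data.frame(gene_id = character(), peak_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  centers <- peak_centers(peaks)
  ggr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$tls - window, 0), genes$tls + window))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(centers, width = 1))
  ov <- GenomicRanges::findOverlaps(ggr, pgr)
  gi <- S4Vectors::queryHits(ov)
  pi <- S4Vectors::subjectHits(ov)
  keep <- abs(centers[pi] - genes$tls[gi]) <= window
  data.frame(gene_id = genes$gene_id[gi][keep],
             peak_id = peaks$peak_id[pi][keep],
             distance = abs(centers[pi] - genes$tls[gi])[keep],
             stringsAsFactors = FALSE)
}

#' Chi-squared test of independence with Pearson residuals
#'
#' Expected counts from the margins; Yates continuity correction applied
#' only for 2x2 tables when `continuity = TRUE`; residuals
#' (O - E) / sqrt(E) are always reported without the correction.
#'
#' @param table Integer matrix (r x c) of counts with positive margins.
#' @param continuity Apply the continuity correction for 2x2 tables.
#' @param name Optional label carried in the result.
#' @return list of class `association_result`: name, table, expected,
#'   statistic, df, p.value, residuals, odds_ratio (2x2 only).
#' @export
chi2_independence <- function(table, continuity = TRUE, name = NULL) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("contingency table entries must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table; merge or drop the category")
  ct <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  or <- if (all(dim(table) == c(2, 2))) {
    (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  } else NA_real_
  structure(list(name = name, table = table,
                 expected = ct$expected,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value,
                 residuals = ct$residuals,
                 odds_ratio = or),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: chi-squared = %.4f, df = %s, p = %.4g\n",
              if (is.null(x$name)) "association" else x$name,
              x$statistic, format(x$df), x$p.value))
  invisible(x)
}

make_2x2 <- function(a, b, labels_a, labels_b) {
  tab <- table(factor(a, levels = c(TRUE, FALSE)),
               factor(b, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(labels_a, labels_b)
  as.matrix(tab)
}

#' Peaks-focused association: is a DA peak's nearest gene more often DE?
#'
#' @param links Nearest-gene links from [nearest_gene()].
#' @param peak_da Named logical vector (by peak_id): is the peak DA.
#' @param gene_de Named logical vector (by gene_id): is the gene DE.
#' @param continuity Passed to [chi2_independence()].
#' @return An `association_result` (2x2: DA x nearest-gene-DE).
#' @export
peaks_focused_test <- function(links, peak_da, gene_de,
                               continuity = TRUE) {
  links <- links[!is.na(links$gene_id), ]
  da <- peak_da[links$peak_id]
  de <- gene_de[links$gene_id]
  if (anyNA(da)) stop("peak(s) missing from peak_da")
  if (anyNA(de)) stop("gene(s) missing from gene_de")
  tab <- make_2x2(da, de, c("DA", "not_DA"),
                  c("nearest_DE", "nearest_not_DE"))
  chi2_independence(tab, continuity, name = "peaks_focused")
}

#' Gene-focused association: does a DE gene have a nearby DA peak?
#'
#' "Nearby" means at least one DA peak center within `window` bp of the
#' TLS (inclusive).
#'
#' @param genes Gene table (gene_id, chrom, tls).
#' @param peaks Peak intervals.
#' @param peak_da Named logical by peak_id.
#' @param gene_de Named logical by gene_id.
#' @param window Window in bp (default 25,000).
#' @param continuity Passed to [chi2_independence()].
#' @return An `association_result` (2x2: DE x has-nearby-DA).
#' @export
gene_focused_test <- function(genes, peaks, peak_da, gene_de,
                              window = 25000, continuity = TRUE) {
  links <- peaks_in_window(genes, peaks, window)
  da_genes <- unique(links$gene_id[peak_da[links$peak_id]])
  has_da <- genes$gene_id %in% da_genes
  de <- gene_de[genes$gene_id]
  if (anyNA(de)) stop("gene(s) missing from gene_de")
  tab <- make_2x2(de, has_da, c("DE", "not_DE"),
                  c("has_DA_peak", "no_DA_peak"))
  chi2_independence(tab, continuity, name = "gene_focused")
}

#' Regulatory-mode-focused association among DE genes
#'
#' Restricted to DE genes: are genes whose expression divergence is
#' cis-based (and, mirrored, trans-based) enriched for at least one
#' nearby DA peak?
#'
#' @param genes Gene table.
#' @param peaks Peak intervals.
#' @param peak_da Named logical by peak_id.
#' @param gene_de Named logical by gene_id.
#' @param expr_mode Named character by gene_id ("cis", "trans", ...).
#' @param window,continuity As in [gene_focused_test()].
#' @return list(cis = association_result, trans = association_result).
#' @export
regmode_focused_test <- function(genes, peaks, peak_da, gene_de,
                                 expr_mode, window = 25000,
                                 continuity = TRUE) {
  de_genes <- genes[gene_de[genes$gene_id] %in% TRUE, ]
  if (nrow(de_genes) == 0) stop("no DE genes to test")
  links <- peaks_in_window(de_genes, peaks, window)
  da_genes <- unique(links$gene_id[peak_da[links$peak_id]])
  has_da <- de_genes$gene_id %in% da_genes
  mode <- expr_mode[de_genes$gene_id]
  out <- list()
  for (m in c("cis", "trans")) {
    tab <- make_2x2(mode == m, has_da,
                    c(paste0(m, "_DE"), paste0("non_", m, "_DE")),
                    c("has_DA_peak", "no_DA_peak"))
    out[[m]] <- chi2_independence(tab, continuity,
                                  name = paste0("regmode_", m))
  }
  out
}

#' Fisher exact enrichment of an indicator within a peak category
#'
#' Conditional maximum-likelihood odds ratio and exact two-sided p
#' (sum of hypergeometric probabilities not exceeding the observed
#' table's).
#'
#' @param in_category Logical vector (e.g. peak is proximal).
#' @param indicator Logical vector (e.g. peak is DA).
#' @return list(odds_ratio, p.value, table).
#' @export
category_enrichment <- function(in_category, indicator) {
  tab <- make_2x2(in_category, indicator,
                  c("in_category", "other"), c("yes", "no"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: category or indicator is constant")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p.value = ft$p.value,
       table = tab)
}

#' Compare value distributions between groups
#'
#' `welch_t`: unequal-variance t-test (two groups); `ks`: two-sample
#' Kolmogorov-Smirnov with asymptotic p; `anova_scheffe`: one-way ANOVA
#' F followed by pairwise Scheffe decisions at level `alpha`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @param method "welch_t", "ks" or "anova_scheffe".
#' @param alpha Level for the Scheffe criterion.
#' @param alternative Passed to the Welch t-test.
#' @return A list with `statistic` and `p.value`; `anova_scheffe` adds a
#'   `pairs` data.frame of pairwise Scheffe decisions.
#' @export
group_compare <- function(values, groups,
                          method = c("welch_t", "ks", "anova_scheffe"),
                          alpha = 0.05, alternative = "two.sided") {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  split_v <- split(values, groups)
  eps <- 1e-12
  if (method == "welch_t") {
    if (nlevels(groups) != 2) stop("welch_t needs exactly 2 groups")
    x <- split_v[[1]]; y <- split_v[[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("welch_t needs >= 2 values per group")
    if (stats::var(x) < eps && stats::var(y) < eps) {
      if (mean(x) == mean(y))
        return(list(statistic = 0, p.value = 1))
      return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                  p.value = 0))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE,
                        alternative = alternative)
    return(list(statistic = unname(tt$statistic), p.value = tt$p.value,
                df = unname(tt$parameter)))
  }
  if (method == "ks") {
    if (nlevels(groups) != 2) stop("ks needs exactly 2 groups")
    kt <- suppressWarnings(stats::ks.test(split_v[[1]], split_v[[2]]))
    return(list(statistic = unname(kt$statistic), p.value = kt$p.value))
  }
  # one-way ANOVA + Scheffe pairwise criterion
  if (any(vapply(split_v, length, 1L) < 2))
    stop("anova_scheffe needs >= 2 values per group")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  k <- nlevels(groups)
  n_tot <- length(values)
  means <- vapply(split_v, mean, numeric(1))
  ns <- vapply(split_v, length, numeric(1))
  combs <- utils::combn(levels(groups), 2)
  pairs <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$diff <- means[pairs$group1] - means[pairs$group2]
  crit_f <- stats::qf(1 - alpha, k - 1, n_tot - k)
  pairs$critical <- sqrt((k - 1) * crit_f) *
    sqrt(mse * (1 / ns[pairs$group1] + 1 / ns[pairs$group2]))
  pairs$significant <- abs(pairs$diff) > pairs$critical
  rownames(pairs) <- NULL
  list(statistic = fstat, p.value = pval, pairs = pairs)
}

#' Per-gene counts of peaks within a window
#'
#' Genes with no peak in the window contribute zero (they are kept, not
#' dropped), so the returned counts are directly comparable across gene
#' subsets with [group_compare()].
#'
#' @param genes Gene table subset of interest (nonempty).
#' @param peaks Peak intervals.
#' @param window Window in bp (default 25,000).
#' @return data.frame(gene_id, n_peaks).
#' @export
peak_density <- function(genes, peaks, window = 25000) {
  if (nrow(genes) == 0) stop("gene subset must be nonempty")
  links <- peaks_in_window(genes, peaks, window)
  tab <- table(factor(links$gene_id, levels = genes$gene_id))
  data.frame(gene_id = genes$gene_id, n_peaks = as.integer(tab),
             stringsAsFactors = FALSE)
}
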