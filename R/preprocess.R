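#' Count reads falling in peak intervals
#'
#' A read is counted for a peak iff the two intervals (both BED-style,
#' 0-based half-open) overlap by at least 1 bp.  A read overlapping
#' several peaks is counted once per peak, but only once in the assigned
#' tally.
#'
#' @param reads data.frame(chrom, start, end) of aligned reads.
#' @param peaks data.frame(chrom, start, end, peak_id).
#' @return list(counts = named per-peak read counts, assigned = number
#'   of reads overlapping >= 1 peak, total = number of reads).
#' @export
count_reads_in_intervals <- function(reads, peaks) {
  if (nrow(peaks) == 0 || nrow(reads) == 0) {
    n <- stats::setNames(integer(nrow(peaks)), peaks$peak_id)
    return(list(counts = n, assigned = 0L, total = nrow(reads)))
  }
  # BED half-open [start, end) -> 1-based closed [start+1, end]
  lev <- unique(c(reads$chrom, peaks$chrom))
  rgr <- GenomicRanges::GRanges(factor(reads$chrom, lev),
                                IRanges::IRanges(reads$start + 1, reads$end))
  pgr <- GenomicRanges::GRanges(factor(peaks$chrom, lev),
                                IRanges::IRanges(peaks$start + 1, peaks$end))
  counts <- GenomicRanges::countOverlaps(pgr, rgr, minoverlap = 1L)
  names(counts) <- peaks$peak_id
  assigned <- sum(GenomicRanges::countOverlaps(rgr, pgr,
                                               minoverlap = 1L) > 0)
  list(counts = counts, assigned = as.integer(assigned),
       total = nrow(reads))
}

#' Fraction of reads in peaks (FRIP)
#'
#' Signal-to-noise QC metric: the fraction of reads overlapping any
#' peak.  For hybrid samples whose reads were binned by parent-of-origin,
#' pass the allele label in `by` to get one score per allele read set.
#'
#' @param reads data.frame(chrom, start, end), optionally with the
#'   grouping column named by `by`.
#' @param peaks data.frame(chrom, start, end).
#' @param by Optional column of `reads` to split by (e.g. "allele").
#' @return A fraction in \[0, 1\], or a named vector of fractions when
#'   `by` is given.
#' @export
frip <- function(reads, peaks, by = NULL) {
  if (nrow(reads) == 0) stop("FRIP is undefined with zero reads")
  if (!is.null(by)) {
    stopifnot(by %in% names(reads))
    groups <- split(reads, reads[[by]])
    return(vapply(groups, frip, numeric(1), peaks = peaks))
  }
  res <- count_reads_in_intervals(reads, peaks)
  res$assigned / res$total
}

#' Low-count filter on counts-per-million
#'
#' Retains a peak iff its CPM is >= `min_cpm` in at least
#' ceiling(`min_fraction` x number of included samples) included
#' samples.  By default the split hybrid allele columns are excluded
#' from the vote (they are half-libraries) but retained in the output.
#'
#' @param x An [atac_counts] object.
#' @param samples Optional descriptor table (to derive the default
#'   inclusion: allele == "total").
#' @param min_cpm CPM threshold (default 3).
#' @param min_fraction Fraction of included samples that must pass
#'   (default 1/3).
#' @param include Logical vector over columns: which samples vote.
#'   Overrides the `samples` default.
#' @return The filtered [atac_counts] (all columns retained).
#' @export
cpm_filter <- function(x, samples = NULL, min_cpm = 3,
                       min_fraction = 1 / 3, include = NULL) {
  stopifnot(inherits(x, "atac_counts"))
  if (is.null(include)) {
    include <- if (is.null(samples)) rep(TRUE, ncol(x$counts)) else
      samples$allele[match(colnames(x$counts), samples$sample_id)] == "total"
  }
  stopifnot(length(include) == ncol(x$counts))
  m <- x$counts[, include, drop = FALSE]
  libs <- colSums(m)
  if (any(libs <= 0))
    stop("included column(s) with zero library size: ",
         paste(colnames(m)[libs <= 0], collapse = ", "))
  cpm <- sweep(m, 2, libs, "/") * 1e6
  need <- ceiling(min_fraction * ncol(m) - 1e-9)
  keep <- rowSums(cpm >= min_cpm) >= need
  if (!any(keep)) warning("all peaks removed by the CPM filter")
  subset_peaks(x, keep)
}

#' Median-of-ratios size factors for a count matrix
#'
#' Factor_j is the median over peaks (with an all-positive geometric-mean
#' reference) of count_ij / geometric mean_i.
#'
#' @param m Numeric count matrix (peaks x samples).
#' @return Numeric vector of size factors, one per column.
#' @export
median_ratio_size_factors <- function(m) {
  logs <- log(m)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no peak has nonzero counts in every column; ",
         "apply a count filter first")
  apply(logs[use, , drop = FALSE], 2,
        function(col) exp(stats::median(col - loggeo[use])))
}

#' Compute and attach size factors
#'
#' Under the default "inherit" policy, factors are estimated from the
#' whole-library (allele == "total") columns only, and each hybrid
#' allele column inherits the factor of its parent hybrid total column
#' (same stage and replicate): both alleles share one library, and
#' allelic ratios must not be renormalized away.  Policy "independent"
#' estimates a factor for every column jointly.
#'
#' @param x An [atac_counts] object.
#' @param samples Descriptor table (required for "inherit").
#' @param policy "inherit" (default) or "independent".
#' @return `x` with size factors set.
#' @export
normalize_counts <- function(x, samples = NULL,
                             policy = c("inherit", "independent")) {
  stopifnot(inherits(x, "atac_counts"))
  policy <- match.arg(policy)
  if (policy == "independent" || is.null(samples)) {
    return(set_size_factors(x, median_ratio_size_factors(x$counts)))
  }
  samples <- samples[match(colnames(x$counts), samples$sample_id), ]
  tot <- samples$allele == "total"
  sf_tot <- median_ratio_size_factors(x$counts[, tot, drop = FALSE])
  sf <- stats::setNames(rep(NA_real_, ncol(x$counts)),
                        colnames(x$counts))
  sf[samples$sample_id[tot]] <- sf_tot
  al <- which(!tot)
  if (length(al) > 0) {
    key <- paste(samples$stage, samples$replicate)
    tot_hyb <- which(tot & samples$cross == "hybrid")
    parent <- match(key[al], key[tot_hyb])
    if (anyNA(parent))
      stop("hybrid allele column(s) with no matching total column: ",
           paste(samples$sample_id[al[is.na(parent)]], collapse = ", "))
    sf[al] <- sf_tot[match(samples$sample_id[tot_hyb][parent],
                           samples$sample_id[tot])]
  }
  set_size_factors(x, sf)
}

#' Variance-taming log transform of normalized counts
#'
#' value = log2(count / size_factor + pseudocount); monotone in the
#' count within each column.
#'
#' @param x An [atac_counts] with size factors set.
#' @param pseudocount Positive offset (default 1).
#' @return A numeric matrix (peaks x samples).
#' @export
transform_counts <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "atac_counts"))
  if (is.null(x$size_factors))
    stop("size factors not set; call normalize_counts() first")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(sweep(x$counts, 2, x$size_factors, "/") + pseudocount)
}

#' PCA of samples on transformed accessibility values
#'
#' Samples are the observations; features (peaks) are centered, not
#' scaled.  Components with zero variance are dropped; a constant input
#' yields zero components rather than a division by zero.
#'
#' @param m Numeric matrix, peaks x samples (e.g. [transform_counts()]).
#' @return list(coordinates = samples x components scores,
#'   var_fraction = fraction of variance per retained component,
#'   sdev, rotation, center).
#' @export
run_pca <- function(m) {
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  keep <- p$sdev > 1e-12 * max(p$sdev, 1e-300)
  if (max(p$sdev) == 0) keep <- rep(FALSE, length(p$sdev))
  list(coordinates = p$x[, keep, drop = FALSE],
       var_fraction = if (any(keep))
         p$sdev[keep]^2 / sum(p$sdev[keep]^2) else numeric(0),
       sdev = p$sdev[keep],
       rotation = p$rotation[, keep, drop = FALSE],
       center = p$center)
}
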