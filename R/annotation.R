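#' Generate gene annotation and peak intervals at controlled distances
#'
#' Places `n_genes` translation start sites (TLS) evenly along one
#' chromosome and assigns each peak in `truth` to a gene at a distance
#' drawn within one of three strata: proximal (center-to-TLS <= 500 bp),
#' distal (501-25,000 bp) or beyond (> 25,000 bp from every gene).  Gene
#' spacing is checked against the stratum quotas so that the assigned
#' gene is always the nearest gene and "beyond" peaks stay > 25 kb from
#' all genes; quotas the chromosome cannot accommodate are rejected.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp.
#' @param truth A [make_truth()] table supplying peak ids.
#' @param placement Named fractions over c(proximal, distal, beyond)
#'   summing to 1 (largest-remainder quotas).
#' @param grn_fraction Fraction of genes in the developmental gene
#'   regulatory network (GRN); GRN genes are a subset of TF genes.
#' @param tf_fraction Fraction of genes encoding transcription factors.
#' @param peak_width Width of each emitted peak interval (bp, even).
#' @param grn_weight Relative sampling weight of GRN genes when peaks are
#'   assigned to genes (> 1 concentrates peaks near GRN genes).
#' @param seed Integer RNG seed.
#' @return list(genes, peaks, distances): gene table (gene_id, chrom,
#'   tls, strand, is_tf, is_grn), BED-style peak intervals (chrom, start,
#'   end, peak_id; 0-based half-open) and the peak-to-assigned-gene
#'   distance table (peak_id, gene_id, distance, stratum).
#' @export
make_annotation <- function(n_genes, chrom_length, truth,
                            placement = c(proximal = 1 / 3, distal = 1 / 3,
                                          beyond = 1 / 3),
                            grn_fraction = 0.1, tf_fraction = 0.3,
                            peak_width = 400, grn_weight = 1,
                            seed = 1L) {
  if (n_genes < 1) stop("need at least one gene")
  if (grn_fraction > tf_fraction)
    stop("GRN genes must be a subset of TF genes (grn_fraction <= tf_fraction)")
  stopifnot(setequal(names(placement), c("proximal", "distal", "beyond")))
  if (abs(sum(placement) - 1) > 1e-9)
    stop("placement fractions must sum to 1")
  placement <- placement[c("proximal", "distal", "beyond")]
  n_peaks <- nrow(truth)
  quota <- largest_remainder(n_peaks, placement)
  half <- peak_width %/% 2

  spacing <- chrom_length / (n_genes + 1)
  # nearest-gene guarantee: assigned distances must stay < spacing/2,
  # and "beyond" peaks must clear 25 kb on both flanks
  if (quota[["beyond"]] > 0 && spacing < 2 * 25001 + 2)
    stop(sprintf(paste0("'beyond' stratum needs gene spacing > %d bp; ",
                        "chromosome of %d bp with %d genes gives %.0f bp"),
                 2 * 25001 + 2, chrom_length, n_genes, spacing))
  distal_hi <- min(25000, floor(spacing / 2) - 1)
  if (quota[["distal"]] > 0 && distal_hi < 501)
    stop("'distal' stratum exceeds chromosome capacity: genes too dense")
  if (quota[["proximal"]] > 0 && floor(spacing / 2) - 1 < 500)
    stop("'proximal' stratum exceeds chromosome capacity: genes too dense")

  set.seed(seed)
  wid <- max(4, nchar(as.character(n_genes)))
  tls <- round(spacing * seq_len(n_genes))
  n_tf <- round(tf_fraction * n_genes)
  n_grn <- round(grn_fraction * n_genes)
  tf_idx <- sort(sample.int(n_genes, n_tf))
  grn_idx <- sort(sample(tf_idx, n_grn))
  genes <- data.frame(
    gene_id = sprintf(paste0("gene_%0", wid, "d"), seq_len(n_genes)),
    chrom = "chr1",
    tls = as.integer(tls),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    is_tf = seq_len(n_genes) %in% tf_idx,
    is_grn = seq_len(n_genes) %in% grn_idx,
    stringsAsFactors = FALSE)

  stratum <- sample(rep(names(quota), quota))
  w <- ifelse(genes$is_grn, grn_weight, 1)
  gene_of <- sample.int(n_genes, n_peaks, replace = TRUE, prob = w)
  dist <- integer(n_peaks)
  i <- stratum == "proximal"
  dist[i] <- sample.int(501, sum(i), replace = TRUE) - 1L
  i <- stratum == "distal"
  dist[i] <- 500L + sample.int(distal_hi - 500L, sum(i), replace = TRUE)
  i <- stratum == "beyond"
  if (any(i)) {
    lo <- 25001L
    hi <- as.integer(floor(spacing)) - 25001L
    dist[i] <- lo + sample.int(hi - lo + 1L, sum(i), replace = TRUE) - 1L
  }
  side <- sample(c(-1L, 1L), n_peaks, replace = TRUE)
  center <- genes$tls[gene_of] + side * dist
  flip <- center < half | center >= chrom_length - half
  center[flip] <- genes$tls[gene_of][flip] - side[flip] * dist[flip]
  if (any(center < half | center >= chrom_length - half))
    stop("peak placement exceeds chromosome bounds; enlarge chrom_length")

  peaks <- data.frame(chrom = "chr1",
                      start = as.integer(center - half),
                      end = as.integer(center + half),
                      peak_id = truth$peak_id,
                      stringsAsFactors = FALSE)
  distances <- data.frame(peak_id = truth$peak_id,
                          gene_id = genes$gene_id[gene_of],
                          distance = as.integer(dist),
                          stratum = stratum,
                          stringsAsFactors = FALSE)
  list(genes = genes, peaks = peaks, distances = distances)
}

#' Simulate a per-gene differential-expression table coupled to peak truth
#'
#' Emulates a companion transcriptome study: each gene gets a DE status
#' and an expression regulatory mode per stage.  A gene with at least one
#' truly non-conserved peak within 25 kb is DE with odds `coupling_odds`
#' times the baseline odds; among DE genes, the cis expression mode is
#' preferentially (same odds machinery) attached to genes with nearby
#' non-conserved peaks.
#'
#' @param genes Gene table from [make_annotation()].
#' @param peak_truth A [make_truth()] table.
#' @param distances Peak-to-gene distance table from [make_annotation()].
#' @param coupling_odds Positive odds ratio linking nearby non-conserved
#'   peak truth to gene DE status (1 = independence).
#' @param base_rate Baseline DE probability for genes with no nearby
#'   non-conserved peak.
#' @param stages Stages to emit (independent draws per stage).
#' @param cis_fraction Baseline probability that a DE gene's expression
#'   mode is cis; the non-cis remainder is split 2:1 between trans and
#'   ambiguous.
#' @param window Coupling window in bp (default 25,000).
#' @param seed Integer RNG seed.
#' @return data.frame(gene_id, stage, de_status, expr_mode) with
#'   expr_mode in c("conserved", "cis", "trans", "ambiguous").
#' @export
simulate_expression_table <- function(genes, peak_truth, distances,
                                      coupling_odds = 1, base_rate = 0.2,
                                      stages = c("blastula", "gastrula",
                                                 "larva"),
                                      cis_fraction = 0.4,
                                      window = 25000, seed = 1L) {
  if (nrow(genes) == 0) stop("gene list must be nonempty")
  if (coupling_odds <= 0) stop("coupling_odds must be positive")
  nc <- peak_truth$peak_id[peak_truth$true_regulatory_mode != "conserved"]
  near <- distances$gene_id[distances$peak_id %in% nc &
                            distances$distance <= window]
  has_nc <- genes$gene_id %in% near

  lift <- function(p, or) (or * p / (1 - p)) / (1 + or * p / (1 - p))
  p_de <- ifelse(has_nc, lift(base_rate, coupling_odds), base_rate)
  p_cis <- ifelse(has_nc, lift(cis_fraction, coupling_odds), cis_fraction)

  set.seed(seed)
  out <- do.call(rbind, lapply(stages, function(st) {
    de <- stats::runif(nrow(genes)) < p_de
    mode <- rep("conserved", nrow(genes))
    if (any(de)) {
      u <- stats::runif(sum(de))
      pc <- p_cis[de]
      mode[de] <- ifelse(u < pc, "cis",
                         ifelse(u < pc + (1 - pc) * 2 / 3, "trans",
                                "ambiguous"))
    }
    data.frame(gene_id = genes$gene_id, stage = st, de_status = de,
               expr_mode = mode, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
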