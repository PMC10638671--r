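rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

norm_counts <- function(x) {
  sf <- if (is.null(x$size_factors)) rep(1, ncol(x$counts)) else
    x$size_factors
  sweep(x$counts, 2, sf, "/")
}

#' Pooled method-of-moments negative-binomial dispersion
#'
#' Per-peak estimate pooled across replicate groups, on the normalized
#' scale: alpha = max(floor, sum_g (s2_g - m_g) w_g / sum_g m_g^2 w_g)
#' with weights w_g = n_g - 1.  Groups with a single replicate carry no
#' weight; at least one group must have >= 2 replicates.
#'
#' With `prior_df > 0` the raw per-peak estimates are moderated toward
#' their across-peak mean, weighted by the residual degrees of freedom:
#' alpha_mod = (df * alpha + prior_df * mean(alpha)) / (df + prior_df).
#' Per-peak method-of-moments estimates from a handful of replicates are
#' noisy, and plugging them into a Wald test unmoderated makes it
#' anti-conservative; the shrinkage mirrors what standard
#' count-differential tools do with their fitted dispersion trends.
#'
#' @param x An [atac_counts]; counts are normalized by the size factors
#'   if set (taken as 1 otherwise).
#' @param groups A list of character vectors of sample ids (one per
#'   replicate group), or a factor/vector over columns.
#' @param floor Lower bound for the estimate (default 1e-8).
#' @param prior_df Weight of the across-peak mean in the moderated
#'   estimate; 0 (default) returns the raw per-peak estimates.
#' @return Named numeric vector of per-peak dispersions.
#' @export
estimate_dispersion <- function(x, groups, floor = 1e-8, prior_df = 0) {
  stopifnot(inherits(x, "atac_counts"))
  nm <- norm_counts(x)
  if (!is.list(groups))
    groups <- split(colnames(x$counts), groups)
  groups <- Filter(function(g) length(g) >= 2, groups)
  if (length(groups) == 0)
    stop("dispersion estimation requires >= 2 replicates in >= 1 group")
  num <- den <- numeric(nrow(nm))
  for (g in groups) {
    sub <- nm[, g, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowVars(sub)
    w <- length(g) - 1
    num <- num + (v - m) * w
    den <- den + m^2 * w
  }
  alpha <- pmax(floor, ifelse(den > 0, num / den, floor))
  if (prior_df > 0) {
    df <- sum(vapply(groups, length, 1L) - 1L)
    alpha <- pmax(floor, (df * alpha + prior_df * mean(alpha)) /
                           (df + prior_df))
  }
  stats::setNames(alpha, rownames(nm))
}

#' Negative-binomial Wald contrast between two sample groups
#'
#' Per-peak plug-in Wald test on the normalized scale.  log2_ratio =
#' log2((m1 + psi) / (m2 + psi)); Var(ln m_g) = (1/n_g)(1/(m_g + psi) +
#' alpha), the delta-method variance of a mean of NB(m, alpha) draws
#' (the pseudocount keeps it finite at zero means); z = log2_ratio / se
#' with se in log2 units, two-sided normal p.
#'
#' @param x An [atac_counts] with size factors set.
#' @param group1,group2 Character vectors of sample ids.
#' @param dispersion Optional per-peak dispersion; default: moderated
#'   pooled method-of-moments over the two groups
#'   ([estimate_dispersion()] with `prior_df = 20`).
#' @param pseudocount psi, added to group means in the ratio (default
#'   0.5).
#' @return data.frame(peak_id, log2_ratio, se, z, p, mean1, mean2).
#' @export
wald_test <- function(x, group1, group2, dispersion = NULL,
                      pseudocount = 0.5) {
  stopifnot(inherits(x, "atac_counts"))
  if (is.null(x$size_factors))
    stop("size factors not set; call normalize_counts() first")
  if (length(group1) == 0 || length(group2) == 0)
    stop("both contrast groups must be nonempty")
  miss <- setdiff(c(group1, group2), colnames(x$counts))
  if (length(miss) > 0)
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(x, list(group1, group2),
                                      prior_df = 20)
  nm <- norm_counts(x)
  m1 <- rowMeans(nm[, group1, drop = FALSE])
  m2 <- rowMeans(nm[, group2, drop = FALSE])
  psi <- pseudocount
  lfc <- log2((m1 + psi) / (m2 + psi))
  v1 <- (1 / (m1 + psi) + dispersion) / length(group1)
  v2 <- (1 / (m2 + psi) + dispersion) / length(group2)
  se <- sqrt(v1 + v2) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  zero <- m1 == 0 & m2 == 0
  lfc[zero] <- 0; z[zero] <- 0; p[zero] <- 1
  data.frame(peak_id = rownames(nm), log2_ratio = lfc, se = se, z = z,
             p = p, mean1 = m1, mean2 = m2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Ratio-divergence (trans) test
#'
#' Tests whether the parental log2 accessibility ratio L_P differs from
#' the hybrid allelic ratio L_H.  Under a pure-cis change the two ratios
#' coincide; a trans change makes the hybrid alleles converge while the
#' parents differ.  z = (L_P - L_H) / sqrt(se_P^2 + se_H^2); the
#' log2_ratio field stores L_P - L_H, the trans component.
#'
#' @param p_result,h_result [wald_test()] results for the parental (P)
#'   and hybrid-allele (H) contrasts on the same peaks and stage.
#' @return data.frame like [wald_test()] (without group means).
#' @export
ratio_divergence_test <- function(p_result, h_result) {
  if (!identical(p_result$peak_id, h_result$peak_id))
    stop("P and H results must cover the same peaks in the same order")
  lfc <- p_result$log2_ratio - h_result$log2_ratio
  se <- sqrt(p_result$se^2 + h_result$se^2)
  z <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(peak_id = p_result$peak_id, log2_ratio = lfc, se = se,
             z = z, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up FDR adjustment applied independently within each level of
#' `family` (e.g. contrast x stage).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param family Optional grouping vector of the same length.
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- numeric(length(p))
  for (f in unique(family)) {
    i <- family == f
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}
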