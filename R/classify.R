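#' Inheritance-mode decision table
#'
#' Relates the hybrid's total accessibility to the two parents using
#' three contrasts (significance = adjusted p <= alpha): P = maternal vs
#' paternal species, M = hybrid total vs maternal species, F = hybrid
#' total vs paternal species.  Overdominant/underdominant (hybrid mean
#' strictly outside the parental interval with both M and F significant)
#' take precedence over additive; exact mean ties fall to ambiguous.
#'
#' @param sig_p,sig_m,sig_f Logical vectors: is each contrast
#'   significant.
#' @param mean_maternal,mean_paternal,mean_hybrid Normalized group
#'   means.
#' @return Character vector of inheritance modes.
#' @export
classify_inheritance <- function(sig_p, sig_m, sig_f,
                                 mean_maternal, mean_paternal,
                                 mean_hybrid) {
  n <- length(sig_p)
  stopifnot(length(sig_m) == n, length(sig_f) == n,
            length(mean_maternal) == n, length(mean_paternal) == n,
            length(mean_hybrid) == n)
  lo <- pmin(mean_maternal, mean_paternal)
  hi <- pmax(mean_maternal, mean_paternal)
  out <- rep("ambiguous", n)
  out[!sig_p & !sig_m & !sig_f] <- "conserved"
  over <- sig_m & sig_f & mean_hybrid > hi
  under <- sig_m & sig_f & mean_hybrid < lo
  out[over] <- "overdominant"
  out[under] <- "underdominant"
  add <- sig_p & sig_m & sig_f & mean_hybrid > lo & mean_hybrid < hi
  out[add & !over & !under] <- "additive"
  mat <- sig_p & sig_f & !sig_m
  pat <- sig_p & sig_m & !sig_f
  out[mat] <- "maternal_dominant"
  out[pat] <- "paternal_dominant"
  out
}

#' Regulatory-mode decision table
#'
#' Classifies each peak from the parental contrast (P), the hybrid
#' allelic contrast (H) and the ratio-divergence test (T): conserved
#' (none significant); cis (P, H significant, T not: parental and
#' allelic ratios agree); trans (P, T significant, H not: parents differ
#' while hybrid alleles equalize); cis_plus_trans / cis_x_trans (all
#' three significant, cis and trans components with equal / opposite
#' signs); compensatory (H, T significant, P not: effects cancel in the
#' parents).  Anything else is ambiguous.
#'
#' @param sig_p,sig_h,sig_t Logical significance of the P, H, T tests.
#' @param l_h Hybrid allelic log2 ratio (the cis component).
#' @param l_t L_P - L_H (the trans component).
#' @param require_parental_sig If FALSE, cis and trans calls drop the P
#'   requirement and rely on the H/T pattern alone.
#' @return Character vector of regulatory modes.
#' @export
classify_regulatory <- function(sig_p, sig_h, sig_t, l_h, l_t,
                                require_parental_sig = TRUE) {
  n <- length(sig_p)
  stopifnot(length(sig_h) == n, length(sig_t) == n,
            length(l_h) == n, length(l_t) == n)
  same_sign <- sign(l_h) * sign(l_t) > 0
  opp_sign <- sign(l_h) * sign(l_t) < 0
  out <- rep("ambiguous", n)
  out[!sig_p & !sig_h & !sig_t] <- "conserved"
  if (require_parental_sig) {
    out[sig_p & sig_h & !sig_t] <- "cis"
    out[sig_p & !sig_h & sig_t] <- "trans"
    out[sig_p & sig_h & sig_t & same_sign] <- "cis_plus_trans"
    out[sig_p & sig_h & sig_t & opp_sign] <- "cis_x_trans"
    out[!sig_p & sig_h & sig_t] <- "compensatory"
  } else {
    out[sig_h & !sig_t] <- "cis"
    out[!sig_h & sig_t] <- "trans"
    out[sig_p & sig_h & sig_t & same_sign] <- "cis_plus_trans"
    out[sig_p & sig_h & sig_t & opp_sign] <- "cis_x_trans"
    out[!sig_p & sig_h & sig_t] <- "compensatory"
  }
  out
}

#' Evolutionary effect size of a peak
#'
#' ES = log2((mean_maternal_species + psi) / (mean_paternal_species +
#' psi)) on the size-factor-normalized scale: the log2 ratio of the
#' accessibility of the same-species peaks.
#'
#' @param mean_maternal,mean_paternal Nonnegative normalized means.
#' @param pseudocount psi > 0.
#' @return Numeric log2 effect sizes.
#' @export
effect_size <- function(mean_maternal, mean_paternal, pseudocount = 0.5) {
  if (any(mean_maternal < 0) || any(mean_paternal < 0))
    stop("group means must be nonnegative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((mean_maternal + pseudocount) / (mean_paternal + pseudocount))
}

#' Full per-stage inheritance and regulatory classification
#'
#' For every stage, runs the five tests (P: parents; H: hybrid alleles;
#' M: hybrid total vs maternal species; F: hybrid total vs paternal
#' species; T: ratio divergence), BH-adjusts p within each (contrast,
#' stage) family, and applies the two decision tables.  The dispersion
#' is a pooled method-of-moments estimate over the five per-stage
#' replicate groups.
#'
#' @param x An [atac_counts]; size factors are computed with the
#'   "inherit" policy if absent.
#' @param samples Descriptor table.
#' @param alpha Significance level on the (adjusted) p (default 0.05).
#' @param pseudocount psi for ratios and effect sizes (default 0.5).
#' @param use_adjusted_p Threshold BH-adjusted p (default) or raw p.
#' @param require_parental_sig See [classify_regulatory()].
#' @return list(calls, tests, tallies): per-peak-per-stage mode calls
#'   with effect sizes and the five adjusted p-values; the long-format
#'   test table; per-stage mode tallies (counts and proportions).
#' @export
classify_all <- function(x, samples, alpha = 0.05, pseudocount = 0.5,
                         use_adjusted_p = TRUE,
                         require_parental_sig = TRUE) {
  stopifnot(inherits(x, "atac_counts"))
  samples <- validate_samples(samples)
  if (is.null(x$size_factors))
    x <- normalize_counts(x, samples, policy = "inherit")
  stages <- unique(samples$stage)
  calls_list <- tests_list <- list()
  for (st in stages) {
    g_mat <- sample_group(samples, "maternal_species", st)
    g_pat <- sample_group(samples, "paternal_species", st)
    g_hyb <- sample_group(samples, "hybrid", st, "total")
    g_hm <- sample_group(samples, "hybrid", st, "maternal")
    g_hp <- sample_group(samples, "hybrid", st, "paternal")
    if (length(g_mat) == 0 || length(g_pat) == 0 || length(g_hyb) == 0)
      stop("stage '", st, "' lacks one of the three crosses")
    disp <- estimate_dispersion(
      x, list(g_mat, g_pat, g_hyb, g_hm, g_hp), prior_df = 20)
    P <- wald_test(x, g_mat, g_pat, disp, pseudocount)
    M <- wald_test(x, g_hyb, g_mat, disp, pseudocount)
    F_ <- wald_test(x, g_hyb, g_pat, disp, pseudocount)
    H <- if (length(g_hm) > 0 && length(g_hp) > 0)
      wald_test(x, g_hm, g_hp, disp, pseudocount) else
      stop("stage '", st, "' lacks split hybrid allele columns")
    T_ <- ratio_divergence_test(P, H)
    res <- list(P = P, H = H, M = M, "F" = F_, "T" = T_)
    padj <- lapply(res, function(r) bh_adjust(r$p))
    sig <- lapply(names(res), function(k)
      (if (use_adjusted_p) padj[[k]] else res[[k]]$p) <= alpha)
    names(sig) <- names(res)

    inh <- classify_inheritance(sig$P, sig$M, sig$F,
                                mean_maternal = P$mean1,
                                mean_paternal = P$mean2,
                                mean_hybrid = M$mean1)
    reg <- classify_regulatory(sig$P, sig$H, sig$T,
                               l_h = H$log2_ratio, l_t = T_$log2_ratio,
                               require_parental_sig = require_parental_sig)
    es <- effect_size(P$mean1, P$mean2, pseudocount)
    calls_list[[st]] <- data.frame(
      peak_id = P$peak_id, stage = st,
      inheritance_mode = inh, regulatory_mode = reg, effect_size = es,
      padj_P = padj$P, padj_H = padj$H, padj_M = padj$M,
      padj_F = padj$F, padj_T = padj$T,
      lfc_P = P$log2_ratio, lfc_H = H$log2_ratio,
      lfc_T = T_$log2_ratio,
      stringsAsFactors = FALSE)
    tests_list[[st]] <- do.call(rbind, lapply(names(res), function(k)
      data.frame(peak_id = res[[k]]$peak_id, stage = st, contrast = k,
                 log2_ratio = res[[k]]$log2_ratio, se = res[[k]]$se,
                 z = res[[k]]$z, p = res[[k]]$p, padj = padj[[k]],
                 stringsAsFactors = FALSE)))
  }
  calls <- do.call(rbind, calls_list)
  rownames(calls) <- NULL
  tests <- do.call(rbind, tests_list)
  rownames(tests) <- NULL
  list(calls = calls, tests = tests, tallies = mode_tallies(calls))
}

#' Per-stage tallies of mode calls
#'
#' @param calls The calls table from [classify_all()].
#' @return data.frame(stage, classification, mode, n, proportion).
#' @export
mode_tallies <- function(calls) {
  out <- list()
  if (nrow(calls) == 0)
    return(data.frame(stage = character(), classification = character(),
                      mode = character(), n = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  for (st in unique(calls$stage)) {
    sub <- calls[calls$stage == st, ]
    for (cl in c("inheritance", "regulatory")) {
      vocab <- if (cl == "inheritance") INHERITANCE_MODES else
        c(REGULATORY_MODES, "ambiguous")
      v <- sub[[paste0(cl, "_mode")]]
      tab <- table(factor(v, levels = vocab))
      out[[paste(st, cl)]] <- data.frame(
        stage = st, classification = cl, mode = names(tab),
        n = as.integer(tab),
        proportion = as.numeric(tab) / nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mode switching between consecutive developmental stages
#'
#' @param calls Calls table from [classify_all()] (needs >= 2 stages).
#' @param classification "regulatory" or "inheritance".
#' @param stages Optional stage order (default: order of appearance).
#' @return list(per_peak = data.frame(peak_id, n_switches),
#'   transitions = from x to count matrix over the mode vocabulary,
#'   n_switch_total).
#' @export
count_mode_switches <- function(calls,
                                classification = c("regulatory",
                                                   "inheritance"),
                                stages = NULL) {
  classification <- match.arg(classification)
  if (is.null(stages)) stages <- unique(calls$stage)
  if (length(stages) < 2)
    stop("mode switching needs >= 2 stages")
  col <- paste0(classification, "_mode")
  vocab <- if (classification == "inheritance") INHERITANCE_MODES else
    c(REGULATORY_MODES, "ambiguous")
  wide <- lapply(stages, function(st) {
    sub <- calls[calls$stage == st, c("peak_id", col)]
    stats::setNames(sub[[col]], sub$peak_id)
  })
  peaks <- Reduce(intersect, lapply(wide, names))
  trans <- matrix(0L, length(vocab), length(vocab),
                  dimnames = list(from = vocab, to = vocab))
  n_sw <- stats::setNames(integer(length(peaks)), peaks)
  for (k in seq_len(length(stages) - 1)) {
    from <- wide[[k]][peaks]
    to <- wide[[k + 1]][peaks]
    n_sw <- n_sw + (from != to)
    tab <- table(factor(from, vocab), factor(to, vocab))
    trans <- trans + tab
  }
  list(per_peak = data.frame(peak_id = peaks, n_switches = unname(n_sw),
                             stringsAsFactors = FALSE),
       transitions = trans,
       n_switch_total = sum(n_sw))
}

#' Top-k peaks by absolute evolutionary effect size
#'
#' Orders peaks by decreasing |ES| (ties broken by lexicographically
#' smaller peak_id) and reports the regulatory-mode composition of the
#' top k against the overall composition.
#'
#' @param calls Calls table for a single stage (or pass `stage`).
#' @param k Number of top peaks (1 <= k <= number of peaks).
#' @param stage Optional stage to subset.
#' @return list(top = the top-k rows, mode_fractions, overall_fractions).
#' @export
rank_by_effect <- function(calls, k, stage = NULL) {
  if (!is.null(stage)) calls <- calls[calls$stage == stage, ]
  if (length(unique(calls$stage)) > 1)
    stop("rank_by_effect operates on a single stage; pass `stage`")
  if (k <= 0) stop("k must be positive")
  if (k > nrow(calls)) stop("k exceeds the number of peaks")
  ord <- order(-abs(calls$effect_size), calls$peak_id)
  top <- calls[ord[seq_len(k)], ]
  vocab <- c(REGULATORY_MODES, "ambiguous")
  frac <- function(v) {
    tab <- table(factor(v, levels = vocab))
    as.numeric(tab) / length(v)
  }
  list(top = top,
       mode_fractions = stats::setNames(frac(top$regulatory_mode), vocab),
       overall_fractions = stats::setNames(frac(calls$regulatory_mode),
                                           vocab))
}
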