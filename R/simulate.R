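#' Effect-size law for simulated cis/trans shifts
#'
#' Describes the distribution of absolute log2 effect magnitudes |c| and
#' |t| used by [make_truth()].
#'
#' @param dist One of `"fixed"`, `"uniform"`, `"lognormal"`, `"gamma"`.
#' @param ... Parameters of the chosen law: `value` (fixed); `min`,`max`
#'   (uniform); `meanlog`,`sdlog` (lognormal); `shape`,`rate` (gamma).
#' @return A list of class `effect_law`.
#' @export
effect_law <- function(dist = c("fixed", "uniform", "lognormal", "gamma"),
                       ...) {
  dist <- match.arg(dist)
  law <- c(list(dist = dist), list(...))
  defaults <- switch(dist,
    fixed     = list(value = 1.5),
    uniform   = list(min = 0.5, max = 2.5),
    lognormal = list(meanlog = 0.3, sdlog = 0.4),
    gamma     = list(shape = 4, rate = 2.5))
  for (nm in names(defaults))
    if (is.null(law[[nm]])) law[[nm]] <- defaults[[nm]]
  structure(law, class = "effect_law")
}

draw_abs_effects <- function(law, n) {
  if (n == 0) return(numeric(0))
  switch(law$dist,
    fixed     = rep(law$value, n),
    uniform   = stats::runif(n, law$min, law$max),
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
    gamma     = stats::rgamma(n, shape = law$shape, rate = law$rate),
    stop("unknown effect law: ", law$dist))
}

REGULATORY_MODES <- c("conserved", "cis", "trans", "cis_plus_trans",
                      "cis_x_trans", "compensatory")

INHERITANCE_MODES <- c("conserved", "additive", "maternal_dominant",
                       "paternal_dominant", "overdominant",
                       "underdominant", "ambiguous")

# deterministic largest-remainder apportionment of n among props
largest_remainder <- function(n, props) {
  exact <- n * props
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate per-peak ground truth for the count simulator
#'
#' Each peak gets a true regulatory mode and log2 cis (`c`) and trans
#' (`t`) shifts satisfying the mode's sign constraints: conserved has
#' c = t = 0; cis has t = 0; trans has c = 0; cis_plus_trans has equal
#' signs; cis_x_trans opposite signs; compensatory has t = -c exactly
#' (parents match while hybrid alleles diverge).  For cis_x_trans, if the
#' drawn magnitudes would cancel exactly (|c| = |t|, which is the
#' compensatory geometry) the trans magnitude is doubled so the class
#' remains identifiable.
#'
#' @param n_peaks Number of peaks (>= 1).
#' @param mode_proportions Named fractions over the regulatory modes,
#'   summing to 1; class counts use largest-remainder rounding.
#' @param effect_size_law An [effect_law()] for |c| and |t|, or a list
#'   `list(cis = , trans = )` with separate laws.
#' @param baseline_mean Expected reads per peak in the paternal
#'   (reference) species; scalar or length-`n_peaks` vector.
#' @param dispersion Negative-binomial dispersion (variance =
#'   m + dispersion * m^2); scalar or per-peak vector, all > 0.
#' @param trans_dominance Fraction `d` in \[0, 1\] of the trans shift
#'   expressed in the hybrid nuclear environment (0.5 = intermediate
#'   blend, 1 = full maternal trans dominance).
#' @param seed Integer RNG seed.
#' @return data.frame of class `truth_table` with columns peak_id,
#'   baseline_mean, cis_shift, trans_shift, trans_dominance, dispersion,
#'   true_regulatory_mode.
#' @export
make_truth <- function(n_peaks,
                       mode_proportions = c(conserved = 0.60, cis = 0.15,
                                            trans = 0.15,
                                            cis_plus_trans = 0.03,
                                            cis_x_trans = 0.03,
                                            compensatory = 0.04),
                       effect_size_law = effect_law("fixed", value = 1.5),
                       baseline_mean = 300,
                       dispersion = 0.05,
                       trans_dominance = 0.5,
                       seed = 1L) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  bad <- setdiff(names(mode_proportions), REGULATORY_MODES)
  if (length(bad) > 0)
    stop("unknown regulatory mode(s): ", paste(bad, collapse = ", "))
  s <- sum(mode_proportions)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("mode proportions must sum to 1 (got %.12g)", s))
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (any(trans_dominance < 0 | trans_dominance > 1))
    stop("trans_dominance must lie in [0, 1]")
  if (inherits(effect_size_law, "effect_law"))
    effect_size_law <- list(cis = effect_size_law, trans = effect_size_law)
  stopifnot(all(c("cis", "trans") %in% names(effect_size_law)))

  quota <- largest_remainder(n_peaks, mode_proportions)
  mode <- rep(names(quota), quota)

  set.seed(seed)
  c_abs <- draw_abs_effects(effect_size_law$cis, n_peaks)
  t_abs <- draw_abs_effects(effect_size_law$trans, n_peaks)
  sgn <- sample(c(-1, 1), n_peaks, replace = TRUE)
  t_sgn <- sample(c(-1, 1), n_peaks, replace = TRUE)

  cis <- numeric(n_peaks)
  trans <- numeric(n_peaks)
  i <- mode == "cis"
  cis[i] <- sgn[i] * c_abs[i]
  i <- mode == "trans"
  trans[i] <- t_sgn[i] * t_abs[i]
  i <- mode == "cis_plus_trans"
  cis[i] <- sgn[i] * c_abs[i]
  trans[i] <- sgn[i] * t_abs[i]
  i <- mode == "cis_x_trans"
  tm <- ifelse(t_abs[i] == c_abs[i], 2 * c_abs[i], t_abs[i])
  cis[i] <- sgn[i] * c_abs[i]
  trans[i] <- -sgn[i] * tm
  i <- mode == "compensatory"
  cis[i] <- sgn[i] * c_abs[i]
  trans[i] <- -cis[i]

  wid <- max(6, nchar(as.character(n_peaks)))
  truth <- data.frame(
    peak_id = sprintf(paste0("peak_%0", wid, "d"), seq_len(n_peaks)),
    baseline_mean = rep_len(baseline_mean, n_peaks),
    cis_shift = cis,
    trans_shift = trans,
    trans_dominance = rep_len(trans_dominance, n_peaks),
    dispersion = rep_len(dispersion, n_peaks),
    true_regulatory_mode = mode,
    stringsAsFactors = FALSE)
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Simulation design: crosses, stages, replication and depth
#'
#' @param stages Ordered character vector of developmental stages.
#' @param replicates Replicates per cross per stage (>= 2).
#' @param depth_scale Per-sample library-size multipliers: scalar, or a
#'   named vector keyed by sample id (unnamed samples get 1).
#' @param seed Integer RNG seed for the count draws.
#' @param stage_effects Optional numeric matrix (peaks x stages) of
#'   multipliers on the baseline mean, to emulate stage-specific
#'   accessibility and mode switching.  Default: all 1.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(stages = c("blastula", "gastrula", "larva"),
                              replicates = 3L,
                              depth_scale = 1,
                              seed = 1L,
                              stage_effects = NULL) {
  replicates <- as.integer(replicates)
  if (replicates < 2) stop("replicates must be >= 2 (variance estimable)")
  if (any(depth_scale <= 0)) stop("depth multipliers must be positive")
  if (length(stages) < 1) stop("need at least one stage")
  structure(list(stages = stages, replicates = replicates,
                 depth_scale = depth_scale, seed = as.integer(seed),
                 stage_effects = stage_effects),
            class = "simulation_design")
}

#' Simulate allele-specific ATAC-seq counts from ground truth
#'
#' Expected group means follow the hybrid cis/trans model with baseline
#' mean m, cis shift c, trans shift t and hybrid trans dominance d:
#' maternal-species total m * 2^(c+t); paternal-species total m; hybrid
#' maternal allele (m/2) * 2^(c + d t); hybrid paternal allele
#' (m/2) * 2^(d t).  Counts are drawn NB(mean x library multiplier,
#' dispersion); each hybrid total column is the exact sum of its two
#' allele columns (one library, not a new draw).
#'
#' @param truth A [make_truth()] table.
#' @param design A [simulation_design()].
#' @return list(counts = [atac_counts], samples = descriptor data.frame).
#' @export
simulate_counts <- function(truth, design) {
  stopifnot(inherits(design, "simulation_design"))
  if (nrow(truth) == 0) stop("truth must be nonempty")
  if (any(truth$dispersion <= 0)) stop("dispersion must be positive")
  n <- nrow(truth)
  reps <- design$replicates
  stages <- design$stages

  samples <- do.call(rbind, lapply(stages, function(st) {
    rbind(
      data.frame(sample_id = sprintf("matsp_%s_r%d", st, seq_len(reps)),
                 cross = "maternal_species", stage = st,
                 replicate = seq_len(reps), allele = "total"),
      data.frame(sample_id = sprintf("patsp_%s_r%d", st, seq_len(reps)),
                 cross = "paternal_species", stage = st,
                 replicate = seq_len(reps), allele = "total"),
      data.frame(sample_id = sprintf("hyb_%s_r%d_total", st, seq_len(reps)),
                 cross = "hybrid", stage = st,
                 replicate = seq_len(reps), allele = "total"),
      data.frame(sample_id = sprintf("hyb_%s_r%d_mat", st, seq_len(reps)),
                 cross = "hybrid", stage = st,
                 replicate = seq_len(reps), allele = "maternal"),
      data.frame(sample_id = sprintf("hyb_%s_r%d_pat", st, seq_len(reps)),
                 cross = "hybrid", stage = st,
                 replicate = seq_len(reps), allele = "paternal"))
  }))
  samples <- validate_samples(samples)

  depth <- rep(1, nrow(samples))
  names(depth) <- samples$sample_id
  if (!is.null(names(design$depth_scale))) {
    hit <- intersect(names(design$depth_scale), samples$sample_id)
    depth[hit] <- design$depth_scale[hit]
  } else {
    depth[] <- rep_len(design$depth_scale, nrow(samples))
  }

  ct <- truth$cis_shift + truth$trans_shift
  d <- truth$trans_dominance
  size <- 1 / truth$dispersion

  m <- matrix(0, nrow = n, ncol = nrow(samples),
              dimnames = list(truth$peak_id, samples$sample_id))
  set.seed(design$seed)
  for (st in stages) {
    mult <- if (is.null(design$stage_effects)) 1 else
      design$stage_effects[, st]
    mu_mat <- truth$baseline_mean * mult * 2^ct
    mu_pat <- truth$baseline_mean * mult
    mu_hm <- truth$baseline_mean * mult / 2 * 2^(truth$cis_shift +
                                                 d * truth$trans_shift)
    mu_hp <- truth$baseline_mean * mult / 2 * 2^(d * truth$trans_shift)
    for (r in seq_len(reps)) {
      id <- sprintf("matsp_%s_r%d", st, r)
      m[, id] <- stats::rnbinom(n, mu = mu_mat * depth[id], size = size)
      id <- sprintf("patsp_%s_r%d", st, r)
      m[, id] <- stats::rnbinom(n, mu = mu_pat * depth[id], size = size)
      idt <- sprintf("hyb_%s_r%d_total", st, r)
      idm <- sprintf("hyb_%s_r%d_mat", st, r)
      idp <- sprintf("hyb_%s_r%d_pat", st, r)
      m[, idm] <- stats::rnbinom(n, mu = mu_hm * depth[idt], size = size)
      m[, idp] <- stats::rnbinom(n, mu = mu_hp * depth[idt], size = size)
      m[, idt] <- m[, idm] + m[, idp]
    }
  }
  list(counts = atac_counts(m), samples = samples)
}
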