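#' Pipeline configuration
#'
#' Assembles and validates the knobs of a full run.  Values not supplied
#' fall back to defaults; a YAML file with the same nesting can be read
#' with [read_pipeline_config()].
#'
#' @param simulation Named list of generator settings (n_peaks,
#'   mode_proportions, effect (fixed |c|,|t| value), baseline_mean,
#'   dispersion, trans_dominance, stages, replicates, n_genes,
#'   chrom_length, placement, grn_fraction, tf_fraction, grn_weight,
#'   coupling_odds, base_rate).  Set to NULL when reading existing
#'   files via `inputs`.
#' @param inputs Named list of file paths (counts, samples, peaks,
#'   genes, expression) when not simulating.
#' @param alpha Significance level in (0, 1).
#' @param use_adjusted_p Threshold BH-adjusted p (default TRUE).
#' @param pseudocount Pseudocount for log ratios (> 0).
#' @param min_cpm,min_fraction CPM filter settings.
#' @param window_bp Peak-gene window (>= proximal_bp).
#' @param proximal_bp Proximal category bound (> 0).
#' @param require_parental_sig See [classify_regulatory()].
#' @param seed Integer root seed; module substreams are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), inputs = NULL,
                            alpha = 0.05, use_adjusted_p = TRUE,
                            pseudocount = 0.5, min_cpm = 3,
                            min_fraction = 1 / 3, window_bp = 25000,
                            proximal_bp = 500,
                            require_parental_sig = TRUE, seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(window_bp >= proximal_bp && proximal_bp > 0))
    stop("need window_bp >= proximal_bp > 0")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  sim_defaults <- list(
    n_peaks = 1200, n_genes = 400, chrom_length = 24000000,
    mode_proportions = c(conserved = 0.60, cis = 0.15, trans = 0.15,
                         cis_plus_trans = 0.03, cis_x_trans = 0.03,
                         compensatory = 0.04),
    effect = 1.5, baseline_mean = 300, dispersion = 0.05,
    trans_dominance = 0.5,
    stages = c("blastula", "gastrula", "larva"), replicates = 3,
    placement = c(proximal = 0.3, distal = 0.5, beyond = 0.2),
    grn_fraction = 0.1, tf_fraction = 0.3, grn_weight = 1,
    coupling_odds = 3, base_rate = 0.2)
  if (!is.null(simulation)) {
    if (!is.null(simulation$mode_proportions))
      simulation$mode_proportions <- unlist(simulation$mode_proportions)
    if (!is.null(simulation$placement))
      simulation$placement <- unlist(simulation$placement)
    for (nm in names(sim_defaults))
      if (is.null(simulation[[nm]])) simulation[[nm]] <- sim_defaults[[nm]]
  }
  structure(list(simulation = simulation, inputs = inputs,
                 alpha = alpha, use_adjusted_p = use_adjusted_p,
                 pseudocount = pseudocount, min_cpm = min_cpm,
                 min_fraction = min_fraction, window_bp = window_bp,
                 proximal_bp = proximal_bp,
                 require_parental_sig = require_parental_sig,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

pipeline_dataset <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (req in c("counts", "samples"))
      if (is.null(inp[[req]]))
        stop("input configuration lacks the '", req, "' path")
    for (nm in names(inp))
      if (!file.exists(inp[[nm]]))
        stop("configured input file does not exist: ", inp[[nm]])
    return(c(do.call(read_inputs, inp), list(truth = NULL)))
  }
  sim <- config$simulation
  truth <- make_truth(sim$n_peaks,
                      mode_proportions = sim$mode_proportions,
                      effect_size_law = effect_law("fixed",
                                                   value = sim$effect),
                      baseline_mean = sim$baseline_mean,
                      dispersion = sim$dispersion,
                      trans_dominance = sim$trans_dominance,
                      seed = config$seed)
  design <- simulation_design(stages = sim$stages,
                              replicates = sim$replicates,
                              seed = config$seed + 1L)
  cs <- simulate_counts(truth, design)
  ann <- make_annotation(sim$n_genes, sim$chrom_length, truth,
                         placement = sim$placement,
                         grn_fraction = sim$grn_fraction,
                         tf_fraction = sim$tf_fraction,
                         grn_weight = sim$grn_weight,
                         seed = config$seed + 2L)
  expr <- simulate_expression_table(ann$genes, truth, ann$distances,
                                    coupling_odds = sim$coupling_odds,
                                    base_rate = sim$base_rate,
                                    stages = sim$stages,
                                    window = config$window_bp,
                                    seed = config$seed + 3L)
  list(counts = cs$counts, samples = cs$samples, peaks = ann$peaks,
       genes = ann$genes, expression = expr, truth = truth)
}

flatten_assoc <- function(res, stage) {
  data.frame(test = res$name, stage = stage,
             n11 = res$table[1, 1], n12 = res$table[1, 2],
             n21 = res$table[2, 1], n22 = res$table[2, 2],
             statistic = res$statistic, df = res$df,
             p = res$p.value,
             r11 = res$residuals[1, 1], r12 = res$residuals[1, 2],
             r21 = res$residuals[2, 1], r22 = res$residuals[2, 2],
             odds_ratio = res$odds_ratio,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> write dataset -> preprocess (CPM filter,
#' median-of-ratios size factors, log transform, PCA) -> differential
#' tests and mode classification -> peak-gene association and landscape
#' contrasts -> report.  Every stage writes its outputs as TSV under
#' `outdir`; downstream stages consume only those declared outputs, so
#' any stage can be re-run from files.  Deterministic for a fixed seed.
#' On stage failure the completed outputs are left in place and an
#' `error.json` manifest is written.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(outdir, "data")
  stage_done <- character()
  manifest <- list(config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("chromdiverge")),
                   r_version = R.version.string,
                   rows = list())
  fail <- function(stage, err) {
    manifest$error <- list(stage = stage,
                           message = conditionMessage(err))
    manifest$stages_completed <- stage_done
    jsonlite::write_json(manifest, file.path(outdir, "error.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ",
         conditionMessage(err), call. = FALSE)
  }

  # --- simulate / ingest -------------------------------------------------
  ds <- tryCatch(pipeline_dataset(config), error = function(e)
    fail("simulate", e))
  write_dataset(data_dir, ds$counts, ds$samples, ds$peaks, ds$genes,
                ds$expression, ds$truth)
  ds <- c(read_inputs(file.path(data_dir, "counts.tsv"),
                      file.path(data_dir, "samples.tsv"),
                      file.path(data_dir, "peaks.bed"),
                      if (!is.null(ds$genes)) file.path(data_dir, "genes.tsv"),
                      if (!is.null(ds$expression))
                        file.path(data_dir, "expression.tsv")),
          list())
  manifest$rows$peaks_in <- nrow(ds$counts$counts)
  stage_done <- c(stage_done, "simulate")

  # --- preprocess --------------------------------------------------------
  pre <- tryCatch({
    flt <- cpm_filter(ds$counts, ds$samples, config$min_cpm,
                      config$min_fraction)
    flt <- normalize_counts(flt, ds$samples, policy = "inherit")
    tr <- transform_counts(flt, pseudocount = 1)
    pca <- run_pca(tr)
    list(flt = flt, pca = pca)
  }, error = function(e) fail("preprocess", e))
  write_counts_tsv(pre$flt, file.path(outdir, "filtered_counts.tsv"))
  write_tsv(data.frame(sample_id = names(pre$flt$size_factors),
                       size_factor = unname(pre$flt$size_factors)),
            file.path(outdir, "size_factors.tsv"))
  write_tsv(data.frame(sample_id = rownames(pre$pca$coordinates),
                       round(pre$pca$coordinates, 6),
                       check.names = FALSE),
            file.path(outdir, "pca_coordinates.tsv"))
  write_tsv(data.frame(component = seq_along(pre$pca$var_fraction),
                       var_fraction = round(pre$pca$var_fraction, 6)),
            file.path(outdir, "pca_variance.tsv"))
  manifest$rows$peaks_retained <- nrow(pre$flt$counts)
  stage_done <- c(stage_done, "preprocess")

  # --- classify ----------------------------------------------------------
  cls <- tryCatch(
    classify_all(pre$flt, ds$samples, alpha = config$alpha,
                 pseudocount = config$pseudocount,
                 use_adjusted_p = config$use_adjusted_p,
                 require_parental_sig = config$require_parental_sig),
    error = function(e) fail("classify", e))
  write_tsv(cls$tests, file.path(outdir, "tests.tsv"))
  write_tsv(cls$calls, file.path(outdir, "mode_calls.tsv"))
  write_tsv(cls$tallies, file.path(outdir, "mode_tallies.tsv"))
  stages <- unique(ds$samples$stage)
  if (length(stages) >= 2) {
    sw <- count_mode_switches(cls$calls, "regulatory", stages)
    write_tsv(sw$per_peak, file.path(outdir, "mode_switches.tsv"))
  }
  manifest$rows$mode_calls <- nrow(cls$calls)
  stage_done <- c(stage_done, "classify")

  # --- associate ---------------------------------------------------------
  if (!is.null(ds$genes)) {
    assoc <- tryCatch({
      peaks_flt <- ds$peaks[ds$peaks$peak_id %in%
                              rownames(pre$flt$counts), ]
      links <- nearest_gene(peaks_flt, ds$genes, config$proximal_bp,
                            config$window_bp)
      rows <- list()
      dens <- NULL
      for (st in stages) {
        sub <- cls$calls[cls$calls$stage == st, ]
        da <- stats::setNames(sub$padj_P <= config$alpha, sub$peak_id)
        ex <- ds$expression[ds$expression$stage == st, ]
        de <- stats::setNames(ex$de_status %in% c(TRUE, "TRUE", 1),
                              ex$gene_id)
        em <- stats::setNames(ex$expr_mode, ex$gene_id)
        rows[[paste(st, "pf")]] <-
          flatten_assoc(peaks_focused_test(links, da, de), st)
        rows[[paste(st, "gf")]] <-
          flatten_assoc(gene_focused_test(ds$genes, peaks_flt, da, de,
                                          config$window_bp), st)
        rm_ <- regmode_focused_test(ds$genes, peaks_flt, da, de, em,
                                    config$window_bp)
        rows[[paste(st, "rm_cis")]] <- flatten_assoc(rm_$cis, st)
        rows[[paste(st, "rm_trans")]] <- flatten_assoc(rm_$trans, st)
      }
      dens <- peak_density(ds$genes, peaks_flt, config$window_bp)
      dens$is_tf <- ds$genes$is_tf
      dens$is_grn <- ds$genes$is_grn
      list(links = links,
           table = do.call(rbind, rows), density = dens)
    }, error = function(e) fail("associate", e))
    write_tsv(assoc$links, file.path(outdir, "nearest_gene.tsv"))
    write_tsv(assoc$table, file.path(outdir, "associations.tsv"))
    write_tsv(assoc$density, file.path(outdir, "peak_density.tsv"))
    manifest$rows$associations <- nrow(assoc$table)
    stage_done <- c(stage_done, "associate")
  }

  # --- report ------------------------------------------------------------
  rep <- tryCatch(pipeline_report(outdir), error = function(e)
    fail("report", e))
  manifest$stages_completed <- c(stage_done, "report")
  out_files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  out_files <- setdiff(out_files, file.path(outdir, "manifest.json"))
  md5 <- tools::md5sum(sort(out_files))
  names(md5) <- substring(names(md5), nchar(outdir) + 2)
  manifest$config_hash <- unname(tools::md5sum(
    file.path(outdir, "report.json")))
  manifest$file_md5 <- as.list(md5)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Aggregate stage outputs into a machine-readable report
#'
#' Reads only the per-stage TSV outputs of [run_pipeline()] under
#' `outdir`, aggregates them (mode tallies per stage, association tables
#' with residuals, proximal/distal and GRN density summaries), and
#' writes `report.json`.  Every number in the JSON is re-derivable from
#' the stage TSVs.
#'
#' @param outdir A directory produced by [run_pipeline()].
#' @return Invisibly, the report list.
#' @export
pipeline_report <- function(outdir) {
  need <- file.path(outdir, c("mode_calls.tsv", "mode_tallies.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss) > 0)
    stop("missing stage output(s): ", paste(miss, collapse = ", "))
  calls <- read_tsv(file.path(outdir, "mode_calls.tsv"))
  tallies <- read_tsv(file.path(outdir, "mode_tallies.tsv"))
  rep <- list(n_peaks = length(unique(calls$peak_id)),
              stages = unique(calls$stage),
              mode_tallies = tallies)
  ap <- file.path(outdir, "associations.tsv")
  if (file.exists(ap)) rep$associations <- read_tsv(ap)
  dp <- file.path(outdir, "peak_density.tsv")
  if (file.exists(dp)) {
    dens <- read_tsv(dp)
    rep$density_summary <- data.frame(
      set = c("all_genes", "tf_genes", "grn_genes"),
      n_genes = c(nrow(dens), sum(dens$is_tf), sum(dens$is_grn)),
      mean_peaks = c(mean(dens$n_peaks),
                     mean(dens$n_peaks[dens$is_tf]),
                     mean(dens$n_peaks[dens$is_grn])))
  }
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rep)
}
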