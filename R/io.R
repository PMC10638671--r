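#' Read / write the package's plain-text interchange formats
#'
#' Counts, samples, genes, expression and truth tables are tab-separated
#' with a header; peaks and reads are BED (0-based, half-open).
#'
#' @name chromdiverge-io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' @rdname chromdiverge-io
#' @param x An [atac_counts] object.
#' @param path File path.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "atac_counts"))
  df <- data.frame(peak_id = rownames(x$counts),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname chromdiverge-io
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  if (names(df)[1] != "peak_id") stop("counts TSV must start with peak_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$peak_id
  atac_counts(m)
}

#' @rdname chromdiverge-io
#' @param bed data.frame with columns chrom, start, end (and optionally a
#'   name column).
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "peak_id", "name"),
                    names(bed))
  utils::write.table(bed[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
}

#' @rdname chromdiverge-io
#' @param name_col Name for the optional fourth BED column.
#' @export
read_bed <- function(path, name_col = "peak_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ",
         which(is.na(start) | is.na(end))[1], ": non-integer coordinate")
  bed <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4)) bed[[name_col]] <- vapply(fields, `[`, "", 4)
  bad <- which(bed$start < 0 | bed$start >= bed$end)
  if (length(bad) > 0)
    stop("degenerate interval at BED line ", bad[1],
         ": requires 0 <= start < end")
  if (name_col %in% names(bed) && anyDuplicated(bed[[name_col]]))
    stop("duplicate interval names in ", path)
  bed
}

#' Write a full synthetic dataset to a directory
#'
#' Emits counts.tsv, samples.tsv, peaks.bed, genes.tsv, expression.tsv
#' and truth.tsv (those provided).
#'
#' @param dir Output directory (created if absent).
#' @param counts [atac_counts]; samples/genes/expression/truth/peaks:
#'   the corresponding tables (NULL to skip).
#' @param samples,peaks,genes,expression,truth Optional tables.
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dir, counts, samples = NULL, peaks = NULL,
                          genes = NULL, expression = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  write_counts_tsv(counts, file.path(dir, "counts.tsv"))
  paths["counts"] <- file.path(dir, "counts.tsv")
  if (!is.null(samples)) {
    write_tsv(samples, file.path(dir, "samples.tsv"))
    paths["samples"] <- file.path(dir, "samples.tsv")
  }
  if (!is.null(peaks)) {
    write_bed(peaks, file.path(dir, "peaks.bed"))
    paths["peaks"] <- file.path(dir, "peaks.bed")
  }
  if (!is.null(genes)) {
    write_tsv(genes, file.path(dir, "genes.tsv"))
    paths["genes"] <- file.path(dir, "genes.tsv")
  }
  if (!is.null(expression)) {
    write_tsv(expression, file.path(dir, "expression.tsv"))
    paths["expression"] <- file.path(dir, "expression.tsv")
  }
  if (!is.null(truth)) {
    write_tsv(truth, file.path(dir, "truth.tsv"))
    paths["truth"] <- file.path(dir, "truth.tsv")
  }
  invisible(paths)
}

#' Read a dataset and verify cross-file referential integrity
#'
#' Every counts column must have a sample descriptor and vice versa;
#' when a peaks BED is supplied, every counts row must have an interval.
#'
#' @param counts,samples Paths to the counts and sample TSVs (required).
#' @param peaks,genes,expression,truth Optional paths.
#' @return list(counts, samples, peaks, genes, expression, truth).
#' @export
read_inputs <- function(counts, samples, peaks = NULL, genes = NULL,
                        expression = NULL, truth = NULL) {
  cm <- read_counts_tsv(counts)
  smp <- validate_samples(read_tsv(samples))
  miss <- setdiff(colnames(cm$counts), smp$sample_id)
  if (length(miss) > 0)
    stop("counts column(s) with no sample descriptor: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(smp$sample_id, colnames(cm$counts))
  if (length(miss) > 0)
    stop("sample descriptor(s) with no counts column: ",
         paste(miss, collapse = ", "))
  cm$counts <- cm$counts[, smp$sample_id, drop = FALSE]
  out <- list(counts = cm, samples = smp, peaks = NULL, genes = NULL,
              expression = NULL, truth = NULL)
  if (!is.null(peaks)) {
    pk <- read_bed(peaks)
    miss <- setdiff(rownames(cm$counts), pk$peak_id)
    if (length(miss) > 0)
      stop("counts peak(s) with no interval: ",
           paste(utils::head(miss, 5), collapse = ", "))
    out$peaks <- pk
  }
  if (!is.null(genes)) {
    g <- read_tsv(genes)
    req <- c("gene_id", "chrom", "tls", "strand", "is_tf", "is_grn")
    miss <- setdiff(req, names(g))
    if (length(miss) > 0)
      stop("genes TSV missing column(s): ", paste(miss, collapse = ", "))
    if (any(g$tls < 0)) stop("gene TLS coordinates must be >= 0")
    out$genes <- g
  }
  if (!is.null(expression)) {
    e <- read_tsv(expression)
    req <- c("gene_id", "stage", "de_status", "expr_mode")
    miss <- setdiff(req, names(e))
    if (length(miss) > 0)
      stop("expression TSV missing column(s): ",
           paste(miss, collapse = ", "))
    out$expression <- e
  }
  if (!is.null(truth)) out$truth <- read_tsv(truth)
  out
}
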