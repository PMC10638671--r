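#' Peak-by-sample ATAC-seq count matrix
#'
#' Lightweight container for a nonnegative integer peak-by-sample count
#' matrix plus (optionally) per-sample size factors.  Rows are peaks
#' (rownames are peak identifiers), columns are samples (colnames are
#' sample identifiers).
#'
#' @param counts Integer matrix with unique rownames (peak ids) and unique
#'   colnames (sample ids).  All entries must be nonnegative integers.
#' @param size_factors Optional numeric vector of positive per-sample
#'   scaling constants, named by sample id (or in column order).
#' @return An object of class `atac_counts`: a list with elements
#'   `counts` and `size_factors`.
#' @export
atac_counts <- function(counts, size_factors = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (peak ids)")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique colnames (sample ids)")
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at row '%s', column '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "double"
  x <- structure(list(counts = counts, size_factors = NULL),
                 class = "atac_counts")
  if (!is.null(size_factors)) x <- set_size_factors(x, size_factors)
  x
}

#' @export
print.atac_counts <- function(x, ...) {
  cat(sprintf("atac_counts: %d peaks x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("size factors: %s\n",
              if (is.null(x$size_factors)) "not set" else "set"))
  invisible(x)
}

#' @export
dim.atac_counts <- function(x) dim(x$counts)

#' Attach size factors to a count matrix
#'
#' @param x An [atac_counts] object.
#' @param size_factors Positive numeric vector, one per sample; if named,
#'   names must match sample ids.
#' @return `x` with `size_factors` set.
#' @export
set_size_factors <- function(x, size_factors) {
  stopifnot(inherits(x, "atac_counts"))
  if (length(size_factors) != ncol(x$counts))
    stop("need one size factor per sample")
  if (!is.null(names(size_factors))) {
    if (!setequal(names(size_factors), colnames(x$counts)))
      stop("size factor names do not match sample ids")
    size_factors <- size_factors[colnames(x$counts)]
  } else {
    names(size_factors) <- colnames(x$counts)
  }
  if (any(!is.finite(size_factors)) || any(size_factors <= 0))
    stop("size factors must all be positive and finite")
  x$size_factors <- size_factors
  x
}

# row subset preserving size factors
subset_peaks <- function(x, keep) {
  stopifnot(inherits(x, "atac_counts"))
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Validate a sample descriptor table
#'
#' Descriptors identify each count column as cross (maternal_species,
#' paternal_species or hybrid), developmental stage, replicate and
#' allele-of-origin (total for whole libraries; maternal/paternal for the
#' parent-of-origin split of hybrid reads).
#'
#' @param samples data.frame with columns sample_id, cross, stage,
#'   replicate, allele.
#' @return The validated data.frame (invisibly usable), with `replicate`
#'   coerced to integer.
#' @export
validate_samples <- function(samples) {
  req <- c("sample_id", "cross", "stage", "replicate", "allele")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  ok_cross <- c("maternal_species", "paternal_species", "hybrid")
  bad <- setdiff(unique(samples$cross), ok_cross)
  if (length(bad) > 0)
    stop("unknown cross label(s): ", paste(bad, collapse = ", "))
  ok_allele <- c("total", "maternal", "paternal")
  bad <- setdiff(unique(samples$allele), ok_allele)
  if (length(bad) > 0)
    stop("unknown allele label(s): ", paste(bad, collapse = ", "))
  off <- samples$allele != "total" & samples$cross != "hybrid"
  if (any(off))
    stop("allele-of-origin columns are only defined for the hybrid cross: ",
         paste(samples$sample_id[off], collapse = ", "))
  samples$replicate <- as.integer(samples$replicate)
  key <- paste(samples$cross, samples$stage, samples$replicate,
               samples$allele)
  if (anyDuplicated(key))
    stop("(cross, stage, replicate, allele) must be unique")
  samples
}

# sample ids for one (cross, stage, allele) group, in table order
sample_group <- function(samples, cross, stage = NULL, allele = "total") {
  sel <- samples$cross == cross & samples$allele == allele
  if (!is.null(stage)) sel <- sel & samples$stage == stage
  samples$sample_id[sel]
}
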