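#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of sorted values.  Within-sample rank order is
#' preserved and ties receive the average of the tied target values
#' (delegated to [limma::normalizeQuantiles()] with `ties = TRUE`).
#' Idempotent up to floating-point noise.
#'
#' @param x an [expression_matrix()].
#' @return quantile-normalized matrix on the same scale.
#' @export
quantile_normalize <- function(x) {
  sc <- expr_scale(x)
  if (anyNA(x)) abort_fmt("quantile_normalize: missing values not allowed")
  if (ncol(x) < 2L) {
    warn_fmt("quantile_normalize: single sample, returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  set_scale(out, sc)
}

#' Log2-transform raw expression values
#'
#' Applies `log2(v + offset)` to every cell.  The conventional offset of 1
#' keeps zero FPKM at zero; microarray intensities that are already
#' strictly positive can use `offset = 0`.
#'
#' @param x an [expression_matrix()] with `scale = "raw"`.
#' @param offset non-negative pseudocount.
#' @return matrix with `scale = "log2"`.
#' @export
log2_transform <- function(x, offset = 1) {
  if (expr_scale(x) != "raw")
    abort_fmt("log2_transform: input is already on the log2 scale")
  if (offset < 0) abort_fmt("log2_transform: offset must be non-negative")
  if (any(x < 0)) abort_fmt("log2_transform: negative expression values")
  if (offset == 0 && any(x == 0))
    abort_fmt("log2_transform: zero values with offset 0 (log of zero)")
  set_scale(log2(x + offset), "log2")
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (probe id, gene id).  Many probes may map to one gene;
#' probes absent from the map are treated as unmappable.
#'
#' @param path TSV path.
#' @return named character vector, `names` = probe ids, values = gene ids.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) abort_fmt("%s: probe map needs two columns (probe, gene)", path)
  probes <- df[[1L]]
  if (anyDuplicated(probes))
    abort_fmt("%s: duplicate probe ids in map", path)
  setNames(df[[2L]], probes)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Multi-probe genes become the per-sample arithmetic mean of their
#' probes' values; probes without a map entry are removed.  The result is
#' invariant to the order of probe rows (genes are emitted in sorted
#' order).
#'
#' @param x probe-level [expression_matrix()] (rows = probe ids).
#' @param probe_map named character vector from [read_probe_map()].
#' @return gene-level expression matrix.
#' @export
collapse_probes <- function(x, probe_map) {
  sc <- expr_scale(x)
  mapped <- intersect(rownames(x), names(probe_map))
  if (!length(mapped))
    abort_fmt("collapse_probes: no probes in the matrix are present in the map")
  genes <- probe_map[mapped]
  sums <- rowsum(x[mapped, , drop = FALSE], group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  expression_matrix(set_scale(out, sc), sc)
}

#' Remove genes that are mostly zero
#'
#' Drops genes whose proportion of exact-zero samples is at least
#' `zero_fraction`.  Intended for RNA-seq FPKM matrices, where pervasive
#' zeros mark genes with no usable signal; microarray intensities are
#' essentially never exactly zero, so this filter is a no-op there.
#'
#' @param x raw-scale [expression_matrix()].
#' @param zero_fraction removal threshold on the zero proportion
#'   (default 0.5, i.e. zero in at least half the samples).
#' @return filtered matrix; the number of removed genes is reported via
#'   `attr(, "n_removed")` and a message.
#' @export
filter_low_expression <- function(x, zero_fraction = 0.5) {
  if (expr_scale(x) != "raw")
    abort_fmt("filter_low_expression operates on raw (FPKM) values")
  zero_prop <- rowMeans(x == 0)
  keep <- zero_prop < zero_fraction
  message(sprintf("filter_low_expression: removed %d of %d genes",
                  sum(!keep), nrow(x)))
  out <- set_scale(x[keep, , drop = FALSE], "raw")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Empirical-Bayes batch correction
#'
#' Parametric location/scale batch adjustment with no biological
#' covariates: per-gene standardization, empirical-Bayes shrinkage of
#' batch means (normal prior) and batch variances (inverse-gamma prior),
#' then back-transformation.  Delegated to [sva::ComBat()], the standard
#' implementation of this estimator.
#'
#' @param x an [expression_matrix()] (log-scale data expected).
#' @param batch per-sample batch labels (length `ncol(x)`).
#' @return batch-adjusted matrix.
#' @export
combat_adjust <- function(x, batch) {
  sc <- expr_scale(x)
  batch <- as.factor(batch)
  if (length(batch) != ncol(x))
    abort_fmt("combat_adjust: need one batch label per sample")
  if (nlevels(droplevels(batch)) < 2L) {
    warn_fmt("combat_adjust: single batch, returning input unchanged")
    return(x)
  }
  small <- table(batch)
  if (any(small < 2L))
    abort_fmt("combat_adjust: batch(es) with fewer than 2 samples: %s",
              paste(names(small)[small < 2L], collapse = ", "))
  out <- suppressMessages(sva::ComBat(dat = x, batch = batch, mod = NULL,
                                      par.prior = TRUE, prior.plots = FALSE))
  dimnames(out) <- dimnames(x)
  set_scale(out, sc)
}
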