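#' Read a gene-pair (REO) signature
#'
#' Two-column TSV (`gene_a`, `gene_b`) with the convention that
#' expression of `gene_a` exceeding `gene_b` within a patient votes
#' "high risk".  Pairs must be unique and the two genes of a pair
#' distinct.
#'
#' @param path TSV path.
#' @return `data.frame(gene_a, gene_b)`.
#' @export
read_gene_pairs <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) abort_fmt("%s: signature needs columns gene_a, gene_b", path)
  df <- data.frame(gene_a = df[[1L]], gene_b = df[[2L]], stringsAsFactors = FALSE)
  if (any(df$gene_a == df$gene_b))
    abort_fmt("%s: a pair lists the same gene twice", path)
  if (anyDuplicated(df)) abort_fmt("%s: duplicate gene pairs", path)
  df
}

#' Relative-expression-ordering (REO) gene-pair classifier
#'
#' Majority-vote risk classifier built on within-patient rank
#' comparisons: each pair votes "high risk" when `gene_a`'s expression
#' strictly exceeds `gene_b`'s (ties count as not-greater); patients with
#' at least `vote_threshold` of the pairs voting high are classified
#' high-risk.  Because only within-patient orderings enter, the result is
#' invariant to any monotone per-patient transformation of expression.
#' Duplicated gene rows are averaged before comparison.
#'
#' @param x [expression_matrix()] (duplicate rownames allowed here; they
#'   are collapsed by arithmetic mean first).
#' @param pairs `data.frame(gene_a, gene_b)` from [read_gene_pairs()].
#' @param vote_threshold fraction of high votes required (default 0.5).
#' @return named factor with levels `low`, `high`; the per-patient high
#'   fraction is attached as `attr(, "vote_fraction")`.
#' @export
classify_reo <- function(x, pairs, vote_threshold = 0.5) {
  x <- as.matrix(x)
  if (anyDuplicated(rownames(x))) {
    sums <- rowsum(x, group = rownames(x), reorder = TRUE)
    counts <- as.vector(table(rownames(x))[rownames(sums)])
    x <- sums / counts
  }
  present <- pairs$gene_a %in% rownames(x) & pairs$gene_b %in% rownames(x)
  if (!all(present)) {
    warn_fmt("classify_reo: dropping %d pair(s) with missing genes", sum(!present))
    pairs <- pairs[present, , drop = FALSE]
  }
  if (!nrow(pairs)) abort_fmt("classify_reo: no usable gene pairs")
  votes <- x[pairs$gene_a, , drop = FALSE] > x[pairs$gene_b, , drop = FALSE]
  frac <- colMeans(votes)
  out <- factor(ifelse(frac >= vote_threshold, "high", "low"),
                levels = c("low", "high"))
  names(out) <- colnames(x)
  attr(out, "vote_fraction") <- frac
  out
}
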