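#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test used by the differential-expression screen.  When both
#' groups have at most `exact_max` members the two-sided p-value is
#' computed by exact enumeration of all group assignments of the observed
#' values (valid with ties); otherwise the tie-corrected normal
#' approximation is used, without continuity correction.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max exact-enumeration size limit per group (default 10).
#' @return `list(statistic = rank sum of x, p, shift = median(x) -
#'   median(y), constant = TRUE if all values identical)`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1L || n2 < 1L) abort_fmt("wilcoxon_rank_sum: both groups must be non-empty")
  v <- c(x, y)
  r <- rank(v)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  shift <- median(x) - median(y)
  if (length(unique(v)) == 1L)
    return(list(statistic = W, p = 1, shift = 0, constant = TRUE))
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- combn(n, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(w_all - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p = p, shift = shift, constant = FALSE)
}

#' Wilcoxon differential-expression screen
#'
#' Tests every gene for a location difference between ACT-benefit and
#' ACT-futile patients and flags candidates at `p < alpha`.  The screen
#' uses raw p-values (genome-wide screening at a stringent alpha is the
#' convention this pipeline follows); set `fdr = TRUE` to flag candidates
#' on Benjamini-Hochberg adjusted p-values instead.
#'
#' @param x [expression_matrix()] aligned to `labels`.
#' @param labels factor/character of `benefit`/`futile` per sample.
#' @param alpha candidate threshold (default 0.001).
#' @param fdr use BH-adjusted p-values for the candidate flag.
#' @return `data.frame(gene, statistic, p, shift, direction, candidate)`,
#'   sorted by p ascending, then |shift| descending, then gene id.
#'   Constant genes get `p = 1` and `constant = TRUE`.
#' @export
wilcoxon_screen <- function(x, labels, alpha = 0.001, fdr = FALSE) {
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    abort_fmt("wilcoxon_screen: need one label per sample")
  ben <- labels == "benefit"; fut <- labels == "futile"
  if (sum(ben) < 2L || sum(fut) < 2L)
    abort_fmt("wilcoxon_screen: need at least 2 samples per class")
  res <- lapply(seq_len(nrow(x)), function(i)
    wilcoxon_rank_sum(x[i, ben], x[i, fut]))
  out <- data.frame(
    gene = rownames(x),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p = vapply(res, `[[`, numeric(1), "p"),
    shift = vapply(res, `[[`, numeric(1), "shift"),
    constant = vapply(res, `[[`, logical(1), "constant"),
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$shift > 0, "higher-in-benefit",
                          ifelse(out$shift < 0, "higher-in-futile", "none"))
  p_flag <- if (fdr) stats::p.adjust(out$p, "BH") else out$p
  out$candidate <- p_flag < alpha & !out$constant
  out <- out[order(out$p, -abs(out$shift), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
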