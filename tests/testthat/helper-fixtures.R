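# Shared fixtures and independent oracles for the test suite.

# small expression matrix with deterministic values
toy_expr <- function(values, genes = NULL, samples = NULL, scale = "log2") {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, scale)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_clinical <- function(n, act = rep(c(TRUE, FALSE), length.out = n),
                         rfs = rep(48, n), event = rep(FALSE, n),
                         stage = rep(c("II", "III"), length.out = n),
                         ids = sprintf("s%02d", seq_len(n)), ...) {
  validate_clinical(data.frame(sample_id = ids, act = as.integer(act),
                               rfs_months = rfs,
                               relapse_event = as.integer(event),
                               tnm_stage = stage, ...,
                               stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# AUC by explicit pair counting (ties count 1/2)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by enumerating value assignments; statistic
# recomputed from raw values for every assignment (independent of the
# implementation's precomputed-rank path)
oracle_wilcoxon_exact <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  mu <- n1 * (n + 1) / 2
  obs <- sum(rank(v)[seq_len(n1)])
  sets <- utils::combn(n, n1)
  stats <- apply(sets, 2L, function(idx) sum(rank(v)[idx]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# exact permutation p for the two-group log-rank statistic at tiny n
oracle_logrank_perm <- function(time, event, group) {
  obs <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ group)$chisq
  n <- length(time); n1 <- sum(group == unique(group)[1L])
  sets <- utils::combn(n, n1)
  stats <- apply(sets, 2L, function(idx) {
    g <- rep(1L, n); g[idx] <- 0L
    survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)$chisq
  })
  mean(stats >= obs - 1e-9)
}

# quantile-normalization target: mean of sorted columns, reassigned by rank
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2L, sort))
  apply(m, 2L, function(col) target[rank(col)])
}

printed_tables <- function() {
  read.csv(system.file("extdata", "printed_baseline_tables.csv",
                       package = "actbenefit"), stringsAsFactors = FALSE)
}

printed_counts <- function(tbl, covariate_name) {
  df <- printed_tables()
  df <- df[df$table == tbl & df$covariate == covariate_name, ]
  as.matrix(df[, c("treated", "untreated")])
}
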