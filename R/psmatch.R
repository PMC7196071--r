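#' Screen covariates for the propensity model
#'
#' Univariate logistic regression of ACT receipt on each candidate
#' covariate; covariates with a likelihood-ratio p-value below `alpha`
#' are retained.  Candidates missing in half or more of the patients are
#' skipped with a warning.  Quasi-separated covariates are flagged and
#' kept (their Wald statistics are unreliable, but they plainly predict
#' treatment).
#'
#' @param clinical clinical `data.frame` with an `act` column.
#' @param candidates character vector of candidate covariate columns.
#' @param alpha inclusion threshold (default 0.05).
#' @return character vector of selected covariates; the per-covariate
#'   test table is attached as `attr(, "tests")`.
#' @export
select_ps_covariates <- function(clinical, candidates, alpha = 0.05) {
  if (!length(candidates)) abort_fmt("select_ps_covariates: empty candidate list")
  missing_cols <- setdiff(candidates, colnames(clinical))
  if (length(missing_cols))
    abort_fmt("select_ps_covariates: unknown column(s): %s",
              paste(missing_cols, collapse = ", "))
  rows <- lapply(candidates, function(cv) {
    v <- clinical[[cv]]
    if (mean(is.na(v)) >= 0.5) {
      warn_fmt("select_ps_covariates: '%s' missing in >= 50%% of patients; skipped", cv)
      return(data.frame(covariate = cv, p = NA_real_, separation = FALSE,
                        selected = FALSE))
    }
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2L)
      return(data.frame(covariate = cv, p = NA_real_, separation = FALSE,
                        selected = FALSE))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(clinical$act[ok] ~ v[ok], family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    null <- glm(clinical$act[ok] ~ 1, family = binomial())
    p <- pchisq(null$deviance - fit$deviance,
                df = null$df.residual - fit$df.residual, lower.tail = FALSE)
    if (sep) warn_fmt("select_ps_covariates: quasi-separation for '%s'; kept", cv)
    data.frame(covariate = cv, p = p, separation = sep,
               selected = sep | p < alpha)
  })
  tests <- do.call(rbind, rows)
  structure(tests$covariate[tests$selected], tests = tests)
}

#' Fit the propensity score
#'
#' Multivariable logistic regression (IRLS via [glm()]) of ACT receipt on
#' the selected covariates; the propensity score is the fitted
#' probability of receiving ACT.  Patients with missing covariate values
#' are dropped with a message.
#'
#' @param clinical clinical `data.frame` with `act` and the covariates.
#' @param covariates covariate column names.
#' @return named numeric vector of propensity scores in (0, 1), one per
#'   included patient.
#' @export
fit_propensity <- function(clinical, covariates) {
  if (!length(covariates)) abort_fmt("fit_propensity: no covariates")
  df <- clinical[, c("sample_id", "act", covariates), drop = FALSE]
  cc <- complete.cases(df)
  if (!all(cc))
    message(sprintf("fit_propensity: dropping %d record(s) with missing covariates",
                    sum(!cc)))
  df <- df[cc, , drop = FALSE]
  const <- vapply(df[covariates], function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    abort_fmt("fit_propensity: constant covariate(s): %s",
              paste(covariates[const], collapse = ", "))
  fml <- as.formula(paste("act ~", paste(sprintf("`%s`", covariates),
                                         collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  if (!fit$converged) abort_fmt("fit_propensity: IRLS did not converge")
  ps <- fitted(fit)
  ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
  setNames(as.numeric(ps), df$sample_id)
}

#' 1:rho greedy nearest-neighbour propensity matching
#'
#' Matches without replacement on the logit propensity scale, processing
#' treated patients in descending propensity order (hardest to match
#' first).  The aggregate control:treated ratio `rho` is hit by a quota
#' scheme that gives the i-th *matched* treated patient
#' `round(i*rho) - round((i-1)*rho)` controls — for `rho = 1.5` this
#' alternates 2 and 1 controls, so `T` matched treated patients target
#' `round(rho * T)` controls in total.  Controls farther than the caliper
#' from their treated patient are never used; treated patients with no
#' in-caliper control remain unmatched and are reported.
#'
#' @param ps named propensity scores (all patients).
#' @param treated logical treatment indicator aligned to `ps`.
#' @param ratio target control:treated ratio (default 1.5).
#' @param caliper_sd caliper as a multiple of the SD of the logit
#'   propensity score (default 0.2); `Inf` disables the caliper.
#' @return `list(pairs = data.frame(treated_id, control_id),
#'   matched_treated, matched_controls, unmatched_treated, ratio,
#'   caliper)` of class `match_result`.  Every control is used at most
#'   once.
#' @export
match_nearest <- function(ps, treated, ratio = 1.5, caliper_sd = 0.2) {
  treated <- as.logical(treated)
  ids <- names(ps) %||% as.character(seq_along(ps))
  if (!any(treated) || all(treated))
    abort_fmt("match_nearest: both arms must be non-empty")
  lps <- qlogis(ps)
  caliper <- caliper_sd * sd(lps)
  t_ord <- order(-ps[treated], ids[treated])
  t_ids <- ids[treated][t_ord]
  t_lps <- lps[treated][t_ord]
  pool_ids <- ids[!treated]
  pool_lps <- lps[!treated]
  ord_pool <- order(pool_ids)
  pool_ids <- pool_ids[ord_pool]; pool_lps <- pool_lps[ord_pool]
  used <- logical(length(pool_ids))
  pairs <- list()
  unmatched <- character()
  m <- 0L
  for (j in seq_along(t_ids)) {
    d <- abs(pool_lps - t_lps[j])
    d[used] <- Inf
    d[d > caliper] <- Inf
    if (!any(is.finite(d))) {
      unmatched <- c(unmatched, t_ids[j])
      next
    }
    quota <- round((m + 1L) * ratio) - round(m * ratio)
    take <- order(d, pool_ids)[seq_len(min(quota, sum(is.finite(d))))]
    take <- take[is.finite(d[take])]
    used[take] <- TRUE
    m <- m + 1L
    pairs[[length(pairs) + 1L]] <-
      data.frame(treated_id = t_ids[j], control_id = pool_ids[take],
                 stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    warn_fmt("match_nearest: no treated patient found an in-caliper control")
    pairs_df <- data.frame(treated_id = character(), control_id = character(),
                           stringsAsFactors = FALSE)
  } else {
    pairs_df <- do.call(rbind, pairs)
  }
  structure(list(pairs = pairs_df,
                 matched_treated = unique(pairs_df$treated_id),
                 matched_controls = pairs_df$control_id,
                 unmatched_treated = unmatched,
                 ratio = ratio, caliper = caliper),
            class = "match_result")
}

#' Covariate balance before and after matching
#'
#' Pearson chi-square p-values of each categorical covariate against ACT
#' receipt, in the full cohort and in the matched cohort.  Categories
#' that empty out after matching are dropped from the after-matching
#' table with a warning.
#'
#' @param clinical clinical `data.frame`.
#' @param match_result a [match_nearest()] result.
#' @param covariates categorical covariate columns to assess.
#' @return `data.frame(covariate, p_before, p_after)`.
#' @export
balance_table <- function(clinical, match_result, covariates) {
  matched_ids <- c(match_result$matched_treated, match_result$matched_controls)
  sub <- clinical[clinical$sample_id %in% matched_ids, , drop = FALSE]
  one <- function(df, cv) {
    tab <- table(droplevels(factor(df[[cv]])), df$act)
    empty <- rowSums(tab) == 0
    if (any(empty)) {
      warn_fmt("balance_table: dropping empty '%s' categories: %s", cv,
               paste(rownames(tab)[empty], collapse = ", "))
      tab <- tab[!empty, , drop = FALSE]
    }
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
    chisq_independence(tab)$p
  }
  data.frame(covariate = covariates,
             p_before = vapply(covariates, function(cv) one(clinical, cv), numeric(1)),
             p_after = vapply(covariates, function(cv) one(sub, cv), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
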