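#' Kaplan-Meier estimate of relapse-free survival
#'
#' Product-limit estimator with Greenwood variance (via
#' [survival::survfit()]); `km_at()` evaluates the step function at a
#' time point, extending the curve beyond the last observation.
#'
#' @param time follow-up times (months, non-negative).
#' @param event logical/0-1 event indicator.
#' @return `km_estimate()` returns a `survfit` object.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) abort_fmt("km_estimate: empty input")
  if (any(time < 0)) abort_fmt("km_estimate: negative times")
  survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
}

#' @rdname km_estimate
#' @param fit a `survfit` object from [km_estimate()].
#' @param t time point(s) at which to evaluate survival.
#' @return `km_at()` returns the survival probability at `t`.
#' @export
km_at <- function(fit, t) {
  s <- summary(fit, times = t, extend = TRUE)
  as.numeric(s$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with a two-sided p-value.  When no
#' events are observed at all the test is undefined and the function
#' returns `p = 1` with `flagged = TRUE`.
#'
#' @param time,event follow-up and event indicator.
#' @param group two-level grouping vector.
#' @return `list(statistic, p, flagged)`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    abort_fmt("logrank_test: need exactly two non-empty groups")
  if (sum(event) == 0L)
    return(list(statistic = 0, p = 1, flagged = TRUE))
  sdf <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  stat <- sdf$chisq
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       flagged = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit with Efron tie handling (via
#' [survival::coxph()]), returning one row per model term with the hazard
#' ratio, 95% Wald confidence interval and Wald p-value.  Constant
#' covariates, non-convergence within `max_iter` iterations, and monotone
#' likelihoods (perfect separation, recognisable by exploding
#' coefficients) are errors rather than silent output.
#'
#' @param time,event follow-up and event indicator.
#' @param covariates `data.frame` of covariates (factors allowed).
#' @param max_iter Newton-Raphson iteration cap.
#' @return `data.frame(term, hr, ci_low, ci_high, p, n, events)`.
#' @export
cox_fit <- function(time, event, covariates, max_iter = 100) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L,
                  logical(1))
  if (any(const))
    abort_fmt("cox_fit: constant covariate(s): %s",
              paste(names(covariates)[const], collapse = ", "))
  cc <- complete.cases(covariates)
  if (!all(cc)) {
    message(sprintf("cox_fit: dropping %d record(s) with missing covariates",
                    sum(!cc)))
    covariates <- covariates[cc, , drop = FALSE]
    time <- time[cc]; event <- event[cc]
  }
  if (sum(event) < ncol(covariates))
    abort_fmt("cox_fit: fewer events (%d) than model terms", sum(event))
  df <- data.frame(.time = time, .event = as.integer(event), covariates,
                   check.names = TRUE)
  terms <- setdiff(colnames(df), c(".time", ".event"))
  fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(iter.max = max_iter)),
    warning = function(w) {
      if (grepl("did not converge|infinite|Loglik converged", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (anyNA(beta)) {
    # aliased (collinear) terms, as lm/coxph report them: drop with a warning
    warn_fmt("cox_fit: dropping aliased term(s): %s",
             paste(names(beta)[is.na(beta)], collapse = ", "))
    keep <- !is.na(beta)
    beta <- beta[keep]
    fit$var <- fit$var[keep, keep, drop = FALSE]
  }
  se <- sqrt(diag(fit$var))
  if (fit$iter >= max_iter)
    abort_fmt("cox_fit: Newton-Raphson did not converge in %d iterations", max_iter)
  if (any(abs(beta) > 15))
    abort_fmt(paste("cox_fit: monotone likelihood (perfect separation) for:",
                    paste(names(beta)[abs(beta) > 15], collapse = ", "),
                    "- consider pooling categories or dropping the covariate"))
  data.frame(term = names(beta),
             hr = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p = 2 * pnorm(-abs(beta / se)),
             n = fit$n, events = fit$nevent,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Treatment-by-group interaction p-value
#'
#' Wald p-value for the treatment x group product term in a Cox model
#' containing treatment, group, their product, and any adjusters — the
#' formal test that the grouping modifies the treatment effect on
#' relapse hazard.
#'
#' @param time,event follow-up and event indicator.
#' @param treatment logical/0-1 treatment indicator.
#' @param group two-level grouping (e.g. predicted benefit/futile).
#' @param adjusters optional `data.frame` of adjustment covariates.
#' @return the interaction p-value (numeric scalar); the full fit is
#'   attached as `attr(, "fit")`.
#' @export
interaction_pvalue <- function(time, event, treatment, group, adjusters = NULL) {
  treatment <- as.numeric(as.logical(treatment))
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    abort_fmt("interaction_pvalue: group is constant")
  grp <- as.numeric(group == levels(group)[2L])
  covs <- data.frame(treatment = treatment, group = grp,
                     treat_x_group = treatment * grp)
  if (!is.null(adjusters)) covs <- cbind(covs, as.data.frame(adjusters))
  fit <- cox_fit(time, event, covs)
  p <- fit$p[fit$term == "treat_x_group"]
  if (!length(p))
    abort_fmt("interaction_pvalue: the treatment x group term is not estimable")
  attr(p, "fit") <- fit
  p
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c contingency table with
#' `(r-1)(c-1)` degrees of freedom.  No continuity correction is applied
#' (matching how published clinical baseline tables are tested).
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @return `list(statistic, df, p)`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    abort_fmt("chisq_independence: need at least a 2x2 table")
  if (any(table < 0)) abort_fmt("chisq_independence: negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort_fmt("chisq_independence: zero marginal row/column")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
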