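#' Assign ACT-benefit / ACT-futile training labels
#'
#' The supervised outcome of the pipeline: a patient is labelled by
#' whether their treatment and three-year relapse status are concordant
#' with chemotherapy having helped.
#'
#' * **benefit** — relapse-free past the threshold *with* ACT, or relapsed
#'   before the threshold *without* ACT (treatment plausibly would have
#'   helped);
#' * **futile** — relapse-free past the threshold *without* ACT, or
#'   relapsed before the threshold *despite* ACT;
#' * **unlabelable** — censored before the threshold without relapse (the
#'   three-year status is unknown), or follow-up equal to the threshold
#'   exactly (the definition uses strict inequalities).
#'
#' Vectorized over patients.
#'
#' @param rfs_months relapse-free survival time in months.
#' @param relapse_event logical, relapse observed.
#' @param act logical, received 5-Fu-based adjuvant chemotherapy.
#' @param threshold_months landmark in months (default 36).
#' @return factor with levels `benefit`, `futile`, `unlabelable`.
#' @export
assign_benefit_label <- function(rfs_months, relapse_event, act,
                                 threshold_months = 36) {
  stopifnot(length(rfs_months) == length(relapse_event),
            length(rfs_months) == length(act))
  out <- rep("unlabelable", length(rfs_months))
  long <- rfs_months > threshold_months
  early_relapse <- rfs_months < threshold_months & relapse_event
  out[(long & act) | (early_relapse & !act)] <- "benefit"
  out[(long & !act) | (early_relapse & act)] <- "futile"
  factor(out, levels = c("benefit", "futile", "unlabelable"))
}

#' Label a cohort and exclude unlabelable patients
#'
#' Applies [assign_benefit_label()] to every patient and removes those who
#' cannot be labelled, returning the labelled sub-cohort (expression
#' columns re-aligned) plus an exclusion report.
#'
#' The default policy removes patients censored before the landmark
#' without relapse — the only patients whose three-year relapse status is
#' genuinely unknown.  `exclusion_policy = "early_relapse"` instead
#' removes patients who *relapsed* before the landmark (a stricter reading
#' of removing early events "to control bias"); under that policy the
#' remaining labels reduce to ACT concordance with three-year
#' relapse-free status.
#'
#' @param cohort `list(expression=, clinical=)` as from [align_cohort()].
#' @param threshold_months landmark in months.
#' @param exclusion_policy `"early_censored"` (default) or
#'   `"early_relapse"`.
#' @return `list(expression=, clinical=, labels=, exclusions=)` where
#'   `labels` is a 2-level factor aligned to the retained samples and
#'   `exclusions` counts removed patients by reason.
#' @export
label_cohort <- function(cohort, threshold_months = 36,
                         exclusion_policy = c("early_censored", "early_relapse")) {
  exclusion_policy <- match.arg(exclusion_policy)
  cl <- cohort$clinical
  labels <- assign_benefit_label(cl$rfs_months, cl$relapse_event, cl$act,
                                 threshold_months)
  reason <- rep(NA_character_, nrow(cl))
  reason[cl$rfs_months == threshold_months] <- "follow-up equals threshold"
  reason[cl$rfs_months < threshold_months & !cl$relapse_event] <-
    "censored before threshold"
  if (exclusion_policy == "early_relapse") {
    early <- cl$rfs_months < threshold_months & cl$relapse_event
    labels[early] <- "unlabelable"
    reason[early] <- "relapsed before threshold"
  }
  keep <- labels != "unlabelable"
  exclusions <- table(reason[!keep], dnn = NULL)
  labels <- factor(as.character(labels[keep]), levels = c("benefit", "futile"))
  if (min(table(labels)) < 2L)
    abort_fmt("label_cohort: need at least 2 patients in each of benefit/futile (got %s)",
              paste(sprintf("%s=%d", names(table(labels)), table(labels)),
                    collapse = ", "))
  sc <- expr_scale(cohort$expression)
  list(expression = set_scale(cohort$expression[, keep, drop = FALSE], sc),
       clinical = cl[keep, , drop = FALSE],
       labels = setNames(labels, cl$sample_id[keep]),
       exclusions = exclusions)
}
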