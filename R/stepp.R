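#' Sliding subpopulation windows over predictive scores
#'
#' Builds the overlapping, rank-contiguous subpopulations of a
#' sliding-window STEPP: patients are sorted by score (ties broken by
#' sample id for reproducibility) and covered by windows of `n2` patients
#' advancing by `n2 - n1`, so consecutive windows share `n1` patients.
#' The last window is right-aligned to include the top-ranked patient.
#'
#' @param scores named numeric vector of predictive scores (names =
#'   sample ids).
#' @param n2 window size (number of patients per subpopulation).
#' @param n1 overlap between consecutive windows (`n1 < n2`).
#' @return list of character vectors of member ids, ordered by window
#'   median score; attribute `"ranks"` holds the rank ranges.
#' @export
build_windows <- function(scores, n2, n1) {
  n <- length(scores)
  ids <- names(scores) %||% as.character(seq_len(n))
  if (n2 > n) {
    warn_fmt("build_windows: n2 = %d exceeds n = %d; using a single window",
             n2, n)
    n2 <- n; n1 <- 0L
  }
  if (n1 >= n2) abort_fmt("build_windows: need overlap n1 < window size n2")
  ord <- order(scores, ids)
  step <- n2 - n1
  starts <- seq(1L, n - n2 + 1L, by = step)
  if (starts[length(starts)] + n2 - 1L < n) starts <- c(starts, n - n2 + 1L)
  windows <- lapply(starts, function(s) ids[ord[s:(s + n2 - 1L)]])
  attr(windows, "ranks") <- cbind(start = starts, end = starts + n2 - 1L)
  windows
}

#' Subpopulation treatment effect pattern plot (STEPP) profile
#'
#' For each score-ordered window, estimates the Kaplan-Meier relapse-free
#' survival at `horizon` months separately in the treated (ACT) and
#' untreated arms, their difference (ACT minus no ACT), and the window's
#' Cox hazard ratio for ACT with a 95% Wald interval.  A rising RFS
#' difference / falling hazard ratio along the score axis is the
#' signature of a true treatment-modifying score.
#'
#' @param scores named predictive scores.
#' @param act logical treatment indicator, aligned to `scores`.
#' @param time,event follow-up months and relapse indicator, aligned.
#' @param n2 window size; default `max(40, round(n/4))`.
#' @param n1 overlap; default `floor(n2/2)`.
#' @param horizon landmark for the RFS rate (months, default 36).
#' @return `data.frame` of class `stepp_profile`: one row per window with
#'   `median_score`, `n`, `n_act`, `rfs36_act`, `rfs36_noact`, `rfs_diff`,
#'   `hr`, `ci_low`, `ci_high`, `flagged` (TRUE when an arm is empty or
#'   the hazard ratio could not be estimated).  Window membership is kept
#'   in `attr(, "windows")`.
#' @export
stepp_profile <- function(scores, act, time, event,
                          n2 = max(40L, round(length(scores) / 4)),
                          n1 = floor(n2 / 2), horizon = 36) {
  n <- length(scores)
  stopifnot(length(act) == n, length(time) == n, length(event) == n)
  ids <- names(scores) %||% as.character(seq_len(n))
  names(scores) <- ids
  act <- as.logical(act)
  windows <- build_windows(scores, n2, n1)
  rows <- lapply(windows, function(w) {
    i <- match(w, ids)
    out <- data.frame(median_score = median(scores[i]), n = length(i),
                      n_act = sum(act[i]), rfs36_act = NA_real_,
                      rfs36_noact = NA_real_, rfs_diff = NA_real_,
                      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      flagged = FALSE)
    if (sum(act[i]) == 0L || sum(!act[i]) == 0L) {
      out$flagged <- TRUE
      return(out)
    }
    out$rfs36_act <- km_at(km_estimate(time[i][act[i]], event[i][act[i]]), horizon)
    out$rfs36_noact <- km_at(km_estimate(time[i][!act[i]], event[i][!act[i]]), horizon)
    out$rfs_diff <- out$rfs36_act - out$rfs36_noact
    cx <- tryCatch(
      cox_fit(time[i], event[i], data.frame(act = act[i])),
      error = function(e) NULL)
    if (is.null(cx)) {
      out$flagged <- TRUE
    } else {
      out$hr <- cx$hr[1L]; out$ci_low <- cx$ci_low[1L]; out$ci_high <- cx$ci_high[1L]
    }
    out
  })
  profile <- do.call(rbind, rows)
  profile <- profile[order(profile$median_score), , drop = FALSE]
  rownames(profile) <- NULL
  attr(profile, "windows") <- windows
  attr(profile, "parameters") <- c(n2 = n2, n1 = n1, horizon = horizon)
  class(profile) <- c("stepp_profile", "data.frame")
  profile
}

#' Choose a predictive-score cutoff from a STEPP profile
#'
#' Formalizes the by-inspection rule "treat patients above the score where
#' ACT starts to help": the cutoff is the smallest window-median score `m`
#' such that *every* window with median score `>= m` has an ACT hazard
#' ratio below 1.  Windows whose hazard ratio could not be estimated
#' count as failing the condition.  Returns `NA` (with a warning) when no
#' window qualifies.
#'
#' @param profile a [stepp_profile()].
#' @return the cutoff score, or `NA_real_` if undefined.
#' @export
select_cutoff <- function(profile) {
  if (!nrow(profile)) abort_fmt("select_cutoff: empty profile")
  ok <- !is.na(profile$hr) & profile$hr < 1
  suffix_ok <- rev(cumprod(rev(ok))) == 1
  if (!any(suffix_ok)) {
    warn_fmt("select_cutoff: no window has hazard ratio < 1 for all higher scores")
    return(NA_real_)
  }
  profile$median_score[which(suffix_ok)[1L]]
}

#' Stratify patients by the score cutoff
#'
#' Scores strictly greater than the cutoff are predicted ACT-benefit;
#' everything else (including scores equal to the cutoff) is predicted
#' ACT-futile.
#'
#' @param scores named numeric scores.
#' @param cutoff score cutoff (must be defined).
#' @return named factor with levels `predicted-futile`, `predicted-benefit`.
#' @export
stratify_patients <- function(scores, cutoff) {
  if (is.na(cutoff)) abort_fmt("stratify_patients: cutoff is undefined")
  out <- factor(ifelse(scores > cutoff, "predicted-benefit", "predicted-futile"),
                levels = c("predicted-futile", "predicted-benefit"))
  names(out) <- names(scores)
  out
}
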