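#' Run the full benefit-modelling pipeline
#'
#' Orchestrates labelling, the Wilcoxon screen, hyperparameter tuning, GA
#' gene selection, final model training, STEPP cutoff determination,
#' stratification, and survival validation on one cohort, writing every
#' artifact to `out_dir`.  All randomness derives deterministically from
#' `config$seed`, so a rerun with the same config and inputs produces
#' byte-identical artifacts.
#'
#' `config` is a list with (at least) `seed`; either `simulate` (a
#' [synthetic_config()]) or `expression_path` + `clinical_path`; and
#' optional overrides `threshold_months` (36), `screen_alpha` (0.001),
#' `ga` (a [ga_config()]), `stepp_n2`/`stepp_n1`, `cutoff` (to impose a
#' cutoff instead of the STEPP criterion), and `validate_adjusters`
#' (clinical columns for the multivariable interaction model).
#'
#' @param config pipeline configuration list.
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, the list of artifact paths; a `manifest.json`
#'   records the seed, configuration hash and per-artifact md5 sums.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed))
    abort_fmt("run_pipeline: config must set a seed (reproducibility is enforced)")
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(out_dir, name)
  paths <- character()

  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  cohort <- step("input", {
    if (!is.null(config$simulate)) {
      sim <- generate_cohort(config$simulate, seed = seed)
      list(expression = sim$expression, clinical = sim$clinical)
    } else if (!is.null(config$expression_path)) {
      align_cohort(read_expression(config$expression_path,
                                   scale = config$expression_scale %||% "log2"),
                   read_clinical(config$clinical_path))
    } else {
      abort_fmt("config needs either 'simulate' or 'expression_path'/'clinical_path'")
    }
  })

  lab <- step("label", label_cohort(cohort,
                                    threshold_months = config$threshold_months %||% 36))
  labels_df <- data.frame(sample_id = names(lab$labels),
                          label = as.character(lab$labels))
  write.csv(labels_df, art("labels.csv"), row.names = FALSE)

  screen <- step("screen",
                 wilcoxon_screen(lab$expression, lab$labels,
                                 alpha = config$screen_alpha %||% 0.001))
  write.csv(screen, art("deg_table.csv"), row.names = FALSE)
  candidates <- screen$gene[screen$candidate]
  if (!length(candidates))
    abort_fmt("pipeline stage 'screen' failed: no candidate genes at alpha = %g%s",
              config$screen_alpha %||% 0.001,
              "; consider a larger alpha for small gene panels")

  ga <- config$ga %||% ga_config()
  res <- step("train", {
    cand_feats <- build_feature_matrix(lab$expression, lab$clinical,
                                       candidates, include_stage = FALSE)
    stage_feat <- cbind(tnm_stage_iii =
                          as.numeric(lab$clinical$tnm_stage == "III"))
    y <- lab$labels == "benefit"
    tuned <- tune_hyperparams(cbind(cand_feats, stage_feat), y,
                              folds = ga$cv_folds, seed = seed + 1L)
    ga$seed <- seed + 2L
    sel <- ga_select(cand_feats, y, tuned$cost, tuned$gamma, config = ga,
                     forced_features = stage_feat)
    model <- train_final_model(lab$expression, lab$clinical, lab$labels,
                               candidates[sel$best], tuned$cost, tuned$gamma,
                               seed = seed + 3L, fitness = sel$best_fitness)
    list(model = model, sel = sel)
  })
  write.csv(res$sel$trace, art("ga_trace.csv"), row.names = FALSE)

  scores <- step("score", predict_scores(res$model, cohort$expression,
                                         cohort$clinical))

  profile <- step("stepp", {
    args <- list(scores = scores, act = cohort$clinical$act,
                 time = cohort$clinical$rfs_months,
                 event = cohort$clinical$relapse_event)
    if (!is.null(config$stepp_n2)) args$n2 <- config$stepp_n2
    if (!is.null(config$stepp_n1)) args$n1 <- config$stepp_n1
    do.call(stepp_profile, args)
  })
  write.csv(as.data.frame(profile), art("stepp_profile.csv"), row.names = FALSE)

  cutoff <- config$cutoff %||% suppressWarnings(select_cutoff(profile))
  if (is.na(cutoff))
    abort_fmt("pipeline stage 'stepp' failed: no cutoff satisfies the criterion%s",
              "; impose one via config$cutoff")
  res$model$cutoff <- cutoff
  write_model(res$model, art("model.json"))

  groups <- stratify_patients(scores, cutoff)
  write.csv(data.frame(sample_id = names(scores), score = unname(scores),
                       group = as.character(groups)),
            art("stratification.csv"), row.names = FALSE)

  validation <- step("validate", {
    cl <- cohort$clinical
    per_group <- lapply(levels(groups), function(gl) {
      i <- groups == gl
      if (sum(cl$act[i]) == 0 || sum(!cl$act[i]) == 0)
        return(data.frame(group = gl, hr = NA, ci_low = NA, ci_high = NA,
                          p_logrank = NA, n = sum(i), events = sum(cl$relapse_event[i])))
      lr <- logrank_test(cl$rfs_months[i], cl$relapse_event[i], cl$act[i])
      cx <- cox_fit(cl$rfs_months[i], cl$relapse_event[i],
                    data.frame(act = cl$act[i]))
      data.frame(group = gl, hr = cx$hr, ci_low = cx$ci_low,
                 ci_high = cx$ci_high, p_logrank = lr$p,
                 n = sum(i), events = sum(cl$relapse_event[i]))
    })
    adj <- NULL
    adj_cols <- config$validate_adjusters %||%
      intersect("tnm_stage", colnames(cl))
    if (length(adj_cols)) adj <- cl[, adj_cols, drop = FALSE]
    p_int <- as.numeric(interaction_pvalue(cl$rfs_months, cl$relapse_event,
                                           cl$act, groups, adjusters = adj))
    out <- do.call(rbind, per_group)
    out$p_interaction <- p_int
    out
  })
  write.csv(validation, art("validation.csv"), row.names = FALSE)

  artifacts <- c("labels.csv", "deg_table.csv", "ga_trace.csv", "model.json",
                 "stepp_profile.csv", "stratification.csv", "validation.csv")
  manifest <- list(
    package = "actbenefit",
    version = as.character(utils::packageVersion("actbenefit")),
    seed = seed,
    config_hash = content_hash(config),
    artifacts = lapply(setNames(nm = artifacts), function(a)
      unname(tools::md5sum(art(a)))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file.path(out_dir, c(artifacts, "manifest.json")))
}
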