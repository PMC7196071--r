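#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with tied scores contributing 1/2 per
#' pair.  Computed from average ranks, which is algebraically identical
#' to pair counting.
#'
#' @param scores numeric predictive scores.
#' @param labels logical (or 0/1): `TRUE` = positive class.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    abort_fmt("compute_auc: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: a pure function of (seed, ids, labels).
# Samples are taken in sorted-id order within each class, permuted under
# the seed, and dealt round-robin, so every fold contains both classes.
make_cv_folds <- function(labels, ids, folds, seed) {
  labels <- as.character(labels)
  if (min(table(labels)) < folds)
    abort_fmt("cannot stratify %d folds: smallest class has %d member(s)",
              folds, min(table(labels)))
  fold <- integer(length(ids))
  local_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)[order(ids[labels == cls])]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# Minimal RBF-SVM wrapper around the libsvm binding.  Works on an already
# standardized feature matrix; the decision function is re-expressed with
# our own kernel arithmetic so that serialized models reproduce scores
# exactly.  `sign` orients decision values so larger = more "positive"
# (labels TRUE), fixed from the training data.
fit_rbf_svm <- function(x, y, cost, gamma) {
  fit <- e1071::svm(x, factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos")),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  m <- list(sv = unname(as.matrix(fit$SV)), coefs = as.vector(fit$coefs),
            rho = fit$rho, gamma = gamma, sign = 1)
  dec <- rbf_decision(m, x)
  if (compute_auc(dec, y) < 0.5) m$sign <- -1
  m
}

rbf_decision <- function(m, x) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(m$sv^2), rowSums(x^2), "+") - 2 * m$sv %*% t(x)
  d2[d2 < 0] <- 0
  m$sign * (as.vector(crossprod(exp(-m$gamma * d2), m$coefs)) - m$rho)
}

#' Cross-validated AUC fitness of a feature subset
#'
#' The genetic algorithm's fitness function: mean out-of-fold AUC of an
#' RBF-SVM over stratified k-folds.  Fold assignment is a pure function
#' of `(seed, sample ids, labels)`, so fitness values are comparable
#' across chromosomes and fully reproducible.
#'
#' @param features numeric matrix, samples x features (already
#'   standardized; see [build_feature_matrix()]).
#' @param labels logical, `TRUE` = benefit.
#' @param cost,gamma RBF-SVM hyperparameters.
#' @param folds number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return mean out-of-fold AUC.
#' @export
cv_fitness <- function(features, labels, cost, gamma, folds = 5, seed = 1) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) abort_fmt("cv_fitness: chromosome selects no features")
  labels <- as.logical(labels)
  fold <- make_cv_folds(labels, rownames(features) %||% seq_len(nrow(features)),
                        folds, seed)
  aucs <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    m <- fit_rbf_svm(features[tr, , drop = FALSE], labels[tr], cost, gamma)
    compute_auc(rbf_decision(m, features[!tr, , drop = FALSE]), labels[!tr])
  }, numeric(1))
  mean(aucs)
}

#' Default (cost, gamma) grid
#'
#' Powers-of-two grid conventional for RBF-SVM tuning.
#' @return `data.frame(cost, gamma)`.
#' @export
default_svm_grid <- function() {
  expand.grid(cost = 2^seq(-2, 4, by = 2), gamma = 2^seq(-6, 0, by = 2),
              KEEP.OUT.ATTRS = FALSE)
}

#' Grid-search RBF-SVM hyperparameters by cross-validated AUC
#'
#' @inheritParams cv_fitness
#' @param grid `data.frame(cost, gamma)`; ties in CV AUC are broken
#'   toward smaller cost, then smaller gamma.
#' @return `list(cost, gamma, cv_auc, grid)` with per-point AUCs.
#' @export
tune_hyperparams <- function(features, labels, grid = default_svm_grid(),
                             folds = 5, seed = 1) {
  if (!nrow(grid)) abort_fmt("tune_hyperparams: empty grid")
  grid$cv_auc <- vapply(seq_len(nrow(grid)), function(i)
    cv_fitness(features, labels, grid$cost[i], grid$gamma[i], folds, seed),
    numeric(1))
  ord <- order(-grid$cv_auc, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  list(cost = best$cost, gamma = best$gamma, cv_auc = best$cv_auc, grid = grid)
}

#' Genetic-algorithm settings
#'
#' Population 20, crossover probability 0.10, mutation probability 0.30
#' and 5-fold CV are the pipeline's standard settings; the full-scale
#' search uses 10000 iterations, while the default here (200) is sized
#' for desk-scale cohorts with tens of candidate genes.
#'
#' @param population_size individuals per generation (>= 2).
#' @param p_crossover probability a parent pair undergoes single-point
#'   crossover.
#' @param p_mutation per-offspring probability of flipping one random bit.
#' @param iterations number of generations (0 = score the initial
#'   population only).
#' @param cv_folds folds for the AUC fitness.
#' @param elitism number of best individuals carried over unchanged.
#' @param seed master seed for the whole GA run.
#' @return validated `ga_config` list.
#' @export
ga_config <- function(population_size = 20, p_crossover = 0.10,
                      p_mutation = 0.30, iterations = 200, cv_folds = 5,
                      elitism = 1, seed = 1) {
  stopifnot(population_size >= 2, iterations >= 0,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            cv_folds >= 2, elitism >= 0)
  structure(list(population_size = as.integer(population_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 iterations = as.integer(iterations),
                 cv_folds = as.integer(cv_folds),
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm gene-subset selection
#'
#' Wrapper feature selection: each chromosome is a bit vector over the
#' candidate genes (any forced features, e.g. TNM stage, are appended to
#' every evaluation), scored by [cv_fitness()].  Per generation:
#' fitness-proportional (roulette) parent selection; single-point
#' crossover of consecutive parent pairs with probability `p_crossover`;
#' per-offspring mutation flipping one uniformly chosen bit with
#' probability `p_mutation`; elitism re-inserts the best-ever individual,
#' so best-so-far fitness is non-decreasing.  Initial bits are on with
#' probability `4/n_candidates` (at least one bit per chromosome).
#' Fitness values are cached per chromosome, and the whole run is a
#' deterministic function of `(config$seed, data)`.
#'
#' @param gene_features samples x candidate-genes matrix (standardized).
#' @param labels logical, `TRUE` = benefit.
#' @param cost,gamma SVM hyperparameters used for every chromosome.
#' @param config a [ga_config()].
#' @param forced_features optional samples x k matrix of features included
#'   in every chromosome (e.g. the TNM-stage indicator).
#' @return `list(best = logical chromosome, best_fitness, trace =
#'   data.frame(generation, best_fitness, mean_fitness), best_per_gen =
#'   generations x genes logical matrix)`.
#' @export
ga_select <- function(gene_features, labels, cost, gamma,
                      config = ga_config(), forced_features = NULL) {
  gene_features <- as.matrix(gene_features)
  L <- ncol(gene_features)
  if (L < 1L) abort_fmt("ga_select: no candidate genes")
  pop_n <- config$population_size

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    val <- cache[[key]]
    if (!is.null(val)) return(val)
    feats <- gene_features[, bits, drop = FALSE]
    if (!is.null(forced_features)) feats <- cbind(feats, forced_features)
    val <- cv_fitness(feats, labels, cost, gamma,
                      folds = config$cv_folds, seed = config$seed)
    cache[[key]] <- val
    val
  }
  repair <- function(bits) {
    if (!any(bits)) bits[sample.int(L, 1L)] <- TRUE
    bits
  }

  local_seed(config$seed, {
    pop <- lapply(seq_len(pop_n), function(i)
      repair(runif(L) < min(1, 4 / L)))
    fit <- vapply(pop, fitness_of, numeric(1))
    best_i <- which.max(fit)
    best <- pop[[best_i]]; best_fit <- fit[best_i]
    n_trace <- config$iterations + 1L
    trace <- data.frame(generation = seq_len(n_trace) - 1L,
                        best_fitness = NA_real_, mean_fitness = NA_real_)
    best_per_gen <- matrix(FALSE, n_trace, L,
                           dimnames = list(NULL, colnames(gene_features)))
    trace$best_fitness[1L] <- best_fit
    trace$mean_fitness[1L] <- mean(fit)
    best_per_gen[1L, ] <- best

    for (gen in seq_len(config$iterations)) {
      # roulette selection
      w <- fit - min(fit) + 1e-6
      parents <- pop[sample.int(pop_n, pop_n, replace = TRUE, prob = w)]
      # single-point crossover on consecutive pairs
      for (i in seq(1L, pop_n - 1L, by = 2L)) {
        if (L > 1L && runif(1) < config$p_crossover) {
          pt <- sample.int(L - 1L, 1L)
          tail_a <- parents[[i]][(pt + 1L):L]
          parents[[i]][(pt + 1L):L] <- parents[[i + 1L]][(pt + 1L):L]
          parents[[i + 1L]][(pt + 1L):L] <- tail_a
        }
      }
      # mutation: one uniformly chosen bit per selected offspring
      pop <- lapply(parents, function(bits) {
        if (runif(1) < config$p_mutation) {
          j <- sample.int(L, 1L)
          bits[j] <- !bits[j]
        }
        repair(bits)
      })
      if (config$elitism > 0L) pop[[1L]] <- best
      fit <- vapply(pop, fitness_of, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best <- pop[[which.max(fit)]]
      }
      trace$best_fitness[gen + 1L] <- best_fit
      trace$mean_fitness[gen + 1L] <- mean(fit)
      best_per_gen[gen + 1L, ] <- best
    }
    list(best = setNames(best, colnames(gene_features)),
         best_fitness = best_fit, trace = trace, best_per_gen = best_per_gen)
  })
}

#' Build the SVM feature matrix for a gene set
#'
#' Expression features are standardized to z-scores; the means/SDs are
#' estimated from the supplied (training) data unless given, so test
#' cohorts are projected onto the training scale.  TNM stage enters as a
#' binary indicator (stage III = 1).
#'
#' @param expression [expression_matrix()].
#' @param clinical clinical data frame aligned to the expression columns.
#' @param genes gene ids to include (rows of `expression`).
#' @param include_stage append the stage indicator.
#' @param means,sds optional named training means/SDs for the genes.
#' @return samples x features matrix with attributes `means` and `sds`.
#' @export
build_feature_matrix <- function(expression, clinical, genes,
                                 include_stage = TRUE,
                                 means = NULL, sds = NULL) {
  missing_genes <- setdiff(genes, rownames(expression))
  if (length(missing_genes))
    abort_fmt("genes absent from expression matrix: %s",
              paste(missing_genes, collapse = ", "))
  x <- t(expression[genes, , drop = FALSE])
  if (is.null(means)) means <- colMeans(x)
  if (is.null(sds)) {
    sds <- apply(x, 2L, sd)
    sds[sds == 0] <- 1
  }
  x <- sweep(sweep(x, 2L, means[genes]), 2L, sds[genes], "/")
  if (include_stage) {
    if (is.null(clinical$tnm_stage)) abort_fmt("clinical tnm_stage required")
    x <- cbind(x, tnm_stage_iii = as.numeric(clinical$tnm_stage == "III"))
  }
  rownames(x) <- clinical$sample_id
  attr(x, "means") <- means
  attr(x, "sds") <- sds
  x
}

#' Train the final benefit model
#'
#' Fits the RBF-SVM on all labelled training patients using the selected
#' genes (plus the TNM-stage indicator), and calibrates decision values
#' to benefit probabilities with a Platt sigmoid fitted to out-of-fold
#' decision values from an internal stratified CV.
#'
#' @param expression training [expression_matrix()].
#' @param clinical aligned clinical data frame.
#' @param labels benefit/futile factor aligned to samples.
#' @param genes selected gene ids.
#' @param cost,gamma tuned SVM hyperparameters.
#' @param include_stage include the TNM-stage indicator feature.
#' @param seed seed for the calibration folds.
#' @param fitness optional CV fitness to record in the training summary.
#' @param calib_folds folds for the calibration CV.
#' @return a `benefit_model` (see [write_model()] for the stored fields).
#' @export
train_final_model <- function(expression, clinical, labels, genes,
                              cost, gamma, include_stage = TRUE, seed = 1,
                              fitness = NA_real_, calib_folds = 5) {
  stopifnot(cost > 0, gamma > 0, length(genes) >= 1)
  y <- as.character(labels) == "benefit"
  feats <- build_feature_matrix(expression, clinical, genes, include_stage)
  m <- fit_rbf_svm(feats, y, cost, gamma)

  # out-of-fold decision values for Platt calibration
  fold <- make_cv_folds(y, clinical$sample_id, calib_folds, seed)
  dec_cv <- numeric(length(y))
  for (k in seq_len(calib_folds)) {
    tr <- fold != k
    mk <- fit_rbf_svm(feats[tr, , drop = FALSE], y[tr], cost, gamma)
    dec_cv[!tr] <- rbf_decision(mk, feats[!tr, , drop = FALSE])
  }
  calibration <- fit_platt(dec_cv, y)

  structure(list(
    selected_genes = genes,
    include_stage = include_stage,
    cost = cost, gamma = gamma,
    feature_names = colnames(feats),
    feature_means = attr(feats, "means"),
    feature_sds = attr(feats, "sds"),
    sv = m$sv, sv_coefs = m$coefs, rho = m$rho, sign = m$sign,
    calibration = calibration,
    cutoff = NA_real_,
    training = list(fitness = fitness, seed = seed,
                    n_train = length(y),
                    config_hash = content_hash(list(genes, include_stage,
                                                    cost, gamma, seed)))),
    class = "benefit_model")
}

# Platt (1999) sigmoid calibration with the standard smoothed targets,
# fitted by weighted logistic IRLS via glm.  Degenerate decision values
# (no spread) cannot be calibrated.
fit_platt <- function(dec, y) {
  if (sd(dec) < 1e-12)
    abort_fmt("probability calibration failed: degenerate decision values")
  n_pos <- sum(y); n_neg <- sum(!y)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  target <- ifelse(y, t_pos, t_neg)
  df <- data.frame(dec = c(dec, dec), resp = c(rep(1, length(y)), rep(0, length(y))),
                   w = c(target, 1 - target))
  fit <- suppressWarnings(glm(resp ~ dec, family = binomial(), data = df,
                              weights = df$w))
  list(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L]))
}

#' Predictive benefit scores
#'
#' Projects patients onto the model's training feature scale and returns
#' the calibrated probability of the ACT-benefit class.
#'
#' @param model a `benefit_model`.
#' @param expression [expression_matrix()] containing all model genes.
#' @param clinical aligned clinical data frame (needed for the stage
#'   indicator when the model includes it).
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, expression, clinical) {
  feats <- build_feature_matrix(expression, clinical, model$selected_genes,
                                model$include_stage,
                                means = model$feature_means,
                                sds = model$feature_sds)
  m <- list(sv = model$sv, coefs = model$sv_coefs, rho = model$rho,
            gamma = model$gamma, sign = model$sign)
  dec <- rbf_decision(m, feats)
  p <- plogis(model$calibration$intercept + model$calibration$slope * dec)
  setNames(p, clinical$sample_id)
}
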