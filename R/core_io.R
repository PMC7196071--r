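#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, unique row/column names, all values finite, and a
#' `"scale"` attribute recording whether values are raw intensities/FPKM
#' (`"raw"`) or log2-transformed (`"log2"`).
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param scale `"raw"` or `"log2"`.
#' @return the validated matrix with its `"scale"` attribute set.
#' @export
expression_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort_fmt("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_fmt("expression matrix needs gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    abort_fmt("duplicate gene ids: %s (collapse probes explicitly first)",
              paste(head(dup_g, 5), collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    abort_fmt("duplicate sample ids: %s", paste(head(dup_s, 5), collapse = ", "))
  if (!all(is.finite(values)))
    abort_fmt("expression matrix contains non-finite values")
  attr(values, "scale") <- scale
  values
}

#' @rdname expression_matrix
#' @param x an expression matrix.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "raw"

# reapply a scale tag after matrix operations that drop attributes
set_scale <- function(x, scale) {
  attr(x, "scale") <- scale
  x
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (microarray convention).  Every cell must parse as a finite number;
#' duplicated gene ids are an error because probe collapsing is an
#' explicit, separate preprocessing step ([collapse_probes()]).
#'
#' @param path file path.
#' @param samples_in_rows set `TRUE` if the file is transposed
#'   (samples in rows, genes in columns).
#' @param scale value scale of the stored data, `"raw"` or `"log2"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, samples_in_rows = FALSE,
                            scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) abort_fmt("%s: expected an id column plus data columns", path)
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)), USE.NAMES = FALSE))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(row_ids, col_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_fmt("%s: non-numeric value '%s' at row '%s', column '%s'",
              path, raw[bad[1L, 1L], bad[1L, 2L] + 1L],
              row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]])
  }
  if (samples_in_rows) vals <- t(vals)
  expression_matrix(vals, scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; round-trips ids and values.
#'
#' @param x expression matrix.
#' @param path output path.
#' @param id_column header name for the gene-id column.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_mandatory <- c("sample_id", "act", "rfs_months", "relapse_event",
                        "tnm_stage")
clinical_optional <- c("age_years", "sex", "t_stage", "n_stage", "site",
                       "grade", "race", "batch")

as_flag <- function(x, column) {
  out <- rep(NA, length(x))
  x_chr <- tolower(trimws(as.character(x)))
  out[x_chr %in% c("1", "true", "yes")] <- TRUE
  out[x_chr %in% c("0", "false", "no")] <- FALSE
  if (anyNA(out))
    abort_fmt("column '%s' must be 0/1 (got: %s)", column,
              paste(head(unique(x[is.na(out)]), 3), collapse = ", "))
  out
}

#' Read a clinical table from CSV
#'
#' Mandatory columns: `sample_id`, `act` (0/1, received 5-Fu-based
#' adjuvant chemotherapy), `rfs_months` (relapse-free survival, months,
#' non-negative), `relapse_event` (0/1), `tnm_stage` (`II` or `III`; the
#' modelling population is restricted to stage II-III disease).  Optional
#' columns (`age_years`, `sex`, `t_stage`, `n_stage`, `site`, `grade`,
#' `race`, `batch`) are typed when present; unknown columns are preserved
#' as categorical extras.  Missing optional values stay missing — nothing
#' is imputed.
#'
#' @param path CSV path.
#' @return a `data.frame`, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(clinical_mandatory, colnames(df))
  if (length(missing_cols))
    abort_fmt("clinical table is missing mandatory column(s): %s",
              paste(missing_cols, collapse = ", "))
  validate_clinical(df, from = path)
}

#' Validate a clinical data frame
#'
#' Applies the same typing and invariant checks as [read_clinical()] to an
#' in-memory data frame (useful for synthetic cohorts).
#'
#' @param df data frame with the documented columns.
#' @param from label used in error messages.
#' @return the typed data frame.
#' @export
validate_clinical <- function(df, from = "clinical table") {
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    abort_fmt("%s: duplicate sample_id: %s", from, paste(head(dup, 5), collapse = ", "))
  df$act <- as_flag(df$act, "act")
  df$relapse_event <- as_flag(df$relapse_event, "relapse_event")
  df$rfs_months <- suppressWarnings(as.numeric(df$rfs_months))
  if (anyNA(df$rfs_months) || any(df$rfs_months < 0))
    abort_fmt("%s: rfs_months must be non-negative numbers", from)
  stage <- toupper(trimws(as.character(df$tnm_stage)))
  bad_stage <- setdiff(unique(stage), c("II", "III"))
  if (length(bad_stage))
    abort_fmt("%s: tnm_stage must be II or III (model population); got: %s",
              from, paste(bad_stage, collapse = ", "))
  df$tnm_stage <- factor(stage, levels = c("II", "III"))
  if ("age_years" %in% colnames(df)) {
    df$age_years <- suppressWarnings(as.numeric(df$age_years))
    if (any(df$age_years <= 0, na.rm = TRUE))
      abort_fmt("%s: age_years must be positive", from)
  }
  if ("sex" %in% colnames(df)) {
    sx <- tolower(trimws(as.character(df$sex)))
    sx[sx %in% c("", "na")] <- NA
    bad <- setdiff(unique(sx[!is.na(sx)]), c("male", "female"))
    if (length(bad))
      abort_fmt("%s: sex must be male/female; got: %s", from,
                paste(bad, collapse = ", "))
    df$sex <- factor(sx, levels = c("male", "female"))
  }
  df
}

#' Align expression and clinical data into a cohort
#'
#' Keeps the intersection of sample ids, warning about ids present on one
#' side only, and returns both parts in a canonical (sorted-id) order so
#' the result does not depend on input row or column order.
#'
#' @param expression an [expression_matrix()].
#' @param clinical a clinical `data.frame` (see [read_clinical()]).
#' @return `list(expression=, clinical=)` with matching, sorted sample ids.
#' @export
align_cohort <- function(expression, clinical) {
  sc <- expr_scale(expression)
  common <- sort(intersect(colnames(expression), clinical$sample_id))
  if (!length(common)) abort_fmt("no sample ids shared between expression and clinical data")
  dropped <- c(setdiff(colnames(expression), common),
               setdiff(clinical$sample_id, common))
  if (length(dropped))
    warn_fmt("dropping %d unmatched sample(s): %s", length(dropped),
             paste(head(sort(dropped), 8), collapse = ", "))
  expression <- set_scale(expression[, common, drop = FALSE], sc)
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expression = expression, clinical = clinical)
}

model_format_version <- "actbenefit-model/1"

#' Serialize a trained benefit model to a JSON document
#'
#' The document stores everything needed to reproduce predictive scores
#' exactly: selected genes, stage inclusion, RBF parameters, support
#' vectors and coefficients, feature standardization constants, the Platt
#' calibration, the score cutoff (if set) and a training summary.
#'
#' @param model a `benefit_model` from [train_final_model()].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "benefit_model"))
  doc <- unclass(model)
  doc$format <- model_format_version
  doc$sv <- lapply(seq_len(nrow(doc$sv)), function(i) as.numeric(doc$sv[i, ]))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the deserialized `benefit_model`; scores
#'   computed from it agree with the original to better than 1e-9.
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    abort_fmt("cannot parse model file %s: %s", path,
                              conditionMessage(e)))
  if (!identical(doc$format, model_format_version))
    abort_fmt("model file %s has format '%s'; this build reads '%s'",
              path, doc$format %||% "<missing>", model_format_version)
  doc$format <- NULL
  if (is.list(doc$sv)) {
    doc$sv <- do.call(rbind, lapply(doc$sv, as.numeric))
  } else if (!is.matrix(doc$sv)) {
    doc$sv <- matrix(as.numeric(doc$sv), nrow = 1L)
  }
  dimnames(doc$sv) <- NULL
  doc$sv_coefs <- as.numeric(doc$sv_coefs)
  doc$feature_means <- setNames(as.numeric(doc$feature_means), doc$selected_genes)
  doc$feature_sds <- setNames(as.numeric(doc$feature_sds), doc$selected_genes)
  doc$cutoff <- if (is.null(doc$cutoff)) NA_real_ else as.numeric(doc$cutoff)
  structure(doc, class = "benefit_model")
}

#' @export
print.benefit_model <- function(x, ...) {
  cat("RBF-SVM treatment-benefit model\n")
  cat("  genes:", paste(x$selected_genes, collapse = ", "), "\n")
  cat("  TNM stage included:", x$include_stage, "\n")
  cat(sprintf("  cost = %g, gamma = %g, support vectors = %d\n",
              x$cost, x$gamma, nrow(x$sv)))
  cat(sprintf("  CV fitness (AUC) = %s, cutoff = %s\n",
              format(x$training$fitness), format(x$cutoff)))
  invisible(x)
}
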