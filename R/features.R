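#' Effective DEGs of a module
#'
#' Module members that are present on the expression platform; only these
#' enter the module's patient feature.
#'
#' @param module_genes Character vector of module members.
#' @param expression_genes Character vector of genes measured on the
#'   platform.
#' @return Character vector (possibly empty) of effective DEGs.
#' @export
effective_degs <- function(module_genes, expression_genes) {
  intersect(unique(as.character(module_genes)), unique(as.character(expression_genes)))
}

#' Module feature: mean expression over effective DEGs
#'
#' Per patient, the arithmetic mean of the expression of the module's
#' effective DEGs — a surrogate for the activation state of the pathway the
#' module represents. Missing expression entries are excluded from that
#' patient's mean; a patient missing all members gets `NA`.
#'
#' @param expression Numeric matrix, patients in rows, genes in columns.
#' @param effective_set Non-empty character vector of genes to average.
#' @return Named numeric vector, one value per patient.
#' @export
module_feature <- function(expression, effective_set) {
  stopifnot(is.matrix(expression), !is.null(colnames(expression)))
  effective_set <- intersect(effective_set, colnames(expression))
  if (length(effective_set) == 0L) {
    stop("effective DEG set is empty for this module", call. = FALSE)
  }
  rowMeans(expression[, effective_set, drop = FALSE], na.rm = TRUE)
}

#' Module feature matrix for a partition
#'
#' Computes one feature column per module from a module partition and an
#' expression matrix. Modules whose members are entirely absent from the
#' platform are skipped with a warning.
#'
#' @param partition Named integer label vector (DEG -> module).
#' @param expression Numeric matrix, patients x genes.
#' @return Numeric matrix, patients x modules, columns named `module_<m>`.
#' @export
module_feature_table <- function(partition, expression) {
  modules <- sort(unique(as.integer(partition)))
  cols <- list()
  for (m in modules) {
    genes <- effective_degs(names(partition)[partition == m], colnames(expression))
    if (length(genes) == 0L) {
      warning(sprintf("module %d has no effective DEGs on the platform; feature skipped", m),
              call. = FALSE)
      next
    }
    cols[[paste0("module_", m)]] <- module_feature(expression, genes)
  }
  do.call(cbind, cols)
}

#' Join module features with clinical covariates
#'
#' Column-binds module features and numerically encoded clinical covariates
#' on the patient identifier. Under the default complete-case policy,
#' patients missing from either table or carrying any missing value are
#' dropped (with a message of how many).
#'
#' @param module_features Numeric matrix, patients x module features, with
#'   patient identifiers as row names.
#' @param clinical Data frame of numeric covariates with a `patient_id`
#'   column, or `NULL` for a module-only table.
#' @param complete_cases Drop patients with any missing feature (default
#'   `TRUE`).
#' @return Numeric matrix, patients x features, with attribute `kind`
#'   labelling each column `"module"` or `"clinical"`.
#' @export
assemble_features <- function(module_features, clinical = NULL,
                              complete_cases = TRUE) {
  stopifnot(is.matrix(module_features), !is.null(rownames(module_features)))
  out <- module_features
  kind <- rep("module", ncol(module_features))
  if (!is.null(clinical)) {
    stop_missing_columns(clinical, "patient_id", "clinical table")
    shared <- intersect(rownames(module_features), clinical$patient_id)
    if (length(shared) == 0L) {
      stop("no overlapping patients between module features and clinical table",
           call. = FALSE)
    }
    clin <- clinical[match(shared, clinical$patient_id),
                     setdiff(names(clinical), "patient_id"), drop = FALSE]
    if (!all(vapply(clin, is.numeric, TRUE))) {
      stop("clinical covariates must be numerically encoded", call. = FALSE)
    }
    out <- cbind(module_features[shared, , drop = FALSE], as.matrix(clin))
    rownames(out) <- shared
    kind <- c(kind, rep("clinical", ncol(clin)))
  }
  if (complete_cases) {
    ok <- stats::complete.cases(out)
    if (!all(ok)) {
      message(sprintf("dropping %d patient(s) with missing features", sum(!ok)))
    }
    out <- out[ok, , drop = FALSE]
  }
  attr(out, "kind") <- stats::setNames(kind, colnames(out))
  out
}

#' Z-score normalization of a feature table
#'
#' Per feature across patients: subtract the mean and divide by the sample
#' (n - 1) standard deviation. Constant features cannot be scaled and are
#' dropped with a warning.
#'
#' @param features Numeric matrix, patients x features.
#' @return Normalized matrix; retained features have mean 0 and unit
#'   standard deviation. The `kind` attribute, if present, is carried along.
#' @export
zscore_normalize <- function(features) {
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  kind <- attr(features, "kind")
  sds <- apply(features, 2L, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(features)[constant], collapse = ", ")),
            call. = FALSE)
    features <- features[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  out <- scale(features, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (!is.null(kind)) attr(out, "kind") <- kind[colnames(out)]
  out
}
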