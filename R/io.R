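read_tsv_checked <- function(path, required, what, colClasses = NA) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = colClasses, quote = "",
                          comment.char = "")
  stop_missing_columns(df, required, what)
  df
}

#' Read a causal-assignment table
#'
#' Tab-separated with header `tumour_id`, `sga`, `deg`, `posterior`.
#'
#' @param path File path.
#' @return Data frame with the four columns, posterior numeric.
#' @export
read_assignments <- function(path) {
  df <- read_tsv_checked(path, c("tumour_id", "sga", "deg", "posterior"),
                         "assignment table")
  df$tumour_id <- as.character(df$tumour_id)
  df$sga <- as.character(df$sga)
  df$deg <- as.character(df$deg)
  df$posterior <- as.numeric(df$posterior)
  validate_assignments(df)
  df
}

#' Read an SGA observation table
#'
#' Tab-separated with header `tumour_id`, `sga`.
#'
#' @param path File path.
#' @return Data frame with the two character columns.
#' @export
read_observations <- function(path) {
  df <- read_tsv_checked(path, c("tumour_id", "sga"), "observation table")
  df$tumour_id <- as.character(df$tumour_id)
  df$sga <- as.character(df$sga)
  df
}

#' Read a patient x gene expression matrix
#'
#' Tab-separated; first column `patient_id`, remaining columns one per
#' gene. Duplicate patient or gene identifiers are rejected.
#'
#' @param path File path.
#' @return Numeric matrix with patient row names and gene column names.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "patient_id", "expression matrix")
  ids <- as.character(df$patient_id)
  if (anyDuplicated(ids)) stop("duplicate patient identifiers", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "patient_id"), drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate gene identifiers", call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a clinical covariate table
#'
#' Tab-separated with a `patient_id` column; all other columns must be
#' numerically encoded covariates.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, "patient_id", "clinical table")
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Read a survival table
#'
#' Tab-separated with header `patient_id`, `time`, `event` (0 alive /
#' 1 dead).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_survival <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "time", "event"),
                         "survival table")
  df$patient_id <- as.character(df$patient_id)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  validate_survival(df$time, df$event)
  df
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: one set per line with fields name,
#' description, then member genes. Lines with fewer than three fields are
#' rejected with their line number; duplicate members within a set are
#' dropped with a warning.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions kept in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line(s) with fewer than 3 fields: %s",
                 paste(short, collapse = ", ")), call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate member(s) in gene set '%s' removed", f[1L]),
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[`, "", 2L)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of descriptions (defaults
#'   to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
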