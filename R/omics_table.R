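#' Construct an omics table
#'
#' An `omics_table` holds a samples-by-variables numeric matrix together with
#' a kind annotation (`"mRNA"` or `"lipid"`) for every variable. It is the
#' container shared by every stage of the pipeline: normalization, normality
#' screening, the single-sample network statistic and the cohort statistics
#' all consume it.
#'
#' Validation is strict: values must be finite (no `NA`/`NaN`/`Inf`; the
#' network statistic has no missing-data rule, so missing values are rejected
#' rather than silently imputed), sample and variable identifiers must be
#' unique, and every variable must carry a kind annotation.
#'
#' @param values Numeric matrix, samples in rows, variables in columns, with
#'   row and column names set.
#' @param variable_kind Named character vector mapping each variable id to
#'   `"mRNA"` or `"lipid"`.
#' @return An object of class `omics_table`: a list with elements `values`,
#'   `sample_ids`, `variable_ids`, `variable_kind`.
#' @export
omics_table <- function(values, variable_kind) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  sample_ids <- rownames(values)
  variable_ids <- colnames(values)
  if (is.null(sample_ids) || is.null(variable_ids)) {
    stop("`values` must have row names (sample ids) and column names (variable ids)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variable_ids)) {
    stop("duplicated variable ids: ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite value at sample '%s', variable '%s'",
                 sample_ids[bad[1L, 1L]], variable_ids[bad[1L, 2L]]))
  }
  variable_kind <- check_kinds(variable_kind, variable_ids)
  structure(
    list(values = values,
         sample_ids = sample_ids,
         variable_ids = variable_ids,
         variable_kind = variable_kind[variable_ids]),
    class = "omics_table")
}

check_kinds <- function(variable_kind, variable_ids) {
  if (is.null(names(variable_kind))) stop("`variable_kind` must be named")
  variable_kind <- vapply(variable_kind, as.character, character(1))
  missing <- setdiff(variable_ids, names(variable_kind))
  if (length(missing) > 0L) {
    stop("variables missing from annotation: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(variable_kind), variable_ids)
  if (length(extra) > 0L) {
    stop("annotated variables absent from data: ", paste(extra, collapse = ", "))
  }
  unknown <- setdiff(unique(variable_kind), c("mRNA", "lipid"))
  if (length(unknown) > 0L) {
    stop("unknown variable kind: ", paste(unknown, collapse = ", "),
         " (expected 'mRNA' or 'lipid')")
  }
  variable_kind
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table: %d samples x %d variables (%d mRNA, %d lipid)\n",
              length(x$sample_ids), length(x$variable_ids),
              sum(x$variable_kind == "mRNA"), sum(x$variable_kind == "lipid")))
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

#' Read an omics table from TSV files
#'
#' The data file is tab-separated with a header row; the first column is
#' `sample_id`, remaining columns are variables, decimal separator is `"."`.
#' The annotation file has columns `variable_id` and `kind` and must cover
#' exactly the variables present in the data.
#'
#' @param path Path to the data TSV.
#' @param annotation_path Path to the variable-annotation TSV.
#' @return A validated [omics_table()].
#' @export
read_omics_table <- function(path, annotation_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 3L) stop("data TSV needs a sample_id column and >= 2 variables")
  sample_ids <- raw[[1L]]
  variable_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(variable_ids),
                 dimnames = list(sample_ids, variable_ids))
  for (j in seq_along(variable_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell '%s' at sample '%s', variable '%s'",
                   col[bad[1L]], sample_ids[bad[1L]], variable_ids[j]))
    }
    vals[, j] <- num
  }
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("variable_id", "kind") %in% colnames(ann))) {
    stop("annotation TSV must have columns 'variable_id' and 'kind'")
  }
  if (anyDuplicated(ann$variable_id)) {
    stop("duplicated variable_id in annotation: ",
         paste(unique(ann$variable_id[duplicated(ann$variable_id)]), collapse = ", "))
  }
  kind <- stats::setNames(ann$kind, ann$variable_id)
  omics_table(vals, kind)
}

#' Write an omics table to TSV files
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every double bit-exactly.
#'
#' @param table An [omics_table()].
#' @param path Output path for the data TSV.
#' @param annotation_path Optional output path for the annotation TSV.
#' @return Invisibly, `path`.
#' @export
write_omics_table <- function(table, path, annotation_path = NULL) {
  stopifnot(inherits(table, "omics_table"))
  header <- paste(c("sample_id", table$variable_ids), collapse = "\t")
  rows <- vapply(seq_along(table$sample_ids), function(i) {
    paste(c(table$sample_ids[i], sprintf("%.17g", table$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  if (!is.null(annotation_path)) {
    writeLines(c("variable_id\tkind",
                 paste(table$variable_ids, table$variable_kind, sep = "\t")),
               annotation_path)
  }
  invisible(path)
}

#' Subset the samples of an omics table
#'
#' @param table An [omics_table()].
#' @param sample_ids Character vector of sample ids to keep (order preserved).
#' @return An [omics_table()] with the requested rows.
#' @export
subset_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "omics_table"))
  missing <- setdiff(sample_ids, table$sample_ids)
  if (length(missing) > 0L) {
    stop("samples absent from table: ", paste(missing, collapse = ", "))
  }
  omics_table(table$values[sample_ids, , drop = FALSE], table$variable_kind)
}
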