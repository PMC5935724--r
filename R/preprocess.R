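#' Normalize an omics table to the reference-group mean
#'
#' Every value is divided by the arithmetic mean of its variable within the
#' reference group, so each variable's reference-group mean equals 1
#' afterwards (fold-change semantics; a `subtract` mode centers instead).
#' With a rank correlation downstream the choice between division and
#' subtraction is inert — both are strictly monotone per-variable maps — but
#' division keeps strictly positive data positive.
#'
#' @param table An [omics_table()].
#' @param design A [group_design()]; its reference cell defines the baseline.
#' @param mode `"divide"` (default) or `"subtract"`.
#' @param tol Reference means with `|mean| < tol` are an error (default 1e-12).
#' @return A normalized [omics_table()].
#' @export
normalize_to_reference <- function(table, design, mode = c("divide", "subtract"),
                                   tol = 1e-12) {
  stopifnot(inherits(table, "omics_table"), inherits(design, "group_design"))
  mode <- match.arg(mode)
  ref_ids <- group_samples(design)
  missing <- setdiff(ref_ids, table$sample_ids)
  if (length(missing) > 0L) {
    stop("reference sample(s) absent from table: ",
         paste(missing, collapse = ", "))
  }
  ref_mean <- colMeans(table$values[ref_ids, , drop = FALSE])
  if (mode == "divide") {
    bad <- which(abs(ref_mean) < tol)
    if (length(bad) > 0L) {
      stop("zero (|mean| < tol) reference mean for variable(s): ",
           paste(table$variable_ids[bad], collapse = ", "))
    }
    vals <- sweep(table$values, 2L, ref_mean, `/`)
  } else {
    vals <- sweep(table$values, 2L, ref_mean, `-`)
  }
  omics_table(vals, table$variable_kind)
}

#' Shapiro-Wilk normality screen
#'
#' Tests each variable for normality with the Shapiro-Wilk test and
#' recommends the correlation method for the network stage: `"spearman"` as
#' soon as any variable rejects normality at `alpha_norm` (or is constant,
#' where W is undefined and the variable is flagged non-normal),
#' `"pearson"` otherwise. The pipeline records this recommendation but
#' defaults to Spearman regardless, the appropriate choice for skewed
#' fold-change and lipid data.
#'
#' @param table An [omics_table()] with at least 3 samples.
#' @param alpha_norm Significance level of the screen (default 0.05).
#' @return Object of class `normality_report`: list with `per_variable`
#'   (data.frame: `variable`, `W`, `p`, `constant`), `recommendation`,
#'   `alpha_norm`, `n_non_normal`.
#' @export
shapiro_screen <- function(table, alpha_norm = 0.05) {
  stopifnot(inherits(table, "omics_table"))
  n <- length(table$sample_ids)
  if (n < 3L) stop("Shapiro-Wilk test needs at least 3 samples")
  res <- lapply(table$variable_ids, function(v) {
    x <- table$values[, v]
    if (diff(range(x)) == 0) {
      data.frame(variable = v, W = NA_real_, p = 0, constant = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      sw <- stats::shapiro.test(x)
      data.frame(variable = v, W = unname(sw$statistic), p = sw$p.value,
                 constant = FALSE, stringsAsFactors = FALSE)
    }
  })
  per_variable <- do.call(rbind, res)
  non_normal <- per_variable$p < alpha_norm | per_variable$constant
  structure(list(
    per_variable = per_variable,
    recommendation = if (any(non_normal)) "spearman" else "pearson",
    alpha_norm = alpha_norm,
    n_non_normal = sum(non_normal)), class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf(
    "normality_report: %d/%d variable(s) non-normal at alpha = %g -> %s\n",
    x$n_non_normal, nrow(x$per_variable), x$alpha_norm, x$recommendation))
  invisible(x)
}

#' Delta-delta-Ct relative quantification
#'
#' Standard ddCt: per sample \eqn{s} and target \eqn{t},
#' \eqn{\Delta Ct = Ct_{t,s} - Ct_{hk,s}}; \eqn{\Delta\Delta Ct} subtracts
#' the arithmetic mean \eqn{\Delta Ct} of the reference group (equivalently,
#' the baseline is the reference group's geometric-mean expression); the
#' fold change is \eqn{2^{-\Delta\Delta Ct}}. The reference group's
#' geometric mean fold is therefore 1 for every target. No amplification-
#' efficiency correction is applied.
#'
#' @param ct A `ct_table` from [generate_ct_table()], or a samples-by-targets
#'   numeric matrix of Ct values with row and column names.
#' @param housekeeping Housekeeping target id; defaults to the `ct_table`'s
#'   own. Required when `ct` is a bare matrix.
#' @param design A [group_design()] whose reference cell sets the baseline;
#'   defaults to the `ct_table`'s design.
#' @return Samples-by-targets matrix of fold changes (housekeeping excluded).
#' @export
ddct_fold_changes <- function(ct, housekeeping = NULL, design = NULL) {
  if (inherits(ct, "ct_table")) {
    if (is.null(housekeeping)) housekeeping <- ct$housekeeping
    if (is.null(design)) design <- ct$design
    ct <- ct$ct
  }
  if (!is.matrix(ct) || !is.numeric(ct)) stop("`ct` must be a numeric matrix")
  if (is.null(housekeeping)) stop("`housekeeping` is required")
  if (is.null(design)) stop("`design` is required")
  stopifnot(inherits(design, "group_design"))
  if (!housekeeping %in% colnames(ct)) {
    stop("housekeeping id '", housekeeping, "' not found in Ct table")
  }
  if (anyNA(ct)) {
    bad <- which(is.na(ct), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing Ct at sample '%s', target '%s'",
                 rownames(ct)[bad[1L]], colnames(ct)[bad[2L]]))
  }
  ref_ids <- group_samples(design)
  missing <- setdiff(ref_ids, rownames(ct))
  if (length(missing) > 0L) {
    stop("reference sample(s) absent from Ct table: ",
         paste(missing, collapse = ", "))
  }
  targets <- setdiff(colnames(ct), housekeeping)
  dct <- ct[, targets, drop = FALSE] - ct[, housekeeping]
  ref_mean <- colMeans(dct[ref_ids, , drop = FALSE])
  ddct <- sweep(dct, 2L, ref_mean, `-`)
  2^(-ddct)
}
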