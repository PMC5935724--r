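#' Pairwise correlation matrix of a sample subset
#'
#' Spearman (default) or Pearson correlation between all variable pairs of a
#' set of samples. Spearman is computed as Pearson on mid-ranks (average
#' ranks for ties), the standard convention. A variable that is constant
#' within the subset makes the correlation undefined and is a hard error —
#' one undefined column would corrupt the pair background distribution used
#' for edge significance downstream.
#'
#' @param values Numeric matrix, samples in rows, variables in columns (an
#'   [omics_table()] is also accepted).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @export
correlation_matrix <- function(values, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (inherits(values, "omics_table")) values <- values$values
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) < 3L) stop("correlation needs at least 3 samples")
  if (ncol(values) < 2L) stop("correlation needs at least 2 variables")
  const <- apply(values, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("constant variable(s) in subset (correlation undefined): ",
         paste(colnames(values)[const], collapse = ", "))
  }
  stats::cor(values, method = method)
}

#' Add-one-sample correlation perturbation (delta SCC)
#'
#' The single-sample network primitive: the entry-wise difference between
#' the correlation matrix of the reference group with one extra sample
#' appended and the correlation matrix of the reference group alone,
#' \eqn{\Delta SCC = SCC_{ref+1} - SCC_{ref}}. A sample that fits the
#' reference correlation structure perturbs nothing; a sample from a
#' perturbed regime shifts the pairs whose dependence it breaks or creates.
#'
#' @param reference_values Numeric matrix of the reference samples (rows) by
#'   variables (columns); at least 3 rows.
#' @param sample_row Numeric vector (or 1-row matrix) with one value per
#'   variable, in the reference column order.
#' @param method Correlation method, see [correlation_matrix()].
#' @return Symmetric matrix with zero diagonal, entries in \eqn{[-2, 2]}.
#' @export
delta_scc <- function(reference_values, sample_row,
                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (inherits(reference_values, "omics_table")) {
    reference_values <- reference_values$values
  }
  sample_row <- as.numeric(sample_row)
  if (length(sample_row) != ncol(reference_values)) {
    stop("added sample must have one value per variable")
  }
  if (anyNA(sample_row) || any(!is.finite(sample_row))) {
    stop("added sample contains non-finite values")
  }
  ref_scc <- correlation_matrix(reference_values, method)
  aug <- rbind(reference_values, sample_row)
  aug_scc <- correlation_matrix(aug, method)
  aug_scc - ref_scc
}

#' Group-median correlation perturbation
#'
#' Computes one [delta_scc()] matrix per group sample — the reference never
#' grows by more than one sample at a time — and takes the entry-wise median
#' across the group. The median (not the mean) is used so no single animal
#' dominates the group's perturbation profile. For even group sizes the
#' median is the mean of the two central values.
#'
#' @param reference_values Reference-group samples-by-variables matrix.
#' @param group_values Matrix of the group's samples (at least 1 row), same
#'   variable columns.
#' @param method Correlation method.
#' @return List: `median_delta` (symmetric matrix, zero diagonal) and
#'   `per_sample` (3-d array, variables x variables x samples).
#' @export
group_median_delta <- function(reference_values, group_values,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (inherits(reference_values, "omics_table")) {
    reference_values <- reference_values$values
  }
  if (inherits(group_values, "omics_table")) group_values <- group_values$values
  if (is.null(dim(group_values))) group_values <- matrix(group_values, nrow = 1L)
  if (nrow(group_values) < 1L) stop("group must contain at least one sample")
  p <- ncol(reference_values)
  per_sample <- array(NA_real_, dim = c(p, p, nrow(group_values)),
                      dimnames = list(colnames(reference_values),
                                      colnames(reference_values),
                                      rownames(group_values)))
  for (i in seq_len(nrow(group_values))) {
    per_sample[, , i] <- delta_scc(reference_values, group_values[i, ], method)
  }
  median_delta <- apply(per_sample, c(1L, 2L), stats::median)
  list(median_delta = median_delta, per_sample = per_sample)
}

#' Edge significance from a median delta-SCC matrix
#'
#' For each variable pair, a z-score measures how far the pair's median
#' perturbation lies from the mean perturbation across *all* pairs of the
#' group (genes and lipids alike; lipid filtering happens only at
#' selection): \eqn{z_e = (m_e - \bar m) / s}, with \eqn{s} the sample
#' (n-1) standard deviation over pairs, and a two-sided normal p-value
#' \eqn{p_e = 2(1 - \Phi(|z_e|))}. By construction the z vector over all
#' pairs has mean 0 and sample s.d. 1.
#'
#' @param median_delta Symmetric matrix of group-median delta-SCC values.
#' @return data.frame with one row per unordered pair: `var_a`, `var_b`,
#'   `pair`, `median_delta`, `z`, `p`.
#' @export
edge_significance <- function(median_delta) {
  if (!is.matrix(median_delta) || !isSymmetric(unname(median_delta))) {
    stop("`median_delta` must be a symmetric matrix")
  }
  vars <- colnames(median_delta)
  if (is.null(vars)) stop("`median_delta` must have variable names")
  pairs <- all_pairs(vars)
  m <- median_delta[cbind(match(pairs$var_a, vars), match(pairs$var_b, vars))]
  zs <- pair_zscores(m)
  data.frame(var_a = pairs$var_a, var_b = pairs$var_b, pair = pairs$pair,
             median_delta = m, z = zs$z, p = zs$p,
             stringsAsFactors = FALSE)
}

#' Standardize a vector of pair statistics to z-scores and p-values
#'
#' The scoring core of [edge_significance()], usable on any vector of
#' per-pair median delta-SCC values: each value is standardized against the
#' mean and sample (n-1) standard deviation of the whole vector, and a
#' two-sided normal p-value is attached. The returned z vector has mean 0
#' and sample s.d. 1 by construction.
#'
#' @param values Numeric vector of per-pair statistics, length >= 2.
#' @return List with numeric vectors `z` and `p`.
#' @export
pair_zscores <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 pairs")
  if (anyNA(values)) stop("pair values must not contain NA")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate median delta-SCC distribution (zero s.d. across pairs)")
  z <- (values - mean(values)) / s
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Select significant network edges
#'
#' Keeps pairs with p below `alpha`, by default restricted to pairs touching
#' at least one lipid variable — the perturbations of interest link the
#' transcriptional program to the lipid phenotype. Edges are sorted by p
#' ascending, ties broken by |median delta| descending, then canonical pair
#' key. A `direction` column marks a gain (`median_delta > 0`) or loss of
#' correlation relative to the reference group. No multiple-testing
#' correction is applied by default (raw p < 0.05 selection);
#' Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @param stats_df Pair table from [edge_significance()].
#' @param variable_kind Named kind vector (`"mRNA"`/`"lipid"`) covering every
#'   endpoint.
#' @param alpha Selection level (default 0.05).
#' @param lipid_only Keep only lipid-touching pairs (default TRUE).
#' @param adjust `"none"` (default) or `"BH"`; applied to the p-values used
#'   for selection and reported in column `p_adj`.
#' @return data.frame of edge records: `var_a`, `var_b`, `pair`, `kind_a`,
#'   `kind_b`, `median_delta`, `z`, `p`, `p_adj`, `direction`,
#'   `involves_lipid`. Empty selections are valid.
#' @export
select_edges <- function(stats_df, variable_kind, alpha = 0.05,
                         lipid_only = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("var_a", "var_b", "pair", "median_delta", "z", "p")
  if (!all(need %in% colnames(stats_df))) {
    stop("`stats_df` must come from edge_significance()")
  }
  endpoints <- unique(c(stats_df$var_a, stats_df$var_b))
  missing <- setdiff(endpoints, names(variable_kind))
  if (length(missing) > 0L) {
    stop("kind annotation missing for: ", paste(missing, collapse = ", "))
  }
  out <- stats_df
  out$kind_a <- unname(variable_kind[out$var_a])
  out$kind_b <- unname(variable_kind[out$var_b])
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, method = "BH") else out$p
  out$direction <- ifelse(out$median_delta > 0, "gain", "loss")
  out$involves_lipid <- out$kind_a == "lipid" | out$kind_b == "lipid"
  keep <- out$p_adj < alpha
  if (lipid_only) keep <- keep & out$involves_lipid
  out <- out[keep, , drop = FALSE]
  ord <- order(out$p, -abs(out$median_delta), out$pair, method = "radix")
  out <- out[ord, c("var_a", "var_b", "pair", "kind_a", "kind_b",
                    "median_delta", "z", "p", "p_adj", "direction",
                    "involves_lipid")]
  rownames(out) <- NULL
  out
}

#' Run the full group-median single-sample network analysis
#'
#' The complete pipeline on one dataset: (1) normalize every variable to the
#' reference-group mean; (2) record a Shapiro-Wilk normality screen (it does
#' not gate the method by default — `method = "auto"` follows its
#' recommendation); (3) for each non-reference group, compute the per-sample
#' add-one delta-SCC matrices against the reference, take their entry-wise
#' median, standardize all pairs to z-scores, and select significant
#' lipid-touching edges. Under the default 2x2 factorial this yields three
#' group networks. The whole computation is deterministic given its inputs.
#'
#' @param table An [omics_table()].
#' @param design A [group_design()].
#' @param alpha Edge-selection level (default 0.05).
#' @param method `"spearman"` (default), `"pearson"`, or `"auto"` (use the
#'   normality screen's recommendation).
#' @param lipid_only Restrict selection to lipid-touching pairs (default TRUE).
#' @param adjust Multiple-testing adjustment for selection: `"none"`
#'   (default) or `"BH"`.
#' @param normalize Apply reference normalization first (default TRUE; rank
#'   correlations are invariant to it, so this affects only the values
#'   carried in the result).
#' @return Object of class `ssn_result`: list with `networks` (named list of
#'   `network_result` objects, one per non-reference group, each holding
#'   `group`, `nodes`, `edges`, `stats` (all pairs), `median_delta`,
#'   `params`), `normality` (the [shapiro_screen()] report), `reference`,
#'   `method`, `params`.
#' @export
run_ssn <- function(table, design, alpha = 0.05,
                    method = c("spearman", "pearson", "auto"),
                    lipid_only = TRUE, adjust = c("none", "BH"),
                    normalize = TRUE) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(inherits(table, "omics_table"), inherits(design, "group_design"))
  report <- validate_dataset(table, design)
  if (report$n_fatal > 0L) {
    stop("dataset validation failed: ",
         paste(report$findings$message[report$findings$level == "fatal"],
               collapse = "; "))
  }
  norm_table <- if (normalize) normalize_to_reference(table, design) else table
  normality <- shapiro_screen(norm_table)
  if (method == "auto") method <- normality$recommendation

  ref_ids <- group_samples(design)
  ref_values <- norm_table$values[ref_ids, , drop = FALSE]
  const <- apply(ref_values, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("variable(s) constant within reference group ",
         design$reference_label, ": ",
         paste(norm_table$variable_ids[const], collapse = ", "))
  }
  params <- list(alpha = alpha, method = method, lipid_only = lipid_only,
                 adjust = adjust, normalize = normalize)
  groups <- setdiff(group_labels(design), design$reference_label)
  networks <- list()
  for (g in groups) {
    ids <- group_samples(design, g)
    gmd <- tryCatch(
      group_median_delta(ref_values, norm_table$values[ids, , drop = FALSE],
                         method),
      error = function(e) {
        stop("group ", g, ": ", conditionMessage(e), call. = FALSE)
      })
    stats_df <- edge_significance(gmd$median_delta)
    edges <- select_edges(stats_df, norm_table$variable_kind, alpha,
                          lipid_only, adjust)
    networks[[g]] <- structure(
      list(group = g,
           nodes = data.frame(variable = norm_table$variable_ids,
                              kind = unname(norm_table$variable_kind),
                              node_class = ifelse(
                                norm_table$variable_kind == "lipid",
                                "lipid", "gene"),
                              stringsAsFactors = FALSE),
           edges = edges, stats = stats_df,
           median_delta = gmd$median_delta, params = params),
      class = "network_result")
  }
  structure(list(networks = networks, normality = normality,
                 reference = design$reference_label, method = method,
                 params = params),
            class = "ssn_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("network_result '%s': %d selected edge(s) of %d pairs (alpha = %g%s)\n",
              x$group, nrow(x$edges), nrow(x$stats), x$params$alpha,
              if (x$params$lipid_only) ", lipid-touching only" else ""))
  invisible(x)
}

#' @export
print.ssn_result <- function(x, ...) {
  cat(sprintf("ssn_result: %d group network(s) vs reference '%s' (%s)\n",
              length(x$networks), x$reference, x$method))
  for (nw in x$networks) print(nw)
  invisible(x)
}
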