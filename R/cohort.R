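#' Pooled-variance t-tests with one-way ANOVA per variable
#'
#' For every variable: a two-sided Student's t-test with a pooled variance
#' estimate comparing the two cells of `contrast`, and (by default) a
#' one-way equal-variance ANOVA across all design cells reported alongside.
#' The ANOVA does not gate the t-tests unless `gate_on_anova` is set, in
#' which case the t-test p-value is reported as NA when the overall F is not
#' significant at `gate_alpha`.
#'
#' @param table An [omics_table()].
#' @param design A [group_design()].
#' @param contrast Character vector of two cell labels
#'   (`"GENOTYPE:TREATMENT"`), compared as `contrast[1] - contrast[2]`.
#' @param anova Compute the per-variable one-way ANOVA across all cells
#'   (default TRUE).
#' @param gate_on_anova Report t-test p only when the ANOVA F is significant
#'   (default FALSE).
#' @param gate_alpha Gate level (default 0.05).
#' @return data.frame with one row per variable: `variable`, `t`, `df`, `p`,
#'   and (when `anova`) `F`, `df1`, `df2`, `p_anova`.
#' @export
pooled_t_tests <- function(table, design, contrast, anova = TRUE,
                           gate_on_anova = FALSE, gate_alpha = 0.05) {
  stopifnot(inherits(table, "omics_table"), inherits(design, "group_design"))
  if (length(contrast) != 2L) stop("`contrast` must name exactly two groups")
  ids1 <- intersect(group_samples(design, contrast[1L]), table$sample_ids)
  ids2 <- intersect(group_samples(design, contrast[2L]), table$sample_ids)
  if (length(ids1) < 2L || length(ids2) < 2L) {
    stop("both contrast groups need at least 2 samples in the table")
  }
  all_ids <- intersect(design$samples$sample_id, table$sample_ids)
  fac <- factor(design$samples$group[match(all_ids, design$samples$sample_id)])
  out <- lapply(table$variable_ids, function(v) {
    x1 <- table$values[ids1, v]
    x2 <- table$values[ids2, v]
    if (stats::var(x1) == 0 && stats::var(x2) == 0) {
      if (mean(x1) == mean(x2)) {
        row <- data.frame(variable = v, t = 0, df = length(x1) + length(x2) - 2L,
                          p = 1, stringsAsFactors = FALSE)
      } else {
        stop("zero pooled variance for variable '", v, "'")
      }
    } else {
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
      row <- data.frame(variable = v, t = unname(tt$statistic),
                        df = unname(tt$parameter), p = tt$p.value,
                        stringsAsFactors = FALSE)
    }
    if (anova) {
      ow <- stats::oneway.test(table$values[all_ids, v] ~ fac, var.equal = TRUE)
      row$F <- unname(ow$statistic)
      row$df1 <- unname(ow$parameter[1L])
      row$df2 <- unname(ow$parameter[2L])
      row$p_anova <- ow$p.value
      if (gate_on_anova && row$p_anova > gate_alpha) row$p <- NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hierarchical clustering of panel variables
#'
#' Agglomerative clustering of variables (the heatmap-row computation for an
#' expression panel): variables are z-scored across samples (optional),
#' pairwise distance is 1 - Pearson correlation (default) or Euclidean, and
#' the tree is cut to exactly `k` clusters. Defaults follow standard
#' expression-heatmap practice: correlation distance, average linkage,
#' row z-scoring, k = 4.
#'
#' The computation is deterministic: identical input yields identical merge
#' heights, leaf order and assignment.
#'
#' @param table An [omics_table()] (variables are clustered).
#' @param k Number of clusters to cut (default 4).
#' @param distance `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"ward"` (Ward.D2).
#' @param scale Z-score each variable across samples first (default TRUE).
#' @return Object of class `cluster_result`: list with `leaf_order`
#'   (variable ids in dendrogram order), `assignment` (named integer vector,
#'   exactly `k` distinct labels), `hclust` (the merge record), `k`,
#'   `distance`, `linkage`.
#' @export
hierarchical_clusters <- function(table, k = 4L,
                                  distance = c("correlation", "euclidean"),
                                  linkage = c("average", "ward"),
                                  scale = TRUE) {
  stopifnot(inherits(table, "omics_table"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  p <- length(table$variable_ids)
  if (k < 1L || k > p) stop("k must be between 1 and the number of variables")
  vals <- table$values
  if (scale) {
    sds <- apply(vals, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant variable(s) cannot be z-scored: ",
           paste(table$variable_ids[sds == 0], collapse = ", "))
    }
    vals <- scale(vals)
  }
  d <- if (distance == "correlation") {
    if (nrow(vals) < 3L) stop("correlation distance needs at least 3 samples")
    stats::as.dist(1 - stats::cor(vals))
  } else {
    stats::dist(t(vals))
  }
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else "average")
  assignment <- stats::cutree(hc, k = k)
  structure(list(leaf_order = hc$labels[hc$order],
                 assignment = assignment, hclust = hc,
                 k = as.integer(k), distance = distance, linkage = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("cluster_result: %d variables in %d clusters (%s distance, %s linkage)\n",
              length(x$assignment), x$k, x$distance, x$linkage))
  cat("  sizes:", paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
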