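#' Construct a factorial group design
#'
#' A `group_design` assigns every sample to one cell of a genotype-by-
#' treatment factorial and designates one cell as the reference group against
#' which all correlation perturbations (and delta-delta-Ct baselines) are
#' computed. In the motivating study design the reference is the untreated
#' wild-type cell of a 2x2 factorial with five animals per cell.
#'
#' Group labels are case-sensitive strings; a cell is written
#' `"GENOTYPE:TREATMENT"`.
#'
#' @param samples A data.frame with columns `sample_id`, `genotype`,
#'   `treatment` (one row per sample, no duplicates).
#' @param reference The reference cell as `"GENOTYPE:TREATMENT"`.
#' @return An object of class `group_design`: list with elements `samples`
#'   (the data.frame, plus a `group` label column), `reference` (length-2
#'   character vector) and `reference_label`.
#' @export
group_design <- function(samples, reference) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "genotype", "treatment")
  if (!all(need %in% colnames(samples))) {
    stop("design needs columns: ", paste(need, collapse = ", "))
  }
  samples <- samples[, need]
  for (col in need) samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in design: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  incomplete <- is.na(samples$genotype) | samples$genotype == "" |
    is.na(samples$treatment) | samples$treatment == ""
  if (any(incomplete)) {
    stop("missing factor level for sample(s): ",
         paste(samples$sample_id[incomplete], collapse = ", "))
  }
  ref <- parse_group_label(reference)
  samples$group <- paste(samples$genotype, samples$treatment, sep = ":")
  if (!any(samples$group == paste(ref, collapse = ":"))) {
    stop("reference group empty: no sample in '", reference, "'")
  }
  sizes <- table(samples$group)
  if (any(sizes < 3L)) {
    warning("group(s) with fewer than 3 samples: ",
            paste(names(sizes)[sizes < 3L], collapse = ", "),
            " (correlation estimates need >= 3)")
  }
  structure(
    list(samples = samples,
         reference = ref,
         reference_label = paste(ref, collapse = ":")),
    class = "group_design")
}

parse_group_label <- function(label) {
  parts <- strsplit(as.character(label), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(parts == "")) {
    stop("group label must be 'GENOTYPE:TREATMENT', got '", label, "'")
  }
  parts
}

#' @export
print.group_design <- function(x, ...) {
  sizes <- table(x$samples$group)
  cat(sprintf("group_design: %d samples in %d cells (reference %s)\n",
              nrow(x$samples), length(sizes), x$reference_label))
  for (g in names(sizes)) {
    cat(sprintf("  %s: n = %d%s\n", g, sizes[[g]],
                if (g == x$reference_label) " [reference]" else ""))
  }
  invisible(x)
}

#' Read a group design from TSV
#'
#' @param path TSV with columns `sample_id`, `genotype`, `treatment`.
#' @param reference Reference cell as `"GENOTYPE:TREATMENT"`.
#' @return A [group_design()].
#' @export
read_group_design <- function(path, reference) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  group_design(df, reference)
}

#' Write a group design to TSV
#' @param design A [group_design()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_group_design <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  utils::write.table(design$samples[, c("sample_id", "genotype", "treatment")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample ids belonging to one design cell
#' @param design A [group_design()].
#' @param group Cell label `"GENOTYPE:TREATMENT"`; default the reference cell.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(design, group = design$reference_label) {
  stopifnot(inherits(design, "group_design"))
  ids <- design$samples$sample_id[design$samples$group == group]
  if (length(ids) == 0L) stop("no samples in group '", group, "'")
  ids
}

#' All cell labels of a design, reference first
#' @param design A [group_design()].
#' @return Character vector of cell labels.
#' @export
group_labels <- function(design) {
  stopifnot(inherits(design, "group_design"))
  labs <- unique(design$samples$group)
  c(design$reference_label, setdiff(labs, design$reference_label))
}

#' Validate an omics table against a design
#'
#' Produces a validation report listing sample-set agreement, group sizes and
#' variables that are constant (zero variance) within any group; a constant
#' variable makes the rank correlation undefined, so the network stage will
#' refuse it. Disjoint sample sets are a fatal finding.
#'
#' @param table An [omics_table()].
#' @param design A [group_design()].
#' @return Object of class `validation_report`: list with `findings`
#'   (data.frame of `level` in `{"info","warning","fatal"}` and `message`),
#'   `group_sizes`, and `n_fatal`.
#' @export
validate_dataset <- function(table, design) {
  stopifnot(inherits(table, "omics_table"), inherits(design, "group_design"))
  findings <- list()
  add <- function(level, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = message, stringsAsFactors = FALSE)
  }
  in_both <- intersect(table$sample_ids, design$samples$sample_id)
  if (length(in_both) == 0L) {
    add("fatal", "table and design share no samples")
  }
  only_design <- setdiff(design$samples$sample_id, table$sample_ids)
  if (length(only_design) > 0L) {
    add("fatal", paste0("design sample(s) absent from table: ",
                        paste(only_design, collapse = ", ")))
  }
  only_table <- setdiff(table$sample_ids, design$samples$sample_id)
  if (length(only_table) > 0L) {
    add("warning", paste0("table sample(s) absent from design (ignored): ",
                          paste(only_table, collapse = ", ")))
  }
  sizes <- table(design$samples$group)
  add("info", paste0("group sizes: ",
                     paste(names(sizes), sizes, sep = "=", collapse = ", ")))
  for (g in names(sizes)) {
    ids <- intersect(group_samples(design, g), table$sample_ids)
    if (length(ids) < 2L) next
    v <- table$values[ids, , drop = FALSE]
    const <- table$variable_ids[apply(v, 2L, function(col) diff(range(col)) == 0)]
    if (length(const) > 0L) {
      add("warning", paste0("variable(s) constant within group ", g, ": ",
                            paste(const, collapse = ", ")))
    }
  }
  findings <- if (length(findings) > 0L) do.call(rbind, findings) else
    data.frame(level = character(), message = character(), stringsAsFactors = FALSE)
  structure(list(findings = findings,
                 group_sizes = as.integer(sizes),
                 n_fatal = sum(findings$level == "fatal")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d finding(s), %d fatal\n",
              nrow(x$findings), x$n_fatal))
  if (nrow(x$findings) > 0L) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s\n", x$findings$level[i], x$findings$message[i]))
    }
  }
  invisible(x)
}
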