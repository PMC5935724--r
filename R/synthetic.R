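#' Configuration of a synthetic dual-extraction study
#'
#' Describes a synthetic 2x2 factorial study (genotype x treatment) with a
#' gene-expression panel and a small set of lipid variables measured on the
#' same samples, emulating the statistical structure of a hepatic
#' LXR-activation experiment: a lipogenic gene cluster induced only in the
#' treated wild-type cell, a few genes repressed in that same cell, a latent
#' "lipogenesis" factor that drives baseline gene-lipid correlation, and
#' optional planted gains/losses of correlation for specific variable pairs
#' in specific groups.
#'
#' The generative model is log-normal: for sample \eqn{i} in group \eqn{g}
#' and variable \eqn{j},
#' \deqn{\log x_{ij} = \mu_{gj} + \lambda_j F_i + a_{gj} U_{e(j),i} + \sigma \epsilon_{ij}}
#' where \eqn{F_i} is the latent factor, \eqn{U_e} is a per-planted-edge
#' shared component and \eqn{\epsilon} is standard normal noise. Values are
#' exponentiated, so everything is strictly positive and right-skewed, as
#' qPCR fold changes and lipid amounts are. The downstream statistic is a
#' rank correlation, which the exponentiation leaves untouched, so planted
#' rank correlations are controllable analytically.
#'
#' A variable that belongs to a planted edge gets its latent-factor loading
#' zeroed and is decomposed into a shared coupling component plus an
#' independent filler component whose loadings are chosen analytically so
#' that (a) the pair's population Spearman correlation in group \eqn{g}
#' equals the configured target exactly (the Pearson correlation of the
#' underlying Gaussians is set to \eqn{2\sin(\pi\rho_s/6)}), and (b) the
#' variable's marginal variance is identical in every group — a planted gain
#' or loss changes only the dependence, never the marginal distribution.
#' Each variable may appear in at most one planted edge.
#'
#' @param n_per_group Samples per factorial cell (default 5, the study size).
#' @param n_genes Number of mRNA variables (default 74).
#' @param n_lipids Number of lipid variables (default 4: triglycerides,
#'   cholesterol, cholesterol esters, MUFA/(SFA+MUFA) ratio).
#' @param genotype_levels,treatment_levels Two labels each; the *induced*
#'   cell is `(genotype_levels[1], treatment_levels[2])`, i.e. treated
#'   wild type.
#' @param induced_cluster Integer gene indices up-shifted only in the induced
#'   cell (default `1:26`, the size of the lipogenic cluster).
#' @param delta_up Log-scale mean shift of the induced cluster (default
#'   `log(4)`, a 4-fold induction).
#' @param repressed_genes Integer gene indices down-shifted only in the
#'   induced cell (default `27:30`, a Dgat2-like profile).
#' @param delta_down Log-scale magnitude of the repression (default `log(2)`).
#' @param lipid_shift Named log-scale mean shifts applied to lipid variables
#'   in the induced cell (default: triglycerides up 2.5-fold, MUFA ratio up
#'   1.5-fold, mirroring treatment-driven steatosis).
#' @param latent_loading Per-variable loadings on the latent lipogenesis
#'   factor; `NULL` uses defaults (0.6 for induced-cluster genes and for the
#'   TG and MUFA-ratio lipids, 0.3 for the remaining lipids, 0.2 elsewhere).
#'   May be a single number or a full named vector.
#' @param planted_edges List of planted correlation edges; each element is a
#'   list with `pair` (two variable ids), `rho_ref` (target Spearman in all
#'   groups except `group`), `rho_perturbed` (target in `group`), and
#'   `group` (cell label `"GENOTYPE:TREATMENT"`). `|rho| < 1` required.
#' @param noise_sd Residual log-scale standard deviation (default 0.3).
#' @param seed Integer seed governing all randomness of the study.
#' @return Object of class `study_config` (a validated list).
#' @export
study_config <- function(n_per_group = 5L,
                         n_genes = 74L,
                         n_lipids = 4L,
                         genotype_levels = c("WT", "KO"),
                         treatment_levels = c("vehicle", "T09"),
                         induced_cluster = 1:26,
                         delta_up = log(4),
                         repressed_genes = 27:30,
                         delta_down = log(2),
                         lipid_shift = NULL,
                         latent_loading = NULL,
                         planted_edges = list(),
                         noise_sd = 0.3,
                         seed = 1L) {
  if (n_per_group < 3L) stop("n_per_group must be >= 3")
  if (n_genes < 1L || n_lipids < 1L) stop("need at least one gene and one lipid")
  stopifnot(length(genotype_levels) == 2L, length(treatment_levels) == 2L)
  if (any(induced_cluster > n_genes) || any(repressed_genes > n_genes)) {
    stop("induced/repressed gene indices exceed n_genes")
  }
  if (length(intersect(induced_cluster, repressed_genes)) > 0L) {
    stop("a gene cannot be both induced and repressed")
  }
  gene_ids <- sprintf("gene_%02d", seq_len(n_genes))
  lipid_ids <- default_lipid_ids(n_lipids)
  variable_ids <- c(gene_ids, lipid_ids)

  if (is.null(lipid_shift)) {
    lipid_shift <- c(log(2.5), log(1.5))[seq_len(min(2L, n_lipids))]
    names(lipid_shift) <- intersect(c("TG", "MUFA_ratio"), lipid_ids)[
      seq_along(lipid_shift)]
    lipid_shift <- lipid_shift[!is.na(names(lipid_shift))]
  }
  if (length(lipid_shift) > 0L && !all(names(lipid_shift) %in% lipid_ids)) {
    stop("lipid_shift names must be lipid variable ids")
  }

  if (is.null(latent_loading)) {
    latent_loading <- stats::setNames(rep(0.2, length(variable_ids)), variable_ids)
    latent_loading[gene_ids[induced_cluster]] <- 0.6
    latent_loading[lipid_ids] <- 0.3
    latent_loading[intersect(c("TG", "MUFA_ratio"), lipid_ids)] <- 0.6
  } else if (length(latent_loading) == 1L && is.null(names(latent_loading))) {
    latent_loading <- stats::setNames(rep(latent_loading, length(variable_ids)),
                                      variable_ids)
  } else if (!all(variable_ids %in% names(latent_loading))) {
    stop("latent_loading must cover every variable")
  }
  latent_loading <- latent_loading[variable_ids]

  planted_vars <- character()
  for (e in planted_edges) {
    if (!all(c("pair", "rho_ref", "rho_perturbed", "group") %in% names(e))) {
      stop("each planted edge needs pair, rho_ref, rho_perturbed, group")
    }
    if (!all(e$pair %in% variable_ids)) {
      stop("planted pair references nonexistent variable: ",
           paste(setdiff(e$pair, variable_ids), collapse = ", "))
    }
    if (abs(e$rho_ref) >= 1 || abs(e$rho_perturbed) >= 1) {
      stop("infeasible correlation target: |rho| must be < 1")
    }
    if (any(e$pair %in% planted_vars)) {
      stop("a variable may appear in at most one planted edge: ",
           paste(intersect(e$pair, planted_vars), collapse = ", "))
    }
    planted_vars <- c(planted_vars, e$pair)
  }

  structure(list(
    n_per_group = as.integer(n_per_group),
    n_genes = as.integer(n_genes), n_lipids = as.integer(n_lipids),
    genotype_levels = genotype_levels, treatment_levels = treatment_levels,
    gene_ids = gene_ids, lipid_ids = lipid_ids, variable_ids = variable_ids,
    induced_cluster = as.integer(induced_cluster), delta_up = delta_up,
    repressed_genes = as.integer(repressed_genes), delta_down = delta_down,
    lipid_shift = lipid_shift, latent_loading = latent_loading,
    planted_edges = planted_edges, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "study_config")
}

default_lipid_ids <- function(n_lipids) {
  base <- c("TG", "chol", "chol_ester", "MUFA_ratio")
  if (n_lipids <= length(base)) base[seq_len(n_lipids)]
  else c(base, sprintf("lipid_%02d", seq_len(n_lipids - length(base))))
}

# Spearman target -> Pearson correlation of the underlying bivariate normal
pearson_for_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic study
#'
#' Draws one complete study under the configured generative model: a
#' samples-by-variables table of strictly positive values, the factorial
#' design (reference = untreated first genotype), and a truth record
#' sufficient to score downstream edge detection.
#'
#' Randomness comes from one generator stream seeded with `config$seed`;
#' the stream order is: latent factor draws for all samples, then per
#' planted edge one shared component and two independent filler components,
#' then the residual noise matrix. Identical seeds give bit-identical
#' output.
#'
#' @param config A [study_config()].
#' @return List with elements `table` ([omics_table()]), `design`
#'   ([group_design()]) and `truth` (list: `induced_cell`, `mean_shifts`
#'   data.frame, `planted_edges` data.frame with canonical `pair` keys and
#'   per-group Spearman targets, and the full config echo).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  design_df <- design_frame(config)
  n <- nrow(design_df)
  p <- length(config$variable_ids)
  group <- paste(design_df$genotype, design_df$treatment, sep = ":")
  induced_cell <- paste(config$genotype_levels[1L], config$treatment_levels[2L],
                        sep = ":")

  # group means on the log scale
  mu <- matrix(0, nrow = n, ncol = p,
               dimnames = list(design_df$sample_id, config$variable_ids))
  in_cell <- group == induced_cell
  mu[in_cell, config$gene_ids[config$induced_cluster]] <- config$delta_up
  mu[in_cell, config$gene_ids[config$repressed_genes]] <- -config$delta_down
  for (lip in names(config$lipid_shift)) {
    mu[in_cell, lip] <- config$lipid_shift[[lip]]
  }

  lambda <- config$latent_loading
  planted_vars <- unlist(lapply(config$planted_edges, `[[`, "pair"))
  lambda[planted_vars] <- 0  # planted pairs get their own shared component

  f <- stats::rnorm(n)
  logx <- mu + outer(f, lambda)

  sigma2 <- config$noise_sd^2
  for (e in config$planted_edges) {
    u <- stats::rnorm(n)
    v1 <- stats::rnorm(n)
    v2 <- stats::rnorm(n)
    rho <- ifelse(group == e$group, e$rho_perturbed, e$rho_ref)
    r <- pearson_for_spearman(rho)
    # constant marginal variance v across groups, so a gain/loss changes the
    # pair's dependence without moving the variable's own distribution:
    # coupling a_g^2 = |r_g| v, independent filler b_g^2 = v(1-|r_g|) - sigma^2
    r_max <- max(abs(pearson_for_spearman(c(e$rho_ref, e$rho_perturbed))))
    v <- sigma2 / (1 - r_max)
    a <- sqrt(abs(r) * v)
    b <- sqrt(pmax(v * (1 - abs(r)) - sigma2, 0))
    logx[, e$pair[1L]] <- logx[, e$pair[1L]] + a * u + b * v1
    logx[, e$pair[2L]] <- logx[, e$pair[2L]] + sign(r) * a * u + b * v2
  }

  logx <- logx + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  kind <- stats::setNames(
    c(rep("mRNA", config$n_genes), rep("lipid", config$n_lipids)),
    config$variable_ids)
  table <- omics_table(exp(logx), kind)
  design <- group_design(design_df,
                         paste(config$genotype_levels[1L],
                               config$treatment_levels[1L], sep = ":"))

  shift_vars <- c(config$gene_ids[config$induced_cluster],
                  config$gene_ids[config$repressed_genes],
                  names(config$lipid_shift))
  mean_shifts <- data.frame(
    variable = shift_vars,
    group = rep(induced_cell, length(shift_vars)),
    log_shift = c(rep(config$delta_up, length(config$induced_cluster)),
                  rep(-config$delta_down, length(config$repressed_genes)),
                  unname(config$lipid_shift)),
    stringsAsFactors = FALSE)
  planted <- if (length(config$planted_edges) > 0L) {
    do.call(rbind, lapply(config$planted_edges, function(e) {
      data.frame(pair = pair_key(e$pair[1L], e$pair[2L]),
                 var_a = sort(e$pair)[1L], var_b = sort(e$pair)[2L],
                 rho_ref = e$rho_ref, rho_perturbed = e$rho_perturbed,
                 group = e$group, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(pair = character(), var_a = character(), var_b = character(),
               rho_ref = numeric(), rho_perturbed = numeric(),
               group = character(), stringsAsFactors = FALSE)
  }
  truth <- list(induced_cell = induced_cell, mean_shifts = mean_shifts,
                planted_edges = planted, config = unclass(config))
  list(table = table, design = design, truth = truth)
}

design_frame <- function(config) {
  rows <- list()
  for (g in config$genotype_levels) {
    for (t in config$treatment_levels) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_%d", g, t, seq_len(config$n_per_group)),
        genotype = g, treatment = t, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic qPCR Ct table
#'
#' Builds cycle-threshold (Ct) values whose delta-delta-Ct analysis recovers
#' the supplied expression levels: for target \eqn{t} and sample \eqn{s},
#' \eqn{Ct_{t,s} = Ct_{hk,s} + B_t - \log_2 E_{t,s}} plus optional Gaussian
#' cycle noise, where \eqn{Ct_{hk,s}} is the housekeeping Ct and \eqn{B_t} a
#' per-target base offset. With `noise_sd = 0`, [ddct_fold_changes()]
#' recovers each sample's expression relative to the reference-group
#' geometric mean exactly.
#'
#' @param config A [study_config()] (supplies the design and the seed).
#' @param true_fold_changes Either a samples-by-genes numeric matrix of
#'   strictly positive expression levels (row names = sample ids of the
#'   config's design, column names = target ids), or a single named vector
#'   giving one fold change per gene applied to every sample of the induced
#'   cell (all other samples at 1).
#' @param housekeeping Housekeeping target id (default `"Tbp"`, the TATA-box
#'   binding protein transcript conventionally used for liver panels).
#' @param noise_sd Standard deviation of Gaussian cycle noise added to every
#'   Ct (default 0: noise-free, exactly invertible).
#' @param base_ct Housekeeping Ct level (cycles, default 20).
#' @param base_offset Per-target offset above housekeeping (default 5 for
#'   every target, i.e. targets around Ct 25).
#' @return List of class `ct_table`: `ct` (samples x targets matrix of Ct
#'   values including the housekeeping column), `housekeeping`, `design`.
#' @export
generate_ct_table <- function(config, true_fold_changes,
                              housekeeping = "Tbp", noise_sd = 0,
                              base_ct = 20, base_offset = 5) {
  stopifnot(inherits(config, "study_config"))
  design_df <- design_frame(config)
  sample_ids <- design_df$sample_id
  if (is.matrix(true_fold_changes)) {
    expr <- true_fold_changes
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      stop("fold-change matrix needs sample row names and target column names")
    }
    if (!setequal(rownames(expr), sample_ids)) {
      stop("fold-change matrix rows must match the config's sample ids")
    }
    expr <- expr[sample_ids, , drop = FALSE]
  } else {
    if (is.null(names(true_fold_changes))) stop("fold-change vector must be named")
    induced_cell <- paste(config$genotype_levels[1L], config$treatment_levels[2L],
                          sep = ":")
    in_cell <- paste(design_df$genotype, design_df$treatment, sep = ":") ==
      induced_cell
    expr <- matrix(1, nrow = length(sample_ids),
                   ncol = length(true_fold_changes),
                   dimnames = list(sample_ids, names(true_fold_changes)))
    expr[in_cell, ] <- matrix(true_fold_changes, nrow = sum(in_cell),
                              ncol = length(true_fold_changes), byrow = TRUE)
  }
  if (any(expr <= 0)) stop("fold changes must be strictly positive")
  if (housekeeping %in% colnames(expr)) {
    stop("housekeeping id clashes with a target id")
  }
  set.seed(config$seed)
  n <- length(sample_ids)
  hk <- rep(base_ct, n) + stats::rnorm(n, sd = noise_sd)
  ct <- matrix(NA_real_, nrow = n, ncol = ncol(expr) + 1L,
               dimnames = list(sample_ids, c(colnames(expr), housekeeping)))
  ct[, housekeeping] <- hk
  offs <- rep_len(base_offset, ncol(expr))
  for (j in seq_len(ncol(expr))) {
    ct[, j] <- hk + offs[j] - log2(expr[, j]) + stats::rnorm(n, sd = noise_sd)
  }
  design <- group_design(design_df,
                         paste(config$genotype_levels[1L],
                               config$treatment_levels[1L], sep = ":"))
  structure(list(ct = ct, housekeeping = housekeeping, design = design),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d samples x %d targets (housekeeping %s)\n",
              nrow(x$ct), ncol(x$ct) - 1L, x$housekeeping))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `data.tsv`, `design.tsv`, `annotation.tsv` and `truth.json` into a
#' directory, the on-disk interface consumed by [read_omics_table()] and
#' [read_group_design()].
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_omics_table(study$table, file.path(dir, "data.tsv"),
                    file.path(dir, "annotation.tsv"))
  write_group_design(study$design, file.path(dir, "design.tsv"))
  truth <- study$truth
  truth$config$latent_loading <- as.list(truth$config$latent_loading)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
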