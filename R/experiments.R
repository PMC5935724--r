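#' Planted-edge recovery experiment
#'
#' The pipeline's power calibration: replicate synthetic studies in the
#' default layout (four groups of `n_per_group` samples, `n_genes` +
#' `n_lipids` variables) carrying one planted lipid-gene loss edge in the
#' treated wild-type cell, run the full network analysis on each, and
#' measure how often the planted edge is selected in that cell versus the
#' mean selection rate of the unplanted ("null") lipid-touching pairs.
#'
#' The groups follow the reference generative law except for the planted
#' edge — no mean shifts — so the experiment isolates detection of a pure
#' correlation change. Replicates share their seed sequence across effect
#' sizes (common random numbers), which stabilizes the comparison of
#' detection rates across the effect-size grid.
#'
#' @param n_rep Replicates per effect size (default 200).
#' @param delta_rho Effect sizes: the drop from `rho_ref` to the perturbed
#'   correlation (default `c(0.3, 0.6, 0.9)`).
#' @param rho_ref Reference-group Spearman target of the planted pair
#'   (default 0.9).
#' @param n_per_group,n_genes,n_lipids Study layout (defaults 5, 74, 4).
#' @param alpha Edge-selection level (default 0.05).
#' @param seed Base seed; replicate `i` uses `seed * 10^6 + i`.
#' @return data.frame with one row per effect size: `delta_rho`,
#'   `planted_rate`, `null_rate`, `n_rep`.
#' @export
planted_recovery_experiment <- function(n_rep = 200,
                                        delta_rho = c(0.3, 0.6, 0.9),
                                        rho_ref = 0.9,
                                        n_per_group = 5, n_genes = 74,
                                        n_lipids = 4, alpha = 0.05,
                                        seed = 1) {
  pair <- c("gene_10", "TG")
  key <- pair_key(pair[1L], pair[2L])
  group <- "WT:T09"
  out <- lapply(delta_rho, function(dr) {
    hits <- 0L
    null_rates <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      cfg <- study_config(
        n_per_group = n_per_group, n_genes = n_genes, n_lipids = n_lipids,
        induced_cluster = integer(0), repressed_genes = integer(0),
        lipid_shift = numeric(0),
        planted_edges = list(list(pair = pair, rho_ref = rho_ref,
                                  rho_perturbed = rho_ref - dr,
                                  group = group)),
        seed = as.integer(seed * 1e6 + i))
      st <- generate_study(cfg)
      res <- run_ssn(st$table, st$design, alpha = alpha)
      nw <- res$networks[[group]]
      hits <- hits + (key %in% nw$edges$pair)
      kind <- st$table$variable_kind
      lip <- kind[nw$stats$var_a] == "lipid" | kind[nw$stats$var_b] == "lipid"
      null_pairs <- nw$stats$pair[lip & nw$stats$pair != key]
      null_rates[i] <- mean(null_pairs %in% nw$edges$pair)
    }
    data.frame(delta_rho = dr, planted_rate = hits / n_rep,
               null_rate = mean(null_rates), n_rep = n_rep)
  })
  do.call(rbind, out)
}

#' Bland-Altman coverage experiment
#'
#' Checks the nominal 95% coverage of the limits of agreement: in each
#' replicate, paired measurements are constructed so their relative
#' differences are i.i.d. normal, [bland_altman()] is run, and the fraction
#' of points inside the limits is recorded. With a fixed 1.96 multiplier
#' and large n the mean inside-fraction is close to 0.95.
#'
#' @param n_points Pairs per replicate (default 1000).
#' @param n_rep Replicates (default 100).
#' @param sd Standard deviation of the relative differences (default 0.1;
#'   must be small enough that `1 + d/2 > 0`).
#' @param seed Base seed; replicate `i` uses `seed * 10^6 + i`.
#' @return List: `coverage` (mean inside-fraction), `per_replicate`.
#' @export
bland_altman_coverage <- function(n_points = 1000, n_rep = 100, sd = 0.1,
                                  seed = 1) {
  per_rep <- vapply(seq_len(n_rep), function(i) {
    set.seed(as.integer(seed * 1e6 + i))
    d <- stats::rnorm(n_points, sd = sd)
    # pairs around a unit average: (x - y)/((x + y)/2) = d exactly
    ba <- bland_altman(1 + d / 2, 1 - d / 2)
    1 - ba$n_outside / ba$n
  }, numeric(1))
  list(coverage = mean(per_rep), per_replicate = per_rep)
}
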