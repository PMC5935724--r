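test_that("default study has the factorial layout and is seed-reproducible", {
  st1 <- generate_study(study_config(seed = 1))
  st2 <- generate_study(study_config(seed = 1))
  expect_equal(dim(st1$table), c(20L, 78L))
  expect_identical(st1$table$values, st2$table$values)
  expect_true(all(st1$table$values > 0))
  expect_equal(sum(st1$table$variable_kind == "lipid"), 4L)

  sizes <- table(st1$design$samples$group)
  expect_equal(length(sizes), 4L)
  expect_true(all(sizes == 5L))

  st3 <- generate_study(study_config(seed = 2))
  expect_false(identical(st1$table$values, st3$table$values))
})

test_that("config validation rejects infeasible structure", {
  expect_error(study_config(n_per_group = 2), "n_per_group")
  expect_error(study_config(induced_cluster = 1:80), "exceed n_genes")
  expect_error(study_config(planted_edges = list(
    list(pair = c("gene_01", "nope"), rho_ref = 0.5, rho_perturbed = 0,
         group = "WT:T09"))), "nonexistent variable")
  expect_error(study_config(planted_edges = list(
    list(pair = c("gene_01", "TG"), rho_ref = 1, rho_perturbed = 0,
         group = "WT:T09"))), "infeasible correlation")
  expect_error(study_config(planted_edges = list(
    list(pair = c("gene_01", "TG"), rho_ref = 0.5, rho_perturbed = 0,
         group = "WT:T09"),
    list(pair = c("gene_01", "chol"), rho_ref = 0.5, rho_perturbed = 0,
         group = "WT:T09"))), "at most one planted edge")
})

test_that("planted gain/loss edges reach their Spearman targets at large n", {
  cfg <- study_config(
    n_per_group = 200, n_genes = 10, n_lipids = 2,
    induced_cluster = 1:2, repressed_genes = 3L,
    planted_edges = list(
      list(pair = c("gene_05", "TG"), rho_ref = 0.9, rho_perturbed = 0,
           group = "WT:T09"),
      list(pair = c("gene_06", "chol"), rho_ref = -0.6, rho_perturbed = 0.4,
           group = "KO:T09")),
    seed = 11)
  st <- generate_study(cfg)
  sp <- function(group, a, b) {
    ids <- group_samples(st$design, group)
    stats::cor(st$table$values[ids, a], st$table$values[ids, b],
               method = "spearman")
  }
  expect_lt(abs(sp("WT:vehicle", "gene_05", "TG") - 0.9), 0.1)
  expect_lt(abs(sp("WT:T09", "gene_05", "TG") - 0), 0.1)
  expect_lt(abs(sp("KO:vehicle", "gene_06", "chol") - (-0.6)), 0.1)
  expect_lt(abs(sp("KO:T09", "gene_06", "chol") - 0.4), 0.1)
})

test_that("planted mean shifts converge to configured effects at large n", {
  cfg <- study_config(n_per_group = 400, n_genes = 6, n_lipids = 2,
                      induced_cluster = 1:2, delta_up = log(4),
                      repressed_genes = 3L, delta_down = log(2), seed = 5)
  st <- generate_study(cfg)
  cell <- function(g) group_samples(st$design, g)
  lm_up <- mean(log(st$table$values[cell("WT:T09"), "gene_01"])) -
    mean(log(st$table$values[cell("WT:vehicle"), "gene_01"]))
  lm_down <- mean(log(st$table$values[cell("WT:T09"), "gene_03"])) -
    mean(log(st$table$values[cell("WT:vehicle"), "gene_03"]))
  lm_other <- mean(log(st$table$values[cell("KO:T09"), "gene_01"])) -
    mean(log(st$table$values[cell("KO:vehicle"), "gene_01"]))
  # s.e. of a log-mean difference here is ~ sqrt(2 * (0.6^2+0.3^2) / 400) < 0.05
  expect_lt(abs(lm_up - log(4)), 0.15)
  expect_lt(abs(lm_down + log(2)), 0.15)
  expect_lt(abs(lm_other), 0.15)
})

test_that("truth record addresses planted structure by canonical pair", {
  cfg <- study_config(planted_edges = list(
    list(pair = c("TG", "gene_10"), rho_ref = 0.9, rho_perturbed = 0,
         group = "WT:T09")), seed = 2)
  st <- generate_study(cfg)
  expect_equal(st$truth$planted_edges$pair, pair_key("gene_10", "TG"))
  expect_equal(st$truth$induced_cell, "WT:T09")
  expect_true(all(c("gene_01", "TG") %in% st$truth$mean_shifts$variable))

  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("data.tsv", "design.tsv", "annotation.tsv", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$induced_cell, "WT:T09")
})

test_that("noise-free Ct tables invert exactly through ddct_fold_changes", {
  cfg <- study_config(n_genes = 3, induced_cluster = 1L,
                      repressed_genes = integer(0), seed = 9)
  ct <- generate_ct_table(cfg, c(gene_01 = 4, gene_02 = 1, gene_03 = 0.25),
                          noise_sd = 0)
  folds <- ddct_fold_changes(ct)
  in_cell <- group_samples(ct$design, "WT:T09")
  ref <- group_samples(ct$design)
  expect_equal(unname(folds[in_cell, "gene_01"]), rep(4, 5))
  expect_equal(unname(folds[in_cell, "gene_02"]), rep(1, 5))
  expect_equal(unname(folds[in_cell, "gene_03"]), rep(0.25, 5))
  expect_equal(unname(folds[ref, ]), matrix(1, 5, 3))
  expect_error(generate_ct_table(cfg, c(gene_01 = -1)), "strictly positive")
})

test_that("noisy Ct recovery is unbiased on the log2 scale", {
  cfg <- study_config(n_per_group = 500, n_genes = 1, induced_cluster = 1L,
                      repressed_genes = integer(0), seed = 13)
  ct <- generate_ct_table(cfg, c(gene_01 = 4), noise_sd = 0.2)
  folds <- ddct_fold_changes(ct)
  in_cell <- group_samples(ct$design, "WT:T09")
  m <- mean(log2(folds[in_cell, "gene_01"]))
  # cycle noise sd 0.2 on target and housekeeping -> se ~ sqrt(2)*0.2/sqrt(500)
  expect_lt(abs(m - 2), 4 * sqrt(2) * 0.2 / sqrt(500) + 0.02)
})
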