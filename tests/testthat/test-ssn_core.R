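test_that("Spearman correlation follows the rank formula", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  vals <- cbind(x = x, y = y)
  rownames(vals) <- sprintf("s%d", 1:5)
  m <- correlation_matrix(vals)
  expect_equal(m["x", "y"], 0.8)           # 1 - 6*4 / (5*24)
  expect_equal(diag(m), c(x = 1, y = 1))
  dec <- matrix(c(x, rev(x)), ncol = 2,
                dimnames = list(sprintf("s%d", 1:5), c("a", "b")))
  expect_equal(correlation_matrix(dec)["a", "b"], -1)
})

test_that("correlation_matrix enforces its preconditions", {
  vals <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(correlation_matrix(vals[1:2, ]), "at least 3 samples")
  vals[, 2] <- 7
  expect_error(correlation_matrix(vals), "constant variable.*b")
})

test_that("delta_scc matches the add-one rank computation", {
  ref <- cbind(x = 1:5, y = c(2, 1, 4, 3, 5))
  rownames(ref) <- sprintf("s%d", 1:5)
  d <- delta_scc(ref, c(6, 6))
  # SCCref = 0.8; SCCref+1 = 1 - 6*4/(6*35) = 0.885714...
  expect_equal(d["x", "y"], 1 - 24 / 210 - 0.8, tolerance = 1e-12)
  expect_equal(diag(d), c(x = 0, y = 0))

  # a sample concordant with a perfect monotone pair perturbs nothing
  ref2 <- cbind(x = 1:5, y = (1:5)^2)
  rownames(ref2) <- sprintf("s%d", 1:5)
  d2 <- delta_scc(ref2, c(6, 36))
  expect_equal(d2["x", "y"], 0)

  expect_error(delta_scc(ref, c(1, NA)), "non-finite")
  expect_error(delta_scc(ref, 1), "one value per variable")
})

test_that("SCC and delta-SCC agree with the independent mid-rank oracle", {
  set.seed(314)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    p <- sample(3:12, 1)
    vals <- random_table(n, p, ties = rep %% 2 == 0)
    expect_lt(max(abs(correlation_matrix(vals) - oracle_spearman_matrix(vals))),
              1e-12)
    extra <- random_table(1, p, ties = rep %% 3 == 0)
    d_pkg <- delta_scc(vals, extra[1, ])
    d_or <- oracle_spearman_matrix(rbind(vals, extra)) -
      oracle_spearman_matrix(vals)
    expect_lt(max(abs(d_pkg - d_or)), 1e-12)
  }
})

test_that("group median is the entry-wise order statistic over samples", {
  set.seed(99)
  ref <- random_table(6, 4)
  grp <- random_table(5, 4)
  gmd <- group_median_delta(ref, grp)
  expect_equal(dim(gmd$per_sample), c(4L, 4L, 5L))
  # brute-force sort-and-pick per entry
  for (i in 1:4) for (j in 1:4) {
    v <- unname(sort(gmd$per_sample[i, j, ]))
    expect_equal(gmd$median_delta[i, j], v[3])
  }
  # even group size: mean of the two central values
  gmd4 <- group_median_delta(ref, grp[1:4, ])
  v <- unname(sort(gmd4$per_sample[1, 2, ]))
  expect_equal(gmd4$median_delta[1, 2], mean(v[2:3]))
  # identical matrices -> median equals each
  grp_same <- grp[rep(1, 5), ]
  rownames(grp_same) <- paste0("r", 1:5)
  gmd_same <- group_median_delta(ref, grp_same)
  expect_equal(gmd_same$median_delta, gmd_same$per_sample[, , 1])
})

test_that("pair z-scores match the worked example and standardize exactly", {
  zs <- pair_zscores(c(0.3, 0.1, -0.2, 0.2))
  # mean 0.1, sample s.d. 0.21602...; z for 0.3 = 0.2/0.216025 = 0.92582
  expect_equal(zs$z[1], 0.2 / stats::sd(c(0.3, 0.1, -0.2, 0.2)))
  expect_equal(zs$z[1], 0.92582, tolerance = 1e-4)
  expect_equal(zs$p[1], 2 * (1 - stats::pnorm(0.92582)), tolerance = 1e-4)
  expect_equal(zs$p[1], 0.3546, tolerance = 1e-3)
  # a pair equal to the mean scores z = 0, p = 1
  zs2 <- pair_zscores(c(0.1, 0.1, -0.2, 0.4))
  expect_equal(zs2$z[1], 0)
  expect_equal(zs2$p[1], 1)

  set.seed(44)
  v <- rnorm(100)
  zs3 <- pair_zscores(v)
  expect_lt(abs(mean(zs3$z)), 1e-12)
  expect_lt(abs(stats::sd(zs3$z) - 1), 1e-12)
  expect_error(pair_zscores(rep(0.2, 10)), "degenerate")
})

test_that("edge selection filters, annotates and orders edges", {
  md <- matrix(0, 4, 4, dimnames = list(c("g1", "g2", "TG", "chol"),
                                        c("g1", "g2", "TG", "chol")))
  md[upper.tri(md)] <- c(0.3, 0.1, -0.2, 0.2, 0.05, -0.3)
  md <- md + t(md)
  stats_df <- edge_significance(md)
  kind <- c(g1 = "mRNA", g2 = "mRNA", TG = "lipid", chol = "lipid")

  all_sel <- select_edges(stats_df, kind, alpha = 1 + 1e-9, lipid_only = FALSE)
  expect_equal(nrow(all_sel), 6L)
  expect_true(all(diff(all_sel$p) >= 0))
  expect_equal(all_sel$direction, ifelse(all_sel$median_delta > 0, "gain", "loss"))

  lipid_sel <- select_edges(stats_df, kind, alpha = 1 + 1e-9, lipid_only = TRUE)
  expect_true(all(lipid_sel$involves_lipid))
  expect_equal(nrow(lipid_sel), 5L)  # only g1-g2 is gene-gene

  expect_equal(nrow(select_edges(stats_df, kind, alpha = 0)), 0L)

  mid <- select_edges(stats_df, kind, alpha = 0.5, lipid_only = FALSE)
  expect_setequal(mid$pair, stats_df$pair[stats_df$p < 0.5])

  bh <- select_edges(stats_df, kind, alpha = 0.9, lipid_only = FALSE,
                     adjust = "BH")
  expect_equal(bh$p_adj, stats::p.adjust(stats_df$p, "BH")[
    match(bh$pair, stats_df$pair)])
})

test_that("run_ssn produces one network per non-reference group", {
  st <- tiny_study(seed = 8)
  res <- run_ssn(st$table, st$design)
  expect_s3_class(res, "ssn_result")
  expect_equal(length(res$networks), 3L)
  expect_setequal(names(res$networks), c("WT:T09", "KO:vehicle", "KO:T09"))
  expect_equal(res$method, "spearman")
  for (nw in res$networks) {
    expect_equal(nrow(nw$stats), choose(10, 2))
    expect_lt(abs(mean(nw$stats$z)), 1e-12)
    expect_lt(abs(stats::sd(nw$stats$z) - 1), 1e-12)
    if (nrow(nw$edges) > 0) expect_true(all(nw$edges$involves_lipid))
    expect_true(all(abs(nw$median_delta) <= 2 + 1e-15))
  }
})

test_that("run_ssn refuses reference constants but tolerates group constants", {
  st <- tiny_study(seed = 15)
  ref <- group_samples(st$design)
  vals2 <- st$table$values
  vals2[ref, "gene_03"] <- 2
  tab2 <- omics_table(vals2, st$table$variable_kind)
  expect_error(run_ssn(tab2, st$design), "reference group.*gene_03")

  # constant within a perturbed group is fine: each sample is added to the
  # (non-constant) reference individually, so the rank correlation exists
  vals <- st$table$values
  ids <- group_samples(st$design, "KO:T09")
  vals[ids, "gene_02"] <- 1.25
  tab <- omics_table(vals, st$table$variable_kind)
  res <- run_ssn(tab, st$design)
  expect_equal(length(res$networks), 3L)
})

test_that("run_ssn is invariant to strictly increasing per-variable maps", {
  st <- tiny_study(seed = 23)
  res0 <- run_ssn(st$table, st$design)
  set.seed(77)
  for (rep in 1:3) {
    a <- runif(ncol(st$table$values), 0.5, 2)
    b <- runif(ncol(st$table$values), 0.5, 2)
    vals <- sweep(sweep(st$table$values, 2, a, `^`), 2, b, `*`)
    res1 <- run_ssn(omics_table(vals, st$table$variable_kind), st$design)
    for (g in names(res0$networks)) {
      expect_identical(res0$networks[[g]]$stats$z, res1$networks[[g]]$stats$z)
      expect_identical(res0$networks[[g]]$stats$p, res1$networks[[g]]$stats$p)
      expect_identical(res0$networks[[g]]$edges$pair, res1$networks[[g]]$edges$pair)
    }
  }
})

test_that("a planted loss edge scores systematically negative z in its group", {
  key <- pair_key("gene_10", "TG")
  planted_z <- numeric(0)
  null_z <- numeric(0)
  for (i in 1:40) {
    cfg <- study_config(
      n_genes = 20, n_lipids = 2,
      induced_cluster = integer(0), repressed_genes = integer(0),
      lipid_shift = numeric(0),
      planted_edges = list(list(pair = c("gene_10", "TG"), rho_ref = 0.9,
                                rho_perturbed = 0, group = "WT:T09")),
      seed = 5000 + i)
    st <- generate_study(cfg)
    res <- run_ssn(st$table, st$design)
    nw <- res$networks[["WT:T09"]]
    planted_z <- c(planted_z, nw$stats$z[nw$stats$pair == key])
    kind <- st$table$variable_kind
    lip <- kind[nw$stats$var_a] == "lipid" | kind[nw$stats$var_b] == "lipid"
    null_z <- c(null_z, mean(nw$stats$z[lip & nw$stats$pair != key]))
  }
  # loss of correlation shows as negative z; unplanted lipid edges center on 0
  expect_lt(mean(planted_z), -0.3)
  expect_lt(abs(mean(null_z)), 0.15)
  expect_lt(mean(planted_z), mean(null_z) - 0.3)
})
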