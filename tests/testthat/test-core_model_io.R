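test_that("omics_table validates dimensions, ids and finiteness", {
  vals <- matrix(1:12 / 2, nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c", "d")))
  kind <- c(a = "mRNA", b = "mRNA", c = "lipid", d = "lipid")
  tab <- omics_table(vals, kind)
  expect_s3_class(tab, "omics_table")
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(tab$variable_kind, kind)

  vals_na <- vals; vals_na[2, 3] <- NA
  expect_error(omics_table(vals_na, kind), "s2.*c")
  expect_error(omics_table(vals, kind[-1]), "missing from annotation.*a")
  expect_error(omics_table(vals, c(kind, e = "lipid")), "absent from data.*e")
  expect_error(omics_table(vals, replace(kind, 1, "protein")), "unknown variable kind")
  dup <- vals; rownames(dup) <- c("s1", "s1", "s3")
  expect_error(omics_table(dup, kind), "duplicated sample ids")
})

test_that("TSV round trip reproduces values bit-exactly", {
  set.seed(7)
  st <- tiny_study(seed = 7)
  dir <- withr::local_tempdir()
  write_omics_table(st$table, file.path(dir, "data.tsv"),
                    file.path(dir, "annotation.tsv"))
  back <- read_omics_table(file.path(dir, "data.tsv"),
                           file.path(dir, "annotation.tsv"))
  expect_identical(back$values, st$table$values)
  expect_identical(back$variable_kind, st$table$variable_kind)

  write_group_design(st$design, file.path(dir, "design.tsv"))
  dback <- read_group_design(file.path(dir, "design.tsv"), "WT:vehicle")
  expect_identical(dback$samples, st$design$samples)
})

test_that("read_omics_table rejects malformed input naming the cell", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tg1\tg2", "s1\t1.5\t2.0", "s2\tNA\t3.0"),
             file.path(dir, "bad.tsv"))
  writeLines(c("variable_id\tkind", "g1\tmRNA", "g2\tmRNA"),
             file.path(dir, "ann.tsv"))
  expect_error(read_omics_table(file.path(dir, "bad.tsv"),
                                file.path(dir, "ann.tsv")),
               "non-numeric cell 'NA'.*'s2'.*'g1'")

  writeLines(c("sample_id\tg1\tg2", "s1\t1.5\t2.0", "s2\t1\t3.0"),
             file.path(dir, "ok.tsv"))
  writeLines(c("variable_id\tkind", "g1\tmRNA"), file.path(dir, "ann1.tsv"))
  expect_error(read_omics_table(file.path(dir, "ok.tsv"),
                                file.path(dir, "ann1.tsv")),
               "missing from annotation.*g2")
})

test_that("group_design resolves the reference cell and flags bad input", {
  df <- data.frame(sample_id = sprintf("m%d", 1:12),
                   genotype = rep(c("WT", "KO"), each = 6),
                   treatment = rep(c("vehicle", "T09"), 6))
  d <- group_design(df, "WT:vehicle")
  expect_equal(sort(group_samples(d)), c("m1", "m3", "m5"))
  expect_equal(length(group_labels(d)), 4L)
  expect_equal(group_labels(d)[1], "WT:vehicle")

  expect_error(group_design(df, "WT:foo"), "reference group empty")
  expect_error(group_design(rbind(df, df[1, ]), "WT:vehicle"), "duplicated sample_id")
  df_bad <- df; df_bad$treatment[3] <- ""
  expect_error(group_design(df_bad, "WT:vehicle"), "missing factor level.*m3")
})

test_that("small cells trigger the group-size warning contract", {
  df <- data.frame(sample_id = c("a", "b", "c", "d"),
                   genotype = c("WT", "WT", "WT", "KO"),
                   treatment = c("v", "v", "v", "v"))
  expect_warning(group_design(df, "WT:v"), "fewer than 3 samples.*KO:v")
})

test_that("pair keys are canonical and all_pairs covers the upper triangle", {
  expect_identical(pair_key("TG", "gene_03"), pair_key("gene_03", "TG"))
  expect_error(pair_key("x", "x"), "paired with itself")
  ids <- c("b", "a", "c")
  pp <- all_pairs(ids)
  expect_equal(nrow(pp), 3L)
  expect_true(all(pp$var_a < pp$var_b))
  expect_setequal(pp$pair, c("a|b", "b|c", "a|c"))
})

test_that("validate_dataset reports group sizes, constants and fatal mismatches", {
  st <- tiny_study(seed = 3)
  rep0 <- validate_dataset(st$table, st$design)
  expect_equal(rep0$n_fatal, 0L)

  vals <- st$table$values
  ref_ids <- group_samples(st$design)
  vals[ref_ids, 1] <- 2.5  # constant within reference group
  tab2 <- omics_table(vals, st$table$variable_kind)
  rep1 <- validate_dataset(tab2, st$design)
  expect_true(any(grepl("constant within group WT:vehicle.*gene_01",
                        rep1$findings$message)))

  extra <- st$design$samples
  extra <- rbind(extra[, 1:3], data.frame(sample_id = "ghost", genotype = "WT",
                                          treatment = "vehicle"))
  d2 <- group_design(extra, "WT:vehicle")
  rep2 <- validate_dataset(st$table, d2)
  expect_gt(rep2$n_fatal, 0L)
  expect_error(run_ssn(st$table, d2), "validation failed")
})
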