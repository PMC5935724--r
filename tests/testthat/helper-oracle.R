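# Independent Spearman oracle: hand-written mid-ranks followed by the
# explicit Pearson sum formula. Shares no code path with the package
# (which goes through stats::cor).

oracle_midranks <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman_matrix <- function(values) {
  ranks <- apply(values, 2L, oracle_midranks)
  p <- ncol(values)
  m <- diag(1, p)
  dimnames(m) <- list(colnames(values), colnames(values))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      m[i, j] <- m[j, i] <- oracle_pearson(ranks[, i], ranks[, j])
    }
  }
  m
}

# random small table with optional ties (values drawn from a small grid);
# constant columns are resampled (correlation undefined on them)
random_table <- function(n, p, ties = FALSE) {
  draw <- function(m) {
    if (ties) matrix(sample(seq(0.5, 5, by = 0.5), n * m, replace = TRUE), n, m)
    else matrix(stats::rnorm(n * m), n, m)
  }
  vals <- draw(p)
  if (n > 1L) {
    repeat {
      const <- which(apply(vals, 2L, function(col) diff(range(col)) == 0))
      if (length(const) == 0L) break
      vals[, const] <- draw(length(const))
    }
  }
  dimnames(vals) <- list(sprintf("s%02d", seq_len(n)),
                         sprintf("v%02d", seq_len(p)))
  vals
}

# small omics table + 2x2 design used across module tests
tiny_study <- function(seed = 42, n_per_group = 5, n_genes = 8, n_lipids = 2) {
  generate_study(study_config(n_per_group = n_per_group, n_genes = n_genes,
                              n_lipids = n_lipids, induced_cluster = 1:3,
                              repressed_genes = 4L, seed = seed))
}
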