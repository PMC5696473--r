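test_that("normalized ranks follow the average-rank convention", {
  expect_equal(sort(normalized_ranks(c(0.2, 0.4, 0.1, 0.9))),
               c(0.25, 0.5, 0.75, 1.0))
  expect_equal(normalized_ranks(rep(0.5, 4)), rep(5 / 8, 4))
  p <- runif(10)
  expect_setequal(normalized_ranks(p), normalized_ranks(rev(p)))
})

test_that("gene scores follow the Beta order-statistic construction", {
  # no significant sgRNA: floor score of exactly 1
  expect_identical(arra_gene_score(c(0.3, 0.6), c(0.5, 0.9), p0 = 0.05),
                   1.0)
  # single-guide gene: Beta(1, 1) CDF is the identity
  expect_equal(arra_gene_score(0.01, 0.001, p0 = 0.05), 0.01)
  # two guides, both significant: min of 1-(1-r1)^2 and r2^2
  expect_equal(arra_gene_score(c(0.01, 0.02), c(0.001, 0.002), p0 = 0.05),
               0.0004)
  # order invariance
  expect_equal(arra_gene_score(c(0.02, 0.01), c(0.002, 0.001), p0 = 0.05),
               0.0004)
  # more corroborating guides at the smallest global ranks: stronger score
  n_tot <- 100
  scores <- vapply(1:4, function(k) {
    r <- (1:6) / n_tot
    p <- c(rep(0.01, k), rep(0.5, 6 - k))
    arra_gene_score(r, p, p0 = 0.05)
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("halving p0 never strengthens a gene score", {
  set.seed(90)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    r <- runif(n)
    p <- runif(n, 0, 0.2)
    expect_gte(arra_gene_score(r, p, p0 = 0.025),
               arra_gene_score(r, p, p0 = 0.05))
  }
})

test_that("the vectorized null scorer agrees with the per-gene scorer", {
  set.seed(91)
  sgrna <- tibble::tibble(
    sgrna_id = sprintf("sg%03d", 1:60),
    gene_id = rep(sprintf("g%02d", 1:10), each = 6),
    p_value = runif(60)^2
  )
  ranking <- arra_ranking(sgrna, p0 = 0.2, n_permutations = 5, seed = 4)
  r <- normalized_ranks(sgrna$p_value)
  manual <- vapply(split(seq_len(60), sgrna$gene_id), function(i)
    arra_gene_score(r[i], sgrna$p_value[i], p0 = 0.2), numeric(1))
  expect_equal(ranking$rho[match(names(manual), ranking$gene_id)],
               unname(manual))
})

test_that("permutation p-values replay a brute-force oracle", {
  set.seed(92)
  sgrna <- tibble::tibble(
    sgrna_id = sprintf("sg%d", 1:6),
    gene_id = rep(c("gA", "gB", "gC"), each = 2),
    p_value = c(0.001, 0.004, 0.3, 0.8, 0.5, 0.02)
  )
  Np <- 10
  ranking <- arra_ranking(sgrna, p0 = 0.05, n_permutations = Np, seed = 7)

  # oracle: replay the same seeded permutation stream with the scalar
  # scorer, pooling null scores across the (all size 2) genes
  r <- normalized_ranks(sgrna$p_value)
  p <- sgrna$p_value
  slots <- split(seq_len(6), sgrna$gene_id)
  set.seed(7)
  null <- c()
  for (b in seq_len(Np)) {
    perm <- sample.int(6)
    rp <- r[perm]; pp <- p[perm]
    null <- c(null, vapply(slots, function(i)
      arra_gene_score(rp[i], pp[i], 0.05), numeric(1)))
  }
  obs <- vapply(slots, function(i) arra_gene_score(r[i], p[i], 0.05),
                numeric(1))
  expected_perm_p <- vapply(obs, function(rho)
    (1 + sum(null <= rho)) / (1 + length(null)), numeric(1))
  got <- ranking$perm_p[match(names(obs), ranking$gene_id)]
  expect_equal(got, unname(expected_perm_p))

  # bit-for-bit reproducibility under the same seed
  again <- arra_ranking(sgrna, p0 = 0.05, n_permutations = Np, seed = 7)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(ranking))

  # a gene with rho = 1 cannot look rare under the null
  expect_gte(ranking$perm_p[ranking$gene_id == "gB"], 0.5)
})

test_that("the ranking sort is two-level with a deterministic tiebreak", {
  recs <- tibble::tibble(
    gene_id = c("gB", "gA", "gC", "gD"),
    fdr = c(0.20, 0.01, 0.01, 0.01),
    rho = c(0.5, 1e-2, 1e-5, 1e-2)
  )
  ranked <- rank_genes(recs)
  expect_equal(ranked$gene_id, c("gC", "gA", "gD", "gB"))
  expect_equal(ranked$rank, 1:4)
})

test_that("a uniformly spiked gene reaches rank 1 end to end", {
  lib <- simulate_library(50, 6, seed = 95)
  sim <- simulate_counts(lib, baseline_mean = 150, dispersion = 0.2,
                         n_controls = 2, n_treatments = 1,
                         spiked_genes = tibble::tibble(gene_id = "gene010",
                                                       fold = 20),
                         seed = 96)
  m <- sim$counts
  attr(m, "normalization") <- "cpm"
  model <- estimate_dispersion(m, c("control_1", "control_2"))
  res <- test_sample(m, "treatment_1", model, "enrichment")
  ranking <- arra_ranking(res, n_permutations = 200, seed = 97)
  expect_equal(ranking$gene_id[1], "gene010")
})
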