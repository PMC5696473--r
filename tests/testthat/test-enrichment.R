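make_control_matrix <- function(lib, cols) {
  m <- tibble::tibble(sgrna_id = lib$sgrna_id, gene_id = lib$gene_id)
  for (s in names(cols)) m[[s]] <- cols[[s]]
  attr(m, "normalization") <- "cpm"
  m
}

test_that("dispersion fitting recovers closed-form cases", {
  lib <- random_library(3, 1, seed = 40)
  # replicate pairs built so that sample variance equals the mean
  pois <- make_control_matrix(lib, list(
    c1 = c(1, 6, 15), c2 = c(3, 10, 21)))  # means 2, 8, 18; vars 2, 8, 18
  fit <- estimate_dispersion(pois)
  expect_equal(fit$D, 0)
  expect_equal(fit$sgrnas$model_var, fit$sgrnas$mu)

  # two sgRNAs on the curve sigma^2 - mu = mu^2 exactly: D = 1
  lib2 <- random_library(2, 1, seed = 41)
  d1 <- make_control_matrix(lib2, list(
    c1 = c(10 - sqrt(55), 100 - sqrt(5050)),
    c2 = c(10 + sqrt(55), 100 + sqrt(5050))))
  fit2 <- estimate_dispersion(d1)
  expect_equal(fit2$D, 1, tolerance = 1e-12)

  expect_error(estimate_dispersion(make_control_matrix(
    lib, list(c1 = c(1, 2, 3)))), "2 control")
})

test_that("dispersion is recovered from simulated NB screens", {
  lib <- simulate_library(334, 6, seed = 50)  # 2004 sgRNAs
  sim <- simulate_counts(lib, baseline_mean = 300, dispersion = 0.5,
                         n_controls = 4, n_treatments = 0, seed = 51)
  m <- sim$counts
  attr(m, "normalization") <- "cpm"  # counts already on a common scale
  fit <- estimate_dispersion(m)
  expect_gt(fit$D, 0.5 * 0.8)
  expect_lt(fit$D, 0.5 * 1.2)

  # scale consistency: doubling all counts leaves D stable
  m2 <- m
  for (s in c("control_1", "control_2", "control_3", "control_4")) {
    m2[[s]] <- 2 * m2[[s]]
  }
  fit2 <- estimate_dispersion(m2)
  expect_equal(fit2$D, fit$D, tolerance = 0.15)
})

test_that("NB tails match closed forms and exhaustive summation", {
  # Poisson limit
  expect_equal(nb_tail_pvalue(10, 5, 5, "enrichment"), 0.031828,
               tolerance = 1e-5)
  expect_equal(nb_tail_pvalue(0, 5, 5, "depletion"), exp(-5),
               tolerance = 1e-12)

  # P(X >= 0) = 1; enrichment at the mean keeps substantial tail mass
  expect_equal(nb_tail_pvalue(0, 5, 10, "enrichment"), 1)
  for (mu in c(1, 5, 20)) {
    expect_gte(nb_tail_pvalue(mu, mu, mu + 0.2 * mu^2, "enrichment"), 0.3)
  }

  set.seed(60)
  for (i in 1:40) {
    mu <- runif(1, 0.5, 50)
    D <- sample(c(0, runif(1, 0.05, 2)), 1)
    v <- mu + D * mu^2
    c <- runif(1, 0, 500)
    dir <- sample(c("enrichment", "depletion"), 1)
    expect_lt(abs(nb_tail_pvalue(c, mu, v, dir) -
                    nb_tail_oracle(c, mu, v, dir)), 1e-10)
  }
})

test_that("BH adjustment equals the textbook step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(61)
  for (i in 1:20) {
    p <- runif(sample(2:1000, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("treatment testing flags spiked sgRNAs and handles zeros", {
  lib <- simulate_library(167, 6, seed = 70)  # 1002 sgRNAs
  sim <- simulate_counts(lib, baseline_mean = 200, dispersion = 0.2,
                         n_controls = 3, n_treatments = 1,
                         spiked_genes = tibble::tibble(gene_id = "gene001",
                                                       fold = 50),
                         seed = 71)
  m <- sim$counts
  attr(m, "normalization") <- "cpm"
  model <- estimate_dispersion(m, paste0("control_", 1:3))
  res <- test_sample(m, "treatment_1", model, "enrichment")
  expect_equal(nrow(res), nrow(lib))
  spiked <- res$gene_id == "gene001"
  expect_lte(min(res$p_value[spiked]), min(res$p_value[!spiked]))
  expect_true(all(res$fold_change >= 0))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # c = mu for every sgRNA means fold-change exactly 1
  flat <- m
  flat$treatment_1 <- model$sgrnas$mu
  res_flat <- test_sample(flat, "treatment_1", model, "enrichment")
  expect_true(all(res_flat$fold_change == 1))

  # length mismatch is an error
  expect_error(test_sample(m[-1, ], "treatment_1", model, "enrichment"),
               "different sgRNAs")
})

test_that("single-control screens report fold-change only", {
  lib <- random_library(3, 1, seed = 80)
  m <- make_control_matrix(lib, list(ctrl = c(10, 0, 5),
                                     trt = c(20, 5, 0)))
  fc <- fold_change_only(m, "trt", "ctrl")
  expect_false(any(c("p_value", "fdr") %in% names(fc)))
  expect_equal(fc$fold_change[1], 2)
  expect_equal(fc$fold_change[2], (5 + 1) / (0 + 1))
  expect_equal(fc$fold_change[3], (0 + 1) / (5 + 1))
})

test_that("replicate correlations behave at the extremes", {
  lib <- random_library(5, 1, seed = 81)
  x <- c(1, 10, 100, 1000, 10000)
  m <- make_control_matrix(lib, list(a = x, b = x, c = rev(x),
                                     d = rep(7, 5)))
  rc <- replicate_correlation(m, c("a", "b"))
  expect_equal(rc$pearson, 1)
  expect_equal(rc$spearman, 1)
  rc2 <- replicate_correlation(m, c("a", "c"))
  expect_equal(rc2$spearman, -1)
  rc3 <- replicate_correlation(m, c("a", "d"))
  expect_true(is.na(rc3$pearson) && is.na(rc3$spearman))

  set.seed(82)
  lib2 <- simulate_library(50, 6, seed = 82)
  sim <- simulate_counts(lib2, baseline_mean = 100, dispersion = 0.2,
                         n_controls = 2, n_treatments = 0, seed = 83)
  m2 <- sim$counts
  attr(m2, "normalization") <- "cpm"
  rc4 <- replicate_correlation(m2, c("control_1", "control_2"))
  expect_gt(rc4$pearson, 0.3)
})
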