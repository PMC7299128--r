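test_that("low-count filtering removes genes below 10 total reads", {
  cm <- toy_counts(rbind(g_keep10 = c(5L, 5L, 0L, 0L),
                         g_drop9 = c(3L, 3L, 3L, 0L),
                         g_zero = c(0L, 0L, 0L, 0L),
                         g_big = c(100L, 100L, 100L, 100L)))
  out <- filter_low_counts(cm)
  expect_identical(rownames(out$counts), c("g_keep10", "g_big"))
  expect_identical(out$samples, cm$samples)
})

test_that("median-of-ratios size factors match hand computations", {
  # identical samples: all factors 1
  cm <- toy_counts(matrix(rep(c(10L, 20L, 30L), 2), ncol = 2))
  expect_equal(unname(estimate_size_factors(cm)), c(1, 1))

  # sample2 = 4x sample1: geomean 2c, ratios c/2c = 0.5 and 4c/2c = 2
  cm <- toy_counts(cbind(s1 = c(10L, 50L), s2 = c(40L, 200L)))
  expect_equal(unname(estimate_size_factors(cm)), c(0.5, 2))

  # zero row excluded from the reference: factors from gene 2 alone
  cm <- toy_counts(rbind(g1 = c(0L, 0L), g2 = c(4L, 8L)))
  expect_equal(unname(estimate_size_factors(cm)), c(4 / sqrt(32), 8 / sqrt(32)))

  # no zero-free gene: estimation error
  cm <- toy_counts(rbind(g1 = c(0L, 5L), g2 = c(4L, 0L)))
  expect_error(estimate_size_factors(cm), "size factors")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (rep in 1:5) {
    p <- runif(20)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone in rank
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("the NB Wald test is calibrated on a null and matches the Poisson limit", {
  # literally identical groups, large counts: log2fc = 0, p near 1
  base <- matrix(rnbinom(40 * 4, mu = 5000, size = 1000), nrow = 40)
  counts <- cbind(base, base)
  cm <- toy_counts(counts, phase = rep(c("sporophyte", "gametophyte"), each = 4))
  de <- nb_wald_test(cm, setNames(rep(1, 8), colnames(cm$counts)),
                     cm$samples$phase)
  expect_true(all(abs(de$log2fc) < 1e-6))
  expect_true(all(de$wald_p > 0.9))

  # random null draws: p roughly uniform
  set.seed(3)
  counts <- matrix(rnbinom(40 * 8, mu = 5000, size = 1000), nrow = 40)
  cm <- toy_counts(counts, phase = rep(c("sporophyte", "gametophyte"), each = 4))
  de <- nb_wald_test(cm, setNames(rep(1, 8), colnames(cm$counts)),
                     cm$samples$phase)
  expect_true(all(abs(de$log2fc) < 0.2))
  expect_gt(median(de$wald_p), 0.25)
  expect_lt(mean(de$preferential), 0.05)

  # alpha = 0 equals a Poisson GLM Wald test (closed-form oracle on large counts)
  counts <- matrix(c(900L, 1100L, 1000L, 980L,   # gametophyte
                     2100L, 1900L, 2050L, 1950L), nrow = 1)  # sporophyte
  cm <- toy_counts(counts, phase = rep(c("gametophyte", "sporophyte"), each = 4))
  sf <- setNames(rep(1, 8), colnames(cm$counts))
  de0 <- nb_wald_test(cm, sf, cm$samples$phase, dispersion = 0)
  fit <- glm(as.numeric(counts) ~ factor(rep(c("g", "s"), each = 4)),
             family = poisson())
  lfc_glm <- coef(fit)[2] / log(2)
  se_glm <- sqrt(diag(vcov(fit)))[2] / log(2)
  expect_equal(de0$log2fc, unname(lfc_glm), tolerance = 1e-3)
  expect_equal(de0$se, unname(se_glm), tolerance = 1e-3)
  expect_equal(de0$wald_p,
               2 * pnorm(-abs(unname(lfc_glm / se_glm))), tolerance = 1e-2)
})

test_that("planted fold changes are recovered without bias", {
  # 500 genes, mu = 200, alpha = 0.05, 3 + 3 samples, log2fc = 3
  set.seed(11)
  n <- 500
  mu_g <- 200; mu_s <- 200 * 8
  counts <- cbind(matrix(rnbinom(n * 3, mu = mu_s, size = 20), n),
                  matrix(rnbinom(n * 3, mu = mu_g, size = 20), n))
  cm <- toy_counts(counts, phase = rep(c("sporophyte", "gametophyte"), each = 3))
  de <- nb_wald_test(cm, setNames(rep(1, 6), colnames(cm$counts)),
                     cm$samples$phase)
  expect_lt(abs(mean(de$log2fc) - 3), 0.15)
})

test_that("degenerate all-zero groups stay finite via the pseudo-mean", {
  counts <- rbind(g1 = c(0L, 0L, 0L, 120L, 110L, 130L),
                  g2 = c(50L, 60L, 55L, 0L, 0L, 0L))
  cm <- toy_counts(counts, phase = rep(c("sporophyte", "gametophyte"), each = 3))
  de <- nb_wald_test(cm, setNames(rep(1, 6), colnames(cm$counts)),
                     cm$samples$phase)
  expect_true(all(is.finite(de$log2fc)))
  expect_true(all(is.finite(de$wald_p)))
  expect_lt(de$log2fc[1], 0)   # sporophyte all-zero: strongly negative
  expect_gt(de$log2fc[2], 0)
})

test_that("the preferential set applies both stated thresholds", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(2.5, 2.5, 1.9, 2.0),
                   padj = c(0.01, 0.06, 0.001, 0.05))
  expect_identical(preferential_sporophyte_set(de), c("a", "d"))
})

test_that("type-I error is controlled on a null simulation", {
  sim <- simulate_two_species(simulation_config(
    n_shared_orthologs = 850, n_specific_per_species = 150,
    n_flat_per_species = 1000, de_fraction = 0, seed = 21))
  cm <- filter_low_counts(sim$counts_a)
  sf <- estimate_size_factors(cm)
  de <- nb_wald_test(cm, sf, cm$samples$phase)
  expect_equal(nrow(de), 2000)
  expect_lte(mean(de$preferential), 0.07)
})

test_that("scaling one sample's counts rescales its size factor and leaves log2fc invariant", {
  set.seed(9)
  counts <- matrix(rnbinom(100 * 6, mu = 300, size = 20) + 1L, nrow = 100)
  cm <- toy_counts(counts, phase = rep(c("sporophyte", "gametophyte"), each = 3))
  sf1 <- estimate_size_factors(cm)
  de1 <- nb_wald_test(cm, sf1, cm$samples$phase)

  counts2 <- counts
  counts2[, 1] <- counts[, 1] * 3L
  cm2 <- toy_counts(counts2, phase = cm$samples$phase)
  sf2 <- estimate_size_factors(cm2)
  expect_equal(unname(sf2[1] / sf1[1]), 3 * unname(sf2[2] / sf1[2]), tolerance = 1e-9)
  de2 <- nb_wald_test(cm2, sf2, cm2$samples$phase)
  # equivariance is approximate for the offset NB fit: rescaling a sample
  # changes its likelihood weight and the moment dispersion estimate, so
  # estimates agree closely but not to machine precision
  expect_lt(max(abs(de2$log2fc - de1$log2fc)), 0.05)
})
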