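mk_hit <- function(query = "q1", evalue = 1e-50, qs = 1, qe = 100, sim = 90,
                   qlen = NULL) {
  df <- data.frame(query_id = query, subject_id = "t1",
                   percent_similarity = sim, alignment_length = qe - qs + 1,
                   mismatches = 0, gap_opens = 0, q_start = qs, q_end = qe,
                   s_start = 1, s_end = qe - qs + 1, evalue = evalue,
                   bitscore = 100, stringsAsFactors = FALSE)
  if (!is.null(qlen)) df$query_length <- qlen
  df
}

test_that("hit filtering enforces E-value, coverage and similarity jointly", {
  qlen <- c(q1 = 100)
  # all three pass
  expect_equal(nrow(filter_hits(mk_hit(evalue = 1e-7, qs = 1, qe = 85, sim = 40), qlen)), 1)
  # weak E-value fails despite strong coverage/similarity
  expect_equal(nrow(filter_hits(mk_hit(evalue = 1e-5, qs = 1, qe = 95, sim = 90), qlen)), 0)
  # coverage 79.9% fails at the 80% boundary
  qlen2 <- c(q1 = 1000)
  expect_equal(nrow(filter_hits(mk_hit(evalue = 1e-50, qs = 1, qe = 799, sim = 90), qlen2)), 0)
  expect_equal(nrow(filter_hits(mk_hit(evalue = 1e-50, qs = 1, qe = 800, sim = 90), qlen2)), 1)
  # similarity below 35 fails
  expect_equal(nrow(filter_hits(mk_hit(sim = 34.9), qlen)), 0)
  # coverage uses the 1-based inclusive query span
  out <- filter_hits(mk_hit(qs = 11, qe = 90), qlen)
  expect_equal(out$coverage, 0.80)
})

test_that("coverage filtering requires query lengths", {
  expect_error(filter_hits(mk_hit()), "query length")
  expect_error(filter_hits(mk_hit("mystery"), c(other = 100)), "mystery")
  # a 13-column table carries its own lengths
  expect_equal(nrow(filter_hits(mk_hit(qlen = 100))), 1)
})

test_that("classification follows orthogroup, then protein hit, then none", {
  og <- og_table(list(spA = c("a1"), spB = c("b1")),
                 list(spA = c("a2"), spB = character(0)))
  hits <- passing_hits("a2")
  cls <- classify_genes(c("a1", "a2", "a3"), "spA", og, hits)
  expect_identical(cls$label, c("homologous", "homologous", "species_specific"))
  expect_identical(cls$evidence, c("orthogroup", "protein_hit", "none"))
  # orthogroup evidence takes precedence even with a hit present
  cls2 <- classify_genes(c("a1"), "spA", og, passing_hits("a1"))
  expect_identical(cls2$evidence, "orthogroup")
  # an orthogroup without the other species does not count
  cls3 <- classify_genes(c("a2"), "spA", og, NULL)
  expect_identical(cls3$label, "species_specific")
})

test_that("genome rescue promotes only species-specific genes and is idempotent", {
  og <- og_table(list(spA = "a1", spB = "b1"))
  cls <- classify_genes(c("a1", "a2", "a3"), "spA", og, NULL)
  rescued <- rescue_with_genome_hits(cls, passing_hits("a2"))
  expect_identical(rescued$label, c("homologous", "homologous", "species_specific"))
  expect_identical(rescued$evidence, c("orthogroup", "genome_rescue", "none"))
  # a sub-threshold genome hit never reaches this step: the caller filters;
  # an empty filtered table leaves everything unchanged
  low_cov <- filter_hits(mk_hit("a3", qs = 1, qe = 60, qlen = 100))
  expect_identical(rescue_with_genome_hits(cls, low_cov), cls)
  # idempotence on second application
  expect_identical(rescue_with_genome_hits(rescued, passing_hits("a2")), rescued)
})

test_that("classification is invariant under gene order permutation", {
  og <- og_table(list(spA = c("a1"), spB = c("b1")),
                 list(spA = c("a4"), spB = c("b4")))
  genes <- c("a1", "a2", "a3", "a4")
  cls <- classify_genes(genes, "spA", og, passing_hits("a3"))
  perm <- c(3, 1, 4, 2)
  cls_perm <- classify_genes(genes[perm], "spA", og, passing_hits("a3"))
  expect_identical(cls_perm[order(cls_perm$gene_id), ]$label,
                   cls[order(cls$gene_id), ]$label)
})

test_that("one-to-one extraction keeps exactly the singleton orthogroups", {
  og <- og_table(list(spA = "a1", spB = "b1"),
                 list(spA = c("a2", "a3"), spB = "b2"),
                 list(spA = "a4", spB = character(0)),
                 list(spA = "a5", spB = "b5"))
  pairs <- extract_one_to_one(og)
  expect_equal(nrow(pairs), 2)
  expect_identical(pairs$gene_a, c("a1", "a5"))
  expect_identical(pairs$gene_b, c("b1", "b5"))

  # brute-force recount on a randomized table
  set.seed(13)
  ogs <- lapply(1:10, function(i) {
    list(spA = paste0("a", i, "_", seq_len(sample(0:3, 1))),
         spB = paste0("b", i, "_", seq_len(sample(0:3, 1))))
  })
  ogs <- lapply(ogs, function(g) lapply(g, function(v) v[grepl("_", v)]))
  tab <- orthogroup_table(paste0("OG", 1:10), ogs, c("spA", "spB"))
  expected <- sum(vapply(ogs, function(g) length(g$spA) == 1 && length(g$spB) == 1, logical(1)))
  expect_equal(nrow(extract_one_to_one(tab)), expected)
})

test_that("the Pearson chi-square matches hand values and the textbook oracle", {
  expect_equal(pearson_chi_square(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  # expected cells all 10: chi2 = 4 * (20-10)^2/10 = 40
  r <- pearson_chi_square(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r$chi2, 40)
  expect_equal(r$df, 1L)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2)), "margin")

  set.seed(17)
  for (rep in 1:10) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2)
    got <- pearson_chi_square(tab)
    expect_equal(got$chi2, oracle_chi2(tab))
    # and agrees with the uncorrected standard implementation
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic))
    expect_equal(got$p, unname(ref$p.value))
  }
})

test_that("enrichment builds the preferential-by-homology table over the universe", {
  og <- og_table(list(spA = paste0("a", 1:4), spB = "b1"))
  cls <- classify_genes(paste0("a", 1:8), "spA", og, NULL)
  res <- chi_square_enrichment(cls, preferential = c("a1", "a5", "a6"))
  expect_equal(res$observed["preferential", ],
               c(homologous = 1, species_specific = 2))
  expect_equal(res$observed["not_preferential", ],
               c(homologous = 3, species_specific = 2))
  expect_equal(res$chi2, oracle_chi2(res$observed))
})
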