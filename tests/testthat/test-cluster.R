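two_clouds <- function(n_per = 5, sd = 0.02, seed = 41) {
  set.seed(seed)
  c1 <- c(1, 0, -1, 0); c2 <- c(-1, 0, 1, 0)
  x <- rbind(matrix(rnorm(n_per * 4, mean = rep(c1, each = n_per), sd = sd), n_per),
             matrix(rnorm(n_per * 4, mean = rep(c2, each = n_per), sd = sd), n_per))
  rownames(x) <- paste0("g", seq_len(2 * n_per))
  x
}

test_that("the fuzzifier estimate behaves as published", {
  # frozen value from direct evaluation of the formula at the real-data size
  expect_equal(estimate_fuzzifier(3976, 4), 2.532317, tolerance = 1e-6)
  grid <- expand.grid(N = c(10, 100, 1000, 10000), D = c(2, 4, 8))
  m <- mapply(estimate_fuzzifier, grid$N, grid$D)
  expect_true(all(m > 1))
  # non-increasing in N at fixed D
  for (D in c(2, 4, 8)) {
    mN <- sapply(c(10, 100, 1000, 10000), estimate_fuzzifier, n_stages = D)
    expect_true(all(diff(mN) < 0))
  }
  expect_error(estimate_fuzzifier(1, 4), "n_genes")
})

test_that("degenerate k = 1 gives the data mean with full membership", {
  x <- two_clouds()
  fit <- fcm(x, 1, m = 2, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(x)))
  expect_equal(unname(fit$memberships[, 1]), rep(1, nrow(x)))
})

test_that("fcm matches the independently coded alternating-update oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(10:50, 1)
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("g", 1:n), NULL))
    k <- sample(2:4, 1)
    init <- x[sample(n, k), , drop = FALSE]
    fit <- fcm(x, k, m = 2, init = init)
    ref <- oracle_fcm(x, init, m = 2)
    expect_equal(unname(fit$centroids), unname(ref$centroids), tolerance = 1e-6)
    expect_equal(unname(fit$memberships), unname(ref$u), tolerance = 1e-6)
    expect_equal(fit$objective, ref$objective, tolerance = 1e-6)
  }
})

test_that("fcm agrees with the reference cmeans implementation on separated data", {
  skip_if_not_installed("e1071")
  x <- two_clouds(n_per = 10)
  init <- x[c(1, 11), ]
  fit <- fcm(x, 2, m = 2, init = init)
  ref <- e1071::cmeans(x, centers = init, m = 2, iter.max = 500)
  # same fixed point (cluster order preserved by the shared initialization)
  expect_equal(unname(fit$centroids), unname(ref$centers), tolerance = 1e-4)
  expect_equal(unname(fit$memberships), unname(ref$membership), tolerance = 1e-4)
})

test_that("well-separated clouds are recovered crisply", {
  x <- two_clouds(n_per = 5)
  fit <- fcm(x, 2, m = 2, seed = 3, n_restarts = 5)
  means <- rbind(colMeans(x[1:5, ]), colMeans(x[6:10, ]))
  # match centroids to cloud means by proximity
  d <- as.matrix(dist(rbind(fit$centroids, means)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), 0.05)
  expect_true(all(fit$max_membership > 0.95))
})

test_that("membership rows sum to one and the objective never increases", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 4), 30, 4)
    fit <- fcm(x, 3, m = 2.2, seed = seed, n_restarts = 2)
    expect_equal(rowSums(fit$memberships), rep(1, 30), tolerance = 1e-9)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    expect_lte(fit$objective, fit$objective_trace[length(fit$objective_trace)] + 1e-8)
  }
})

test_that("projection applies the membership formula against fixed centroids", {
  cent <- rbind(c(1, 0, -1, 0), c(-1, 0, 1, 0))
  model <- structure(list(centroids = cent, m = 2, k = 2L, n_stages = 4L),
                     class = "fcm")
  # profile equal to a centroid: membership 1 there
  p <- predict(model, rbind(cent[2, ]))
  expect_equal(unname(p$memberships[1, ]), c(0, 1))
  expect_equal(p$cluster, 2L)
  # profile equidistant from all centroids: uniform memberships
  p2 <- predict(model, rbind(c(0, 1, 0, -1)))
  expect_equal(unname(p2$memberships[1, ]), c(0.5, 0.5))
  expect_equal(p2$cluster, 1L)  # tie broken to the lowest index
  # hand-evaluated memberships for three profiles vs two centroids
  prof <- rbind(a = c(0.5, 0, -0.5, 0), b = c(-0.5, 0.2, 0.5, 0), c = c(2, 0, -2, 0))
  p3 <- predict(model, prof)
  for (i in 1:3) {
    d2 <- c(sum((prof[i, ] - cent[1, ])^2), sum((prof[i, ] - cent[2, ])^2))
    expect_equal(unname(p3$memberships[i, ]),
                 (1 / d2) / sum(1 / d2), tolerance = 1e-12)
  }
  expect_error(predict(model, matrix(0, 1, 3)), "stages")
})

test_that("self-projection reproduces confident hard assignments", {
  set.seed(47)
  z <- archetype_z()
  x <- z[sample(1:12, 200, replace = TRUE), ] + matrix(rnorm(800, sd = 0.3), 200)
  rownames(x) <- paste0("g", 1:200)
  fit <- fcm(x, 6, m = 2, seed = 8)
  proj <- predict(fit, x)
  confident <- fit$max_membership >= 0.6
  expect_true(any(confident))
  expect_identical(proj$cluster[confident], fit$cluster[confident])
  expect_equal(unname(rowSums(proj$memberships)), rep(1, 200), tolerance = 1e-9)
})

test_that("the Dmin profile flags redundant cluster numbers", {
  # only 3 distinct archetype shapes: Dmin collapses beyond k = 3
  set.seed(53)
  z <- archetype_z()[c(1, 6, 9), ]
  x <- z[rep(1:3, each = 40), ] + matrix(rnorm(480, sd = 0.1), 120)
  rownames(x) <- paste0("g", 1:120)
  prof <- dmin_profile(x, 2:6, m = 2, seed = 61)
  expect_true(all(prof$dmin >= 0))
  # sharp relative drop from k = 3 to k = 4
  d <- prof$dmin
  expect_gt((d[2] - d[3]) / d[2], 0.4)
  expect_gt(d[2], d[4])

  # k = 2: Dmin is the distance between the two centroids
  fit2 <- fcm(x, 2, m = 2, seed = 62, n_restarts = 3)
  prof2 <- dmin_profile(x, 2, m = 2, seed = 61 + 1, n_restarts = 3)
  expect_equal(prof2$dmin, as.numeric(dist(fit2$centroids)), tolerance = 0.05)
})

test_that("cluster-number selection honours the override and the elbow rule", {
  prof <- structure(data.frame(k = 2:5, dmin = c(1.0, 0.9, 0.2, 0.19)),
                    class = c("dmin_profile", "data.frame"))
  expect_identical(select_k(prof, override = 12), 12L)
  expect_identical(select_k(prof), 4L)
  flat <- structure(data.frame(k = 2:5, dmin = rep(0.5, 4)),
                    class = c("dmin_profile", "data.frame"))
  expect_identical(select_k(flat), 2L)
  expect_error(select_k(flat[0, ]), "empty")
})

test_that("major clusters follow the centroid peak stage", {
  cent <- rbind(c(2, 1, 0, -1),      # peak stage 1
                c(0, 2, 1, -1),      # peak stage 2
                c(-1, 0, 2, 1),      # peak stage 3
                c(-1, 0, 1, 2),      # peak stage 4
                c(1.5, -1, -1, 1.45))# U-shape, near-equal ends
  mm <- assign_major_clusters(cent)
  expect_identical(mm, c("MC1_early", "MC2_mid", "MC2_mid", "MC3_late", "unassigned"))
})

test_that("shift classification combines majors, memberships and exclusions", {
  pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                      gene_b = c("b1", "b2", "b3", "b4"))
  major_map <- c("MC1_early", "MC2_mid", "unassigned")
  asg_a <- list(cluster = c(1L, 1L, 3L, 2L), max_membership = c(0.9, 0.8, 0.9, 0.9),
                gene_ids = pairs$gene_a)
  asg_b <- list(cluster = c(1L, 2L, 1L, 2L), max_membership = c(0.9, 0.9, 0.9, 0.2),
                gene_ids = pairs$gene_b)
  sh <- classify_shifts(asg_a, asg_b, major_map, pairs, membership_min = 0.3)
  expect_identical(sh$table$call, c("conserved", "heterochronic", "excluded", "excluded"))
  s <- sh$summary
  expect_equal(s$n[s$call == "conserved"], 1)
  expect_equal(s$n[s$call == "excluded"], 2)
  expect_equal(s$percent[s$call == "heterochronic"], 50)
})

test_that("the TF contrast reduces to the Pearson chi-square oracle", {
  tab <- data.frame(gene_a = paste0("a", 1:8), gene_b = paste0("b", 1:8),
                    call = rep(c("conserved", "heterochronic"), 4))
  sh <- structure(list(table = tab), class = "shift_table")
  # TFs with identical proportions: chi2 = 0
  res <- tf_subset_comparison(sh, c("a1", "a2"))
  expect_equal(res$chi2, 0)
  expect_equal(res$observed, matrix(c(1, 1, 3, 3), 2, byrow = TRUE,
                                    dimnames = dimnames(res$observed)))
  # random small tables match the oracle
  set.seed(67)
  for (rep in 1:5) {
    calls <- sample(c("conserved", "heterochronic"), 40, replace = TRUE)
    tab <- data.frame(gene_a = paste0("a", 1:40), gene_b = paste0("b", 1:40),
                      call = calls)
    sh <- structure(list(table = tab), class = "shift_table")
    tf <- paste0("a", sample(40, 15))
    got <- tryCatch(tf_subset_comparison(sh, tf), error = function(e) NULL)
    if (!is.null(got)) expect_equal(got$chi2, oracle_chi2(got$observed))
  }
  expect_error(tf_subset_comparison(sh, "zz"), "transcription factor")
})
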