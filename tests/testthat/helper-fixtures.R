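# shared fixtures and independent oracles

# small count_matrix with explicit cells
toy_counts <- function(counts, phase = NULL, species = "spA", stage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  n <- ncol(counts)
  if (is.null(phase)) phase <- rep("sporophyte", n)
  if (is.null(stage)) {
    stage <- ifelse(phase == "sporophyte",
                    as.character(rep_len(1:4, n))[seq_len(n)], "g1")
  }
  samples <- data.frame(sample_id = colnames(counts), species = species,
                        phase = phase, stage = stage,
                        replicate = seq_len(n), stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

# a count matrix with balanced sporophyte stages + gametophyte samples
toy_design_counts <- function(n_genes = 20, n_reps = 3, n_gam = 4,
                              mu = 100, seed = 1) {
  set.seed(seed)
  n_spo <- 4 * n_reps
  counts <- matrix(rnbinom(n_genes * (n_spo + n_gam), mu = mu, size = 20),
                   nrow = n_genes,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("s", seq_len(n_spo + n_gam))))
  phase <- c(rep("sporophyte", n_spo), rep("gametophyte", n_gam))
  stage <- c(as.character(rep(1:4, each = n_reps)), paste0("g", seq_len(n_gam)))
  samples <- data.frame(sample_id = colnames(counts), species = "spA",
                        phase = phase, stage = stage,
                        replicate = c(rep(seq_len(n_reps), 4), seq_len(n_gam)),
                        stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

# one well-formed 12-column outfmt-6 line
hit_line <- function(q = "q1", s = "s1", pident = 50, len = 100, qs = 1, qe = 100,
                     evalue = 1e-10, qlen = NULL) {
  fields <- c(q, s, pident, len, 0, 0, qs, qe, 1, len, evalue, 180)
  if (!is.null(qlen)) fields <- c(fields, qlen)
  paste(fields, collapse = "\t")
}

# minimal passing hit table built directly
passing_hits <- function(queries, subjects = paste0("t", seq_along(queries))) {
  df <- data.frame(query_id = queries, subject_id = subjects,
                   percent_similarity = 90, alignment_length = 100,
                   mismatches = 0, gap_opens = 0, q_start = 1, q_end = 100,
                   s_start = 1, s_end = 100, evalue = 1e-50, bitscore = 200,
                   query_length = 100, stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

og_table <- function(...) {
  ogs <- list(...)
  orthogroup_table(paste0("OG", seq_along(ogs)), ogs,
                   species = names(ogs[[1]]))
}

# brute-force Pearson chi-square oracle, plain arithmetic
oracle_chi2 <- function(tab) {
  total <- sum(tab)
  chi2 <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / total
    chi2 <- chi2 + (tab[i, j] - e)^2 / e
  }
  chi2
}

# independently coded loop-based fuzzy c-means oracle: plain alternating
# updates from a fixed initial centroid matrix
oracle_fcm <- function(x, centroids, m, max_iter = 500, tol = 1e-6) {
  n <- nrow(x); k <- nrow(centroids)
  u_old <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    u <- matrix(0, n, k)
    for (i in seq_len(n)) {
      d <- numeric(k)
      for (j in seq_len(k)) d[j] <- sum((x[i, ] - centroids[j, ])^2)
      if (any(d < 1e-16)) {
        u[i, which(d < 1e-16)[1]] <- 1
      } else {
        for (j in seq_len(k)) u[i, j] <- 1 / sum((d[j] / d)^(1 / (m - 1)))
      }
    }
    for (j in seq_len(k)) {
      w <- u[, j]^m
      centroids[j, ] <- colSums(x * w) / sum(w)
    }
    if (max(abs(u - u_old)) < tol) break
    u_old <- u
  }
  obj <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    obj <- obj + u[i, j]^m * sum((x[i, ] - centroids[j, ])^2)
  }
  list(centroids = centroids, u = u, objective = obj)
}

# average-rank Spearman oracle from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# hypergeometric upper tail by explicit factorial arithmetic
oracle_hyper_tail <- function(obs, n_success, n_fail, n_draw) {
  total <- n_success + n_fail
  p <- 0
  for (j in obs:min(n_draw, n_success)) {
    p <- p + choose(n_success, j) * choose(n_fail, n_draw - j) / choose(total, n_draw)
  }
  p
}

# transitive-closure oracle: repeated one-step parent expansion
oracle_closure <- function(parents, terms) {
  anc <- setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    cur <- parents[[t]]
    repeat {
      nxt <- unique(c(cur, unlist(parents[cur])))
      if (length(nxt) == length(cur)) break
      cur <- nxt
    }
    anc[[t]] <- sort(cur)
  }
  anc
}

# standardized archetype z-profiles
archetype_z <- function() {
  t(apply(default_archetypes()$profiles, 1, function(v) (v - mean(v)) / sd(v)))
}
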