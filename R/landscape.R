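#' Per-stage mean normalized expression
#'
#' For each gene and sporophyte stage, the mean of size-factor-normalized
#' counts over that stage's replicates. Gametophyte samples are ignored.
#'
#' @param x a [count_matrix()].
#' @param size_factors named size-factor vector covering the samples of `x`.
#' @return Numeric matrix genes x stages, columns named `"1"`, `"2"`, ... in
#'   increasing stage order.
#' @export
stage_means <- function(x, size_factors) {
  stopifnot(inherits(x, "count_matrix"))
  sf <- size_factors[colnames(x$counts)]
  if (anyNA(sf)) stop("size factors must cover every sample")
  spo <- x$samples$phase == "sporophyte"
  if (!any(spo)) stop("no sporophyte samples present")
  stage_int <- rep(NA_integer_, nrow(x$samples))
  stage_int[spo] <- as.integer(x$samples$stage[spo])
  stages <- sort(unique(stage_int[spo]))
  norm <- sweep(x$counts, 2, sf, "/")
  out <- vapply(stages, function(s) {
    idx <- !is.na(stage_int) & stage_int == s
    if (!any(idx)) stop("no samples for sporophyte stage ", s)
    rowMeans(norm[, idx, drop = FALSE])
  }, numeric(nrow(x$counts)))
  dimnames(out) <- list(rownames(x$counts), as.character(stages))
  out
}

#' Row-standardize temporal expression profiles
#'
#' Per gene, subtracts the row mean and divides by the row standard deviation
#' (n - 1 denominator). Genes with zero variance across stages carry no
#' temporal signal and are dropped; their ids are attached as attribute
#' `"dropped"`.
#'
#' @param m numeric matrix, genes x stages.
#' @return Standardized matrix (each surviving row has mean 0, sd 1) with
#'   attribute `dropped`.
#' @export
standardize_profiles <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  keep <- sd > 0 & !is.na(sd)
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  attr(z, "dropped") <- rownames(m)[!keep]
  z
}

#' PCA of expression over a gene subset
#'
#' Singular value decomposition of the column-centered observation x gene
#' matrix: observations are samples (or stage means), variables the selected
#' genes. Subsetting happens before centering.
#'
#' @param m numeric matrix, observations in rows, genes in columns.
#' @param gene_subset optional character vector of gene (column) names to
#'   restrict to; default all.
#' @return Object of class `"expression_pca"`: list with `scores`
#'   (observations x components), `loadings`, `variance_explained`
#'   (fractions summing to 1 over all components).
#' @export
expression_pca <- function(m, gene_subset = NULL) {
  m <- as.matrix(m)
  if (!is.null(gene_subset)) {
    gene_subset <- intersect(colnames(m), gene_subset)
    if (!length(gene_subset)) stop("gene subset is empty after intersection with the matrix")
    m <- m[, gene_subset, drop = FALSE]
  }
  if (nrow(m) < 2) stop("PCA needs at least two observations")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation, variance_explained = ve),
            class = "expression_pca")
}

#' @export
print.expression_pca <- function(x, ...) {
  k <- min(4, length(x$variance_explained))
  cat(sprintf("PCA: %d observations, %d components; variance explained: %s\n",
              nrow(x$scores), length(x$variance_explained),
              paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Cross-species Spearman expression-divergence matrix
#'
#' For every pair of sporophyte stages (one from each species), Spearman's
#' rank correlation over one-to-one orthologs expressed in both stages
#' (stage-mean normalized value > 0 in both species), computed on
#' log2(value + 1); ties receive average ranks. Cells with fewer than
#' `min_pairs` usable orthologs are `NA`.
#'
#' @param stage_a,stage_b stage-mean matrices (see [stage_means()]) for the
#'   two species, on the normalized (not log) scale.
#' @param pairs one-to-one ortholog data.frame with columns `gene_a`
#'   (ids in `stage_a`) and `gene_b` (ids in `stage_b`).
#' @param min_pairs minimum orthologs per cell (default 3).
#' @return List of class `"divergence_matrix"`: `rho` (stages_A x stages_B)
#'   and `n_genes` (orthologs used per cell).
#' @export
spearman_divergence <- function(stage_a, stage_b, pairs, min_pairs = 3) {
  pairs <- pairs[pairs$gene_a %in% rownames(stage_a) &
                 pairs$gene_b %in% rownames(stage_b), , drop = FALSE]
  a <- stage_a[pairs$gene_a, , drop = FALSE]
  b <- stage_b[pairs$gene_b, , drop = FALSE]
  rho <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
  n_genes <- matrix(0L, ncol(a), ncol(b), dimnames = dimnames(rho))
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      use <- a[, i] > 0 & b[, j] > 0
      n_genes[i, j] <- sum(use)
      if (sum(use) >= min_pairs) {
        rho[i, j] <- stats::cor(log2(a[use, i] + 1), log2(b[use, j] + 1),
                                method = "spearman")
      }
    }
  }
  structure(list(rho = rho, n_genes = n_genes), class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat("Spearman expression-divergence matrix (rows: species A stages, cols: species B stages)\n")
  print(round(x$rho, 3))
  invisible(x)
}
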