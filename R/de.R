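#' Remove genes with negligible total counts
#'
#' Drops gene models whose summed read count over all samples is below
#' `min_total` (default 10), the usual guard against models supported only by
#' a handful of potentially misaligned reads. Genes with total exactly at the
#' threshold are retained; survivor order is preserved.
#'
#' @param x a [count_matrix()].
#' @param min_total minimum total count across samples required to keep a gene.
#' @return A [count_matrix()] restricted to the surviving genes.
#' @export
filter_low_counts <- function(x, min_total = 10) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts) >= min_total
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' Median-of-ratios size factors
#'
#' Classical library-size normalization: the reference for each gene is its
#' geometric mean across samples (genes with any zero count are excluded from
#' the reference set), and a sample's size factor is the median over reference
#' genes of count / geometric mean.
#'
#' @param x a [count_matrix()] or plain count matrix.
#' @return Named positive numeric vector, one size factor per sample.
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) stop("no gene has nonzero counts in every sample; cannot estimate size factors")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(exp(logc - loggeo), 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (wraps [stats::p.adjust()] after
#' input validation): monotone in rank, never below the raw p-value, capped
#' at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for sporophyte vs gametophyte expression
#'
#' A two-group NB test in the classical mould: median-of-ratios size factors
#' enter as offsets, a per-gene dispersion \eqn{\alpha} (variance
#' \eqn{\mu + \alpha\mu^2}) is estimated by method of moments on normalized
#' counts pooled within groups and floored, group means come from a
#' log-link NB fit per group (Newton iterations on the group mean with
#' size-factor offsets), and the Wald statistic compares
#' \eqn{\log_2}-fold change to its standard error against a standard normal.
#' A pseudo-mean of 0.5 normalized counts is added to both group means before
#' taking the fold change so all-zero groups yield finite estimates.
#'
#' @param x a [count_matrix()].
#' @param size_factors named size-factor vector as from
#'   [estimate_size_factors()].
#' @param groups factor or character vector over samples with exactly two
#'   levels; the *second* level sorted last is taken as the numerator unless
#'   `numerator` is given. For the canonical design pass the sample phase and
#'   `numerator = "sporophyte"`.
#' @param numerator group whose mean goes in the fold-change numerator
#'   (default `"sporophyte"` when present).
#' @param dispersion optional fixed dispersion (recycled over genes),
#'   overriding the moment estimate; `0` gives the Poisson limit.
#' @param alpha_floor lower bound for the moment dispersion estimate.
#' @return data.frame with columns `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_p`, `padj`, `preferential` (padj <= 0.05 and log2fc >= 2).
#' @export
nb_wald_test <- function(x, size_factors, groups,
                         numerator = "sporophyte",
                         dispersion = NULL, alpha_floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  if (is.null(names(size_factors))) names(size_factors) <- colnames(counts)
  sf <- size_factors[colnames(counts)]
  if (anyNA(sf) || any(sf <= 0)) stop("size factors must be positive and cover every sample")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (!numerator %in% lev) numerator <- lev[2]
  denom <- setdiff(lev, numerator)
  in_num <- groups == numerator
  if (sum(in_num) < 2 || sum(!in_num) < 2) stop("each group needs at least two samples")

  norm <- sweep(counts, 2, sf, "/")
  if (is.null(dispersion)) {
    alpha <- .moment_dispersion(norm, in_num, alpha_floor)
  } else {
    alpha <- pmax(rep_len(dispersion, nrow(counts)), 0)
  }
  fit_num <- .nb_group_fit(counts[, in_num, drop = FALSE], sf[in_num], alpha)
  fit_den <- .nb_group_fit(counts[, !in_num, drop = FALSE], sf[!in_num], alpha)

  log2fc <- log2(fit_num$mean + 0.5) - log2(fit_den$mean + 0.5)
  se <- sqrt(1 / pmax(fit_num$info, 1e-12) + 1 / pmax(fit_den$info, 1e-12)) / log(2)
  wald_p <- 2 * stats::pnorm(-abs(log2fc / se))
  padj <- bh_adjust(wald_p)
  data.frame(gene_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2fc = log2fc, se = se, wald_p = wald_p, padj = padj,
             preferential = padj <= 0.05 & log2fc >= 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

# moment estimator of NB dispersion pooled within the two groups:
# alpha_g = (s2_g - m_g) / m_g^2 per group on normalized counts, averaged
# over groups with positive mean, floored.
.moment_dispersion <- function(norm, in_num, alpha_floor) {
  est_one <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  }
  a1 <- est_one(norm[, in_num, drop = FALSE])
  a2 <- est_one(norm[, !in_num, drop = FALSE])
  a <- rowMeans(cbind(a1, a2), na.rm = TRUE)
  a[is.nan(a)] <- alpha_floor
  pmax(a, alpha_floor)
}

# Per-group NB mean fit with log link and size-factor offsets, vectorized
# over genes. Newton iterations on eta = log(q), q the normalized group mean;
# returns the mean and the Fisher information of eta (= sum mu/(1+alpha*mu)).
.nb_group_fit <- function(counts, sf, alpha, max_iter = 50, tol = 1e-10) {
  n_genes <- nrow(counts)
  q <- pmax(rowSums(counts) / sum(sf), 1e-8)
  eta <- log(q)
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf                       # genes x samples
    w <- 1 + alpha * mu
    score <- rowSums((counts - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  # all-zero groups: mean -> 0, information from the near-zero fit is kept
  # (the pseudo-mean downstream bounds the fold change).
  list(mean = exp(eta), info = info)
}

#' Preferentially sporophyte-expressed gene set
#'
#' Applies the definition used throughout the package: adjusted p-value at or
#' below `fdr` and \eqn{\log_2}-fold change (sporophyte vs gametophyte) at or
#' above `lfc`.
#'
#' @param de data.frame from [nb_wald_test()].
#' @param lfc minimum log2 fold change (default 2).
#' @param fdr maximum adjusted p-value (default 0.05).
#' @return Character vector of gene ids.
#' @export
preferential_sporophyte_set <- function(de, lfc = 2, fdr = 0.05) {
  de$gene_id[!is.na(de$padj) & de$padj <= fdr & de$log2fc >= lfc]
}
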