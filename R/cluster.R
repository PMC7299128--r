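#' Empirical fuzzifier estimate
#'
#' The data-driven choice of the fuzzy c-means fuzzifier m from the number of
#' objects N (genes) and feature-space dimension D (stages):
#' \deqn{m = 1 + (1418/N + 22.05) D^{-2} +
#'           (12.33/N + 0.243) D^{-0.0406 \ln N - 0.1134}}
#' It is always greater than 1 and decreases towards 1 as N grows.
#'
#' @param n_genes number of profiles to be clustered (N >= 2).
#' @param n_stages profile dimension (D >= 2).
#' @return The fuzzifier m (> 1).
#' @export
estimate_fuzzifier <- function(n_genes, n_stages) {
  if (length(n_genes) != 1 || length(n_stages) != 1 ||
      is.na(n_genes) || is.na(n_stages) || n_genes < 2 || n_stages < 2) {
    stop("need n_genes >= 2 and n_stages >= 2")
  }
  N <- as.numeric(n_genes); D <- as.numeric(n_stages)
  1 + (1418 / N + 22.05) * D^-2 +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

# Membership update for fixed centroids: u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))
# on squared Euclidean distances; a profile coinciding with a centroid gets
# full membership there (first such centroid on ties).
.fcm_memberships <- function(x, centroids, m) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(x)), rowSums(centroids^2)) -
    2 * x %*% t(centroids)
  d2 <- pmax(d2, 0)
  zero <- d2 < 1e-16
  pw <- d2^(-1 / (m - 1))
  u <- pw / rowSums(pw)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    first <- apply(zero[hit, , drop = FALSE], 1, which.max)
    u[cbind(which(hit), first)] <- 1
  }
  list(u = u, d2 = d2)
}

#' Fuzzy c-means clustering of temporal expression profiles
#'
#' Fits the fuzzy c-means model by alternating minimization of
#' \deqn{J = \sum_i \sum_j u_{ij}^m \|x_i - c_j\|^2, \qquad \sum_j u_{ij} = 1,}
#' with the standard closed-form updates (memberships from centroid
#' distances, centroids as membership^m-weighted means). Convergence is
#' declared when the largest membership change falls below `tol`; the best of
#' `n_restarts` seeded restarts by final objective is returned. Row profiles
#' are expected on the standardized scale (see [standardize_profiles()]).
#'
#' @param x numeric matrix, genes x stages.
#' @param k number of clusters (2 <= k < number of genes; k = 1 allowed as
#'   the degenerate mean-profile model).
#' @param m fuzzifier (> 1); default estimated via [estimate_fuzzifier()].
#' @param seed integer seed for the restart initializations (`NULL` leaves
#'   the RNG state alone).
#' @param n_restarts number of random centroid initializations (data points
#'   sampled without replacement).
#' @param max_iter,tol iteration cap and membership-change tolerance.
#' @param init optional k x stages matrix of starting centroids; suppresses
#'   restarts.
#' @return Object of class `"fcm"`: list with `centroids` (k x stages),
#'   `memberships` (genes x k, rows summing to 1), `k`, `m`, `objective`,
#'   `objective_trace` (per-iteration objective of the winning restart),
#'   `cluster` (hard argmax assignment, ties to the lowest index) and
#'   `max_membership`.
#' @export
fcm <- function(x, k, m = NULL, seed = NULL, n_restarts = 10,
                max_iter = 500, tol = 1e-6, init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(m)) m <- estimate_fuzzifier(n, ncol(x))
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n_genes")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(init)) {
    inits <- list(as.matrix(init))
  } else {
    inits <- lapply(seq_len(n_restarts), function(r) {
      x[sample.int(n, k), , drop = FALSE]
    })
  }
  best <- NULL
  for (cent in inits) {
    fit <- .fcm_one(x, cent, m, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  hard <- max.col(best$u, ties.method = "first")
  structure(list(centroids = best$centroids, memberships = best$u,
                 k = as.integer(k), m = m,
                 objective = best$objective, objective_trace = best$trace,
                 cluster = hard,
                 max_membership = best$u[cbind(seq_len(n), hard)],
                 gene_ids = rownames(x), n_stages = ncol(x),
                 stage_names = colnames(x)),
            class = "fcm")
}

.fcm_one <- function(x, centroids, m, max_iter, tol) {
  u_prev <- NULL
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    mem <- .fcm_memberships(x, centroids, m)
    u <- mem$u
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    d2_new <- .fcm_memberships(x, centroids, m)$d2
    trace[iter] <- sum(um * d2_new)
    if (!is.null(u_prev) && max(abs(u - u_prev)) < tol) break
    u_prev <- u
  }
  mem <- .fcm_memberships(x, centroids, m)
  list(centroids = centroids, u = mem$u,
       objective = sum(mem$u^m * mem$d2), trace = trace)
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means model: k = %d clusters, m = %.3f, %d profiles x %d stages\n",
              x$k, x$m, nrow(x$memberships), x$n_stages))
  cat(sprintf("objective J = %.4f\n", x$objective))
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  sizes <- tabulate(object$cluster, nbins = object$k)
  out <- data.frame(cluster = seq_len(object$k), n_genes = sizes,
                    mean_max_membership = vapply(seq_len(object$k), function(j) {
                      idx <- object$cluster == j
                      if (any(idx)) mean(object$max_membership[idx]) else NA_real_
                    }, numeric(1)),
                    peak_stage = apply(object$centroids, 1, which.max))
  structure(list(model = object, clusters = out), class = "summary.fcm")
}

#' @export
print.summary.fcm <- function(x, ...) {
  print(x$model)
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fcm <- function(object, ...) object$centroids

#' @export
fitted.fcm <- function(object, ...) object$memberships

#' Project new profiles onto a fitted cluster model
#'
#' Evaluates the fuzzy c-means membership formula against the model's fixed
#' centroids and fuzzifier for new (identically standardized) profiles — the
#' cross-species assignment step: cluster one species, then statistically
#' assign the other species' one-to-one orthologs to those clusters.
#'
#' @param object an `"fcm"` model.
#' @param newdata numeric matrix, profiles x stages (stages must match the
#'   model).
#' @param ... unused.
#' @return List with `memberships` (profiles x k), `cluster` (hard argmax
#'   assignment, ties to the lowest cluster index) and `max_membership`.
#' @export
predict.fcm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_stages) {
    stop("newdata has ", ncol(newdata), " stages but the model expects ", object$n_stages)
  }
  u <- .fcm_memberships(newdata, object$centroids, object$m)$u
  rownames(u) <- rownames(newdata)
  hard <- max.col(u, ties.method = "first")
  list(memberships = u, cluster = hard,
       max_membership = u[cbind(seq_len(nrow(u)), hard)])
}

#' Project profiles onto a fitted model
#'
#' Convenience wrapper around [predict.fcm()].
#'
#' @param model an `"fcm"` model.
#' @param profiles standardized profiles x stages matrix.
#' @return See [predict.fcm()].
#' @export
project_profiles <- function(model, profiles) predict(model, profiles)

#' Plot fuzzy c-means centroid profiles
#'
#' One line per cluster centroid across stages, on the standardized scale.
#'
#' @param x an `"fcm"` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fcm <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "b", lty = 1, pch = 16,
                    xlab = "stage", ylab = "standardized expression",
                    main = sprintf("FCM centroids (k = %d, m = %.2f)", x$k, x$m), ...)
  graphics::legend("topright", legend = seq_len(x$k), col = seq_len(x$k),
                   lty = 1, cex = 0.7, ncol = 2)
}

#' Minimum centroid distance over a range of cluster numbers
#'
#' Fits the model for each k and records the minimum pairwise Euclidean
#' distance between centroids (Dmin) — the selection diagnostic: Dmin drops
#' steeply while added clusters still capture distinct profile shapes and
#' flattens once clusters become redundant.
#'
#' @param x standardized profiles matrix.
#' @param k_range integer vector of cluster numbers (e.g. `4:40`).
#' @param m fuzzifier; default estimated.
#' @param seed seed for the fits.
#' @param n_restarts restarts per k (default 3 — the diagnostic tolerates
#'   rougher fits than the final model).
#' @return data.frame of class `"dmin_profile"` with columns `k`, `dmin`.
#' @export
dmin_profile <- function(x, k_range, m = NULL, seed = NULL, n_restarts = 3) {
  x <- as.matrix(x)
  if (is.null(m)) m <- estimate_fuzzifier(nrow(x), ncol(x))
  if (any(k_range < 2) || any(k_range >= nrow(x))) {
    stop("k_range must lie within [2, n_genes - 1]")
  }
  dmin <- vapply(seq_along(k_range), function(i) {
    fit <- fcm(x, k_range[i], m = m,
               seed = if (is.null(seed)) NULL else seed + i,
               n_restarts = n_restarts)
    min(stats::dist(fit$centroids))
  }, numeric(1))
  structure(data.frame(k = as.integer(k_range), dmin = dmin),
            class = c("dmin_profile", "data.frame"))
}

#' Choose the number of clusters
#'
#' With `override` given (the package default analysis uses 12), returns it
#' unchanged. Otherwise applies an elbow rule to the Dmin profile: the first
#' k whose relative Dmin decrease to k + 1 falls below `flat_fraction`; a
#' profile flat from the start returns the smallest k.
#'
#' @param profile a `"dmin_profile"` data.frame (consecutive k values).
#' @param override fixed cluster number short-circuiting the rule.
#' @param flat_fraction relative-decrease threshold (default 0.1).
#' @return Integer cluster number.
#' @export
select_k <- function(profile, override = NULL, flat_fraction = 0.1) {
  if (!is.null(override)) return(as.integer(override))
  if (is.null(profile) || !nrow(profile)) stop("empty Dmin profile and no override")
  profile <- profile[order(profile$k), , drop = FALSE]
  if (nrow(profile) == 1) return(profile$k[1])
  rel_drop <- (profile$dmin[-nrow(profile)] - profile$dmin[-1]) /
    pmax(profile$dmin[-nrow(profile)], 1e-12)
  # strict "falls below", robust to floating-point representation of the ratio
  flat <- which(rel_drop < flat_fraction - 1e-9)
  if (length(flat)) profile$k[flat[1]] else profile$k[nrow(profile)]
}

#' Condense minor clusters into major temporal phases
#'
#' Maps each centroid to a major phase of sporophyte development by its peak
#' stage: stage 1 is early (MC1), stages 2-3 intermediate (MC2), stage 4 late
#' (MC3). A centroid with two local maxima at non-adjacent stages whose
#' heights differ by less than `bimodal_tol` has no single expression peak
#' and is left unassigned.
#'
#' @param model an `"fcm"` model (or a centroids matrix) over 4 stages.
#' @param bimodal_tol height difference below which two non-adjacent local
#'   maxima make a centroid unassignable (default 0.1, standardized scale).
#' @return Character vector over minor clusters with values `"MC1_early"`,
#'   `"MC2_mid"`, `"MC3_late"` or `"unassigned"`.
#' @export
assign_major_clusters <- function(model, bimodal_tol = 0.1) {
  cent <- if (inherits(model, "fcm")) model$centroids else as.matrix(model)
  if (ncol(cent) != 4) stop("major-cluster assignment is defined for 4 stages")
  vapply(seq_len(nrow(cent)), function(j) {
    v <- cent[j, ]
    is_max <- vapply(1:4, function(s) {
      left <- if (s > 1) v[s] >= v[s - 1] else TRUE
      right <- if (s < 4) v[s] >= v[s + 1] else TRUE
      left && right
    }, logical(1))
    peaks <- which(is_max)
    if (length(peaks) >= 2) {
      pairs <- utils::combn(peaks, 2)
      nonadj <- pairs[, pairs[2, ] - pairs[1, ] > 1, drop = FALSE]
      if (ncol(nonadj) > 0 &&
          any(abs(v[nonadj[1, ]] - v[nonadj[2, ]]) < bimodal_tol)) {
        return("unassigned")
      }
    }
    peak <- which.max(v)
    c("MC1_early", "MC2_mid", "MC2_mid", "MC3_late")[peak]
  }, character(1))
}

#' Classify ortholog pairs as conserved or heterochronic
#'
#' Joins the native-species cluster assignments with the projected
#' assignments of the other species' orthologs, condenses both through the
#' major-cluster map, and calls each pair conserved (same major phase),
#' heterochronic (different major phases) or excluded (either gene in an
#' unassigned minor cluster, below the membership floor, or absent from the
#' assignments).
#'
#' @param assign_a,assign_b lists with elements `cluster` (integer minor
#'   cluster per gene) and `max_membership`, named or ordered by
#'   `pairs$gene_a` / `pairs$gene_b` — the model-side assignment (e.g.
#'   `model["cluster"]`-style fields of [fcm()]) and the [predict.fcm()]
#'   output. Gene ids are taken from `gene_ids`/`rownames` when present,
#'   otherwise positionally from `pairs`.
#' @param major_map character vector from [assign_major_clusters()].
#' @param pairs one-to-one ortholog data.frame with `gene_a`, `gene_b`.
#' @param membership_min minimum max-membership for a confident assignment
#'   (default 0.3).
#' @return List of class `"shift_table"`: `table` (per-pair data.frame with
#'   minor/major cluster and membership in each species and `call`) and
#'   `summary` (counts and percentages of conserved/heterochronic among
#'   classified pairs, plus the excluded count).
#' @export
classify_shifts <- function(assign_a, assign_b, major_map, pairs,
                            membership_min = 0.3) {
  get_ids <- function(a, fallback) {
    if (!is.null(a$gene_ids)) a$gene_ids
    else if (!is.null(rownames(a$memberships))) rownames(a$memberships)
    else fallback
  }
  ids_a <- get_ids(assign_a, pairs$gene_a)
  ids_b <- get_ids(assign_b, pairs$gene_b)
  ia <- match(pairs$gene_a, ids_a)
  ib <- match(pairs$gene_b, ids_b)
  minor_a <- assign_a$cluster[ia]
  minor_b <- assign_b$cluster[ib]
  mem_a <- assign_a$max_membership[ia]
  mem_b <- assign_b$max_membership[ib]
  major_a <- ifelse(is.na(minor_a), NA_character_, major_map[minor_a])
  major_b <- ifelse(is.na(minor_b), NA_character_, major_map[minor_b])
  excluded <- is.na(minor_a) | is.na(minor_b) |
    major_a == "unassigned" | major_b == "unassigned" |
    mem_a < membership_min | mem_b < membership_min
  call <- ifelse(excluded, "excluded",
                 ifelse(major_a == major_b, "conserved", "heterochronic"))
  tab <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    minor_a = minor_a, minor_b = minor_b,
                    membership_a = mem_a, membership_b = mem_b,
                    major_a = major_a, major_b = major_b,
                    call = call, stringsAsFactors = FALSE)
  n_class <- sum(call != "excluded")
  summary <- data.frame(
    call = c("conserved", "heterochronic", "excluded"),
    n = c(sum(call == "conserved"), sum(call == "heterochronic"), sum(call == "excluded")),
    percent = c(100 * sum(call == "conserved") / max(n_class, 1),
                100 * sum(call == "heterochronic") / max(n_class, 1), NA))
  structure(list(table = tab, summary = summary), class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("Heterochronic-shift table: %d ortholog pairs\n", nrow(x$table)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Contrast shift proportions between transcription factors and other genes
#'
#' 2x2 Pearson chi-square (no continuity correction) of conserved vs
#' heterochronic calls between transcription-factor-encoding ortholog pairs
#' and all remaining classified pairs. A pair counts as a TF pair when either
#' member is on the list.
#'
#' @param shifts a `"shift_table"` from [classify_shifts()].
#' @param tf_genes character vector of transcription-factor gene ids.
#' @return A `"contingency_result"` (see [pearson_chi_square()]).
#' @export
tf_subset_comparison <- function(shifts, tf_genes) {
  tab <- shifts$table
  tab <- tab[tab$call != "excluded", , drop = FALSE]
  is_tf <- tab$gene_a %in% tf_genes | tab$gene_b %in% tf_genes
  if (!any(is_tf)) stop("no classified ortholog pair involves a listed transcription factor")
  obs <- matrix(c(sum(is_tf & tab$call == "conserved"),
                  sum(is_tf & tab$call == "heterochronic"),
                  sum(!is_tf & tab$call == "conserved"),
                  sum(!is_tf & tab$call == "heterochronic")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("TF", "non_TF"), c("conserved", "heterochronic")))
  pearson_chi_square(obs)
}
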