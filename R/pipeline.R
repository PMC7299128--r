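#' Pipeline configuration
#'
#' Collects the inputs and thresholds of the full cross-species analysis.
#' All thresholds default to the canonical values used throughout the
#' package: log2 fold change 2 and FDR 0.05 for preferential sporophyte
#' expression, E-value 1e-6 / 80% query coverage / 35% similarity for
#' homology hits, membership floor 0.3 for confident cluster assignment, and
#' 12 clusters.
#'
#' @param species the two species labels; the first is clustered natively,
#'   the second projected.
#' @param counts_a,samples_a,counts_b,samples_b paths to the count matrices
#'   and sample sheets.
#' @param orthogroups path to the orthogroup TSV.
#' @param hits_ab,hits_ba optional paths to proteome-vs-proteome hit tables
#'   (A query vs B subject and vice versa).
#' @param genome_hits_ab,genome_hits_ba optional protein-vs-genome hit
#'   tables used for the rescue step.
#' @param qlen_a,qlen_b optional query-length tables (needed when hit files
#'   lack a 13th column).
#' @param go_obo,go_annotations_a,go_annotations_b optional GO inputs.
#' @param tf_list optional path to a transcription-factor gene list (one id
#'   per line, either species).
#' @param lfc,fdr preferential-expression thresholds.
#' @param evalue,coverage,similarity homology hit filters.
#' @param membership_min cluster-assignment confidence floor.
#' @param k cluster-number override (`NULL`: choose by the Dmin elbow over
#'   `k_range`).
#' @param k_range candidate cluster numbers for [dmin_profile()].
#' @param fuzzifier override for m (`NULL`: estimated from the data).
#' @param seed integer seed for the clustering restarts.
#' @param output_dir where [run_pipeline()] writes its tables (`NULL`: no
#'   files, results returned only).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(species,
                            counts_a, samples_a, counts_b, samples_b,
                            orthogroups,
                            hits_ab = NULL, hits_ba = NULL,
                            genome_hits_ab = NULL, genome_hits_ba = NULL,
                            qlen_a = NULL, qlen_b = NULL,
                            go_obo = NULL, go_annotations_a = NULL,
                            go_annotations_b = NULL, tf_list = NULL,
                            lfc = 2, fdr = 0.05,
                            evalue = 1e-6, coverage = 0.80, similarity = 35,
                            membership_min = 0.3,
                            k = 12, k_range = 4:40, fuzzifier = NULL,
                            seed = 1, output_dir = NULL) {
  if (length(species) != 2 || anyDuplicated(species)) {
    stop("exactly two distinct species labels required")
  }
  if (lfc < 0 || fdr <= 0 || fdr > 1 || evalue < 0 ||
      coverage < 0 || coverage > 1 || similarity < 0 || similarity > 100 ||
      membership_min < 0 || membership_min > 1) {
    stop("a threshold is outside its valid range")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path path to the YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$species <- unlist(vals$species)
  do.call(pipeline_config, vals)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full cross-species analysis
#'
#' Executes, per species: low-count filtering, size-factor estimation, NB
#' differential expression (sporophyte vs gametophyte) and the preferential
#' gene set; then homology classification (orthogroups, protein hits, genome
#' rescue) with the species-specific enrichment chi-square; the expression
#' landscape (PCAs over the full/homologous/species-specific gene sets and
#' the cross-species Spearman divergence matrix); fuzzy c-means clustering
#' of species A ortholog profiles with projection of species B, major-phase
#' condensation and heterochronic-shift classification; optionally the
#' transcription-factor contrast and parent-child GO enrichment. With
#' `output_dir` set, every result table plus a run manifest is written as
#' TSV; identical config and seed give identical outputs.
#'
#' @param config a `"pipeline_config"`.
#' @return List of class `"pipeline_result"` with the per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  res <- list(config = cfg)

  counts <- .run_stage("read", {
    list(a = read_count_matrix(cfg$counts_a, cfg$samples_a),
         b = read_count_matrix(cfg$counts_b, cfg$samples_b))
  })
  .stage_log("read", "counts: %d x %d (%s), %d x %d (%s)",
             nrow(counts$a$counts), ncol(counts$a$counts), cfg$species[1],
             nrow(counts$b$counts), ncol(counts$b$counts), cfg$species[2])

  de <- .run_stage("de", {
    lapply(counts, function(cm) {
      cm <- filter_low_counts(cm)
      sf <- estimate_size_factors(cm)
      tab <- nb_wald_test(cm, sf, cm$samples$phase, numerator = "sporophyte")
      list(counts = cm, size_factors = sf, table = tab,
           preferential = preferential_sporophyte_set(tab, cfg$lfc, cfg$fdr))
    })
  })
  res$de <- de
  .stage_log("de", "expressed %d/%d; preferential %d/%d",
             nrow(de$a$counts$counts), nrow(de$b$counts$counts),
             length(de$a$preferential), length(de$b$preferential))

  homology <- .run_stage("homology", {
    og <- read_orthogroups(cfg$orthogroups, cfg$species)
    load_hits <- function(path, qlen_path) {
      if (is.null(path)) return(NULL)
      h <- read_hit_table(path)
      ql <- if (!is.null(qlen_path)) read_query_lengths(qlen_path) else NULL
      filter_hits(h, ql, max_evalue = cfg$evalue,
                  min_coverage = cfg$coverage, min_similarity = cfg$similarity)
    }
    cls <- function(cm, species, hits, genome_hits) {
      k <- classify_genes(rownames(cm$counts), species, og, hits)
      rescue_with_genome_hits(k, genome_hits)
    }
    class_a <- cls(de$a$counts, cfg$species[1],
                   load_hits(cfg$hits_ab, cfg$qlen_a),
                   load_hits(cfg$genome_hits_ab, cfg$qlen_a))
    class_b <- cls(de$b$counts, cfg$species[2],
                   load_hits(cfg$hits_ba, cfg$qlen_b),
                   load_hits(cfg$genome_hits_ba, cfg$qlen_b))
    list(orthogroups = og, class_a = class_a, class_b = class_b,
         pairs = extract_one_to_one(og, cfg$species[1], cfg$species[2]),
         enrichment_a = chi_square_enrichment(class_a, de$a$preferential),
         enrichment_b = chi_square_enrichment(class_b, de$b$preferential))
  })
  res$homology <- homology
  .stage_log("homology", "one-to-one pairs: %d; homologous: %d (%s), %d (%s)",
             nrow(homology$pairs),
             sum(homology$class_a$label == "homologous"), cfg$species[1],
             sum(homology$class_b$label == "homologous"), cfg$species[2])

  landscape <- .run_stage("landscape", {
    one <- function(side, classification) {
      cm <- de[[side]]$counts
      sf <- de[[side]]$size_factors
      spo <- cm$samples$phase == "sporophyte"
      obs <- t(sweep(cm$counts[, spo, drop = FALSE], 2, sf[spo], "/"))
      hom <- classification$gene_id[classification$label == "homologous"]
      spec <- classification$gene_id[classification$label == "species_specific"]
      list(stage_means = stage_means(cm, sf),
           pca_all = expression_pca(obs),
           pca_homolog = if (length(hom) >= 2) expression_pca(obs, hom) else NULL,
           pca_specific = if (length(spec) >= 2) expression_pca(obs, spec) else NULL)
    }
    la <- one("a", homology$class_a)
    lb <- one("b", homology$class_b)
    list(a = la, b = lb,
         divergence = spearman_divergence(la$stage_means, lb$stage_means,
                                          homology$pairs))
  })
  res$landscape <- landscape
  .stage_log("landscape", "divergence matrix %dx%d",
             nrow(landscape$divergence$rho), ncol(landscape$divergence$rho))

  clustering <- .run_stage("cluster", {
    pairs <- homology$pairs
    pairs <- pairs[pairs$gene_a %in% rownames(landscape$a$stage_means) &
                   pairs$gene_b %in% rownames(landscape$b$stage_means), , drop = FALSE]
    prof_a <- standardize_profiles(landscape$a$stage_means[pairs$gene_a, , drop = FALSE])
    prof_b <- standardize_profiles(landscape$b$stage_means[pairs$gene_b, , drop = FALSE])
    pairs <- pairs[pairs$gene_a %in% rownames(prof_a) &
                   pairs$gene_b %in% rownames(prof_b), , drop = FALSE]
    prof_a <- prof_a[pairs$gene_a, , drop = FALSE]
    prof_b <- prof_b[pairs$gene_b, , drop = FALSE]
    m <- if (is.null(cfg$fuzzifier)) estimate_fuzzifier(nrow(prof_a), ncol(prof_a)) else cfg$fuzzifier
    if (is.null(cfg$k)) {
      prof <- dmin_profile(prof_a, cfg$k_range, m = m, seed = cfg$seed)
      k <- select_k(prof)
    } else {
      prof <- NULL
      k <- cfg$k
    }
    model <- fcm(prof_a, k, m = m, seed = cfg$seed)
    projection <- predict(model, prof_b)
    major_map <- assign_major_clusters(model)
    shifts <- classify_shifts(
      list(cluster = model$cluster, max_membership = model$max_membership,
           gene_ids = model$gene_ids),
      list(cluster = projection$cluster, max_membership = projection$max_membership,
           gene_ids = rownames(prof_b)),
      major_map, pairs, membership_min = cfg$membership_min)
    out <- list(model = model, projection = projection, major_map = major_map,
                dmin = prof, k = k, m = m, shifts = shifts, pairs = pairs)
    if (!is.null(cfg$tf_list)) {
      tf <- readLines(cfg$tf_list)
      tf <- trimws(tf[nzchar(trimws(tf))])
      out$tf_contrast <- tf_subset_comparison(shifts, tf)
    }
    out
  })
  res$clustering <- clustering
  .stage_log("cluster", "k = %d, m = %.3f, %d orthologs clustered; %s",
             clustering$k, clustering$m, nrow(clustering$pairs),
             paste(sprintf("%s %d", clustering$shifts$summary$call,
                           clustering$shifts$summary$n), collapse = ", "))

  if (!is.null(cfg$go_obo)) {
    res$go <- .run_stage("enrich", {
      dag <- read_obo(cfg$go_obo)
      one <- function(ann_path, side, classification) {
        if (is.null(ann_path)) return(NULL)
        ann <- propagate_annotations(dag, read_gene_annotations(ann_path))
        universe <- rownames(de[[side]]$counts$counts)
        study <- de[[side]]$preferential
        hom <- classification$gene_id[classification$label == "homologous"]
        list(homolog = parent_child_fisher(dag, ann, intersect(study, hom), universe),
             specific = parent_child_fisher(dag, ann, setdiff(study, hom), universe))
      }
      list(dag = dag,
           a = one(cfg$go_annotations_a, "a", homology$class_a),
           b = one(cfg$go_annotations_b, "b", homology$class_b))
    })
    .stage_log("enrich", "GO DAG: %d terms", length(res$go$dag$term_ids))
  }

  class(res) <- "pipeline_result"
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(res, cfg$output_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(df, name) write_table(df, file.path(dir, name))
  out(res$de$a$table, "de_results_a.tsv")
  out(res$de$b$table, "de_results_b.tsv")
  out(as.data.frame(res$homology$class_a), "classification_a.tsv")
  out(as.data.frame(res$homology$class_b), "classification_b.tsv")
  out(res$homology$pairs, "one_to_one.tsv")
  cent <- res$clustering$model$centroids
  out(data.frame(cluster = seq_len(nrow(cent)),
                 major = res$clustering$major_map, cent, check.names = FALSE),
      "cluster_model.tsv")
  out(res$clustering$shifts$table, "shift_table.tsv")
  out(res$clustering$shifts$summary, "shift_summary.tsv")
  div <- res$landscape$divergence$rho
  out(data.frame(stage_a = rownames(div), div, check.names = FALSE),
      "divergence_matrix.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("sporoshift")),
    r_version = as.character(getRversion()),
    seed = res$config$seed,
    species = res$config$species,
    thresholds = list(lfc = res$config$lfc, fdr = res$config$fdr,
                      evalue = res$config$evalue, coverage = res$config$coverage,
                      similarity = res$config$similarity,
                      membership_min = res$config$membership_min),
    k = res$clustering$k, m = res$clustering$m)
  yaml::write_yaml(manifest, file.path(dir, "run_manifest.yaml"))
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Cross-species pipeline result\n")
  print(report(x), row.names = FALSE)
  invisible(x)
}

#' Summary report of a pipeline run
#'
#' Per species: expressed and preferential gene counts and percentages,
#' homologous vs species-specific proportions overall and within the
#' preferential set, the enrichment chi-square, plus the shared clustering
#' outcome (orthologs clustered, conserved/heterochronic percentages and,
#' when a TF list was supplied, the TF-contrast chi-square).
#'
#' @param result a `"pipeline_result"`.
#' @return data.frame with one row per reported quantity (`metric`,
#'   one column per species or `shared`).
#' @export
report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  de <- result$de; hom <- result$homology; cl <- result$clustering
  one <- function(side, classification, enrichment) {
    n_exp <- nrow(de[[side]]$counts$counts)
    n_pref <- length(de[[side]]$preferential)
    n_hom <- sum(classification$label == "homologous")
    pref_hom <- sum(de[[side]]$preferential %in%
                      classification$gene_id[classification$label == "homologous"])
    c(n_expressed = n_exp,
      n_preferential = n_pref,
      pct_preferential = round(100 * n_pref / n_exp, 1),
      pct_homologous = round(100 * n_hom / n_exp, 1),
      pct_homologous_in_preferential = round(100 * pref_hom / max(n_pref, 1), 1),
      enrichment_chi2 = round(enrichment$chi2, 2))
  }
  a <- one("a", hom$class_a, hom$enrichment_a)
  b <- one("b", hom$class_b, hom$enrichment_b)
  s <- cl$shifts$summary
  n_class <- sum(s$n[s$call != "excluded"])
  shared <- c(n_pairs_clustered = nrow(cl$pairs),
              n_classified = n_class,
              pct_conserved = round(s$percent[s$call == "conserved"], 1),
              pct_heterochronic = round(s$percent[s$call == "heterochronic"], 1),
              tf_contrast_chi2 = if (!is.null(cl$tf_contrast)) round(cl$tf_contrast$chi2, 2) else NA)
  metrics <- union(names(a), names(shared))
  df <- data.frame(metric = metrics,
                   a = a[metrics], b = b[metrics], shared = shared[metrics],
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df) <- c("metric", result$config$species, "shared")
  df
}
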