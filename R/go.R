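#' Read a GO DAG from an OBO file
#'
#' Minimal reader for the OBO flat-file format: `[Term]` stanzas with `id`,
#' `name`, `namespace` and `is_a` lines (trailing `! comment` stripped);
#' obsolete terms are skipped. Only the is_a hierarchy is retained, which is
#' what the parent-child enrichment test conditions on.
#'
#' @param path path to the .obo file.
#' @return Object of class `"go_dag"` (see [go_dag()]).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); names_ <- character(0); ns <- character(0)
  parents <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      sub("\\s*!.*$", "", trimws(sub(paste0("^", key, ":\\s*"), "", v)))
    }
    if (length(get("is_obsolete")) && any(get("is_obsolete") == "true")) next
    id <- get("id")[1]
    if (is.na(id) || !length(id)) next
    ids <- c(ids, id)
    nm <- get("name"); names_ <- c(names_, if (length(nm)) nm[1] else NA_character_)
    n1 <- get("namespace"); ns <- c(ns, if (length(n1)) n1[1] else NA_character_)
    parents[[id]] <- get("is_a")
  }
  go_dag(ids, parents[ids], namespace = ns, term_name = names_)
}

#' Construct a GO DAG
#'
#' @param term_ids character vector of term ids.
#' @param parents named list: per term, character vector of is_a parent ids
#'   (empty for roots). Must be acyclic; parents must themselves be terms.
#' @param namespace optional namespace per term (e.g.
#'   `"biological_process"`).
#' @param term_name optional human-readable name per term.
#' @return Object of class `"go_dag"`.
#' @export
go_dag <- function(term_ids, parents, namespace = NULL, term_name = NULL) {
  term_ids <- as.character(term_ids)
  parents <- lapply(term_ids, function(t) {
    p <- parents[[t]]
    if (is.null(p)) character(0) else as.character(p)
  })
  names(parents) <- term_ids
  unknown <- setdiff(unlist(parents, use.names = FALSE), term_ids)
  if (length(unknown)) stop("is_a parent(s) not defined as terms: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  dag <- structure(list(term_ids = term_ids, parents = parents,
                        namespace = if (is.null(namespace)) rep(NA_character_, length(term_ids)) else namespace,
                        term_name = if (is.null(term_name)) rep(NA_character_, length(term_ids)) else term_name),
                   class = "go_dag")
  # cycle check via ancestor closure (errors on infinite recursion depth)
  invisible(term_ancestors(dag))
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms (%d roots)\n", length(x$term_ids),
              sum(lengths(x$parents) == 0)))
  invisible(x)
}

#' Ancestors of every term
#'
#' Transitive closure over is_a links, excluding the term itself.
#'
#' @param dag a `"go_dag"`.
#' @return Named list: per term, character vector of all ancestors.
#' @export
term_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  on_path <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (!is.null(on_path[[t]])) stop("cycle detected at term ", t)
    on_path[[t]] <- TRUE
    p <- dag$parents[[t]]
    res <- unique(c(p, unlist(lapply(p, anc), use.names = FALSE)))
    rm(list = t, envir = on_path)
    memo[[t]] <- res
    res
  }
  out <- lapply(dag$term_ids, anc)
  names(out) <- dag$term_ids
  out
}

#' Propagate gene annotations up the DAG
#'
#' True-path rule: a gene annotated to a term is annotated to all of the
#' term's ancestors; duplicates are removed.
#'
#' @param dag a `"go_dag"`.
#' @param gene2term named list (gene id -> character vector of term ids) or
#'   a two-column data.frame (gene, term).
#' @return Named list gene -> sorted unique term ids including all ancestors.
#' @export
propagate_annotations <- function(dag, gene2term) {
  if (is.data.frame(gene2term)) {
    gene2term <- split(as.character(gene2term[[2]]), as.character(gene2term[[1]]))
  }
  unknown <- setdiff(unique(unlist(gene2term, use.names = FALSE)), dag$term_ids)
  if (length(unknown)) {
    stop("annotation references unknown term(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  anc <- term_ancestors(dag)
  lapply(gene2term, function(terms) {
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
}

#' Read a gene-to-GO annotation table
#'
#' Two-column TSV without header: gene id, term id (one pair per line).
#'
#' @param path path to the TSV.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
read_gene_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation table must have two columns: gene, term")
  data.frame(gene_id = as.character(df[[1]]), term_id = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Parent-child GO term enrichment
#'
#' For each term, tests over-representation of study genes among the genes
#' annotated to the term's parents (parent-child-union: the parents' gene
#' sets are pooled by union), rather than against the whole universe — this
#' discounts enrichment inherited from a parent. The p-value is the
#' hypergeometric upper tail of drawing at least the observed number of
#' term-annotated study genes when sampling the study genes found in the
#' parent pool. Terms without parents (roots) get p = 1.
#'
#' @param dag a `"go_dag"`.
#' @param annotations propagated gene -> terms list (see
#'   [propagate_annotations()]).
#' @param study character vector of study gene ids (must be within
#'   `universe`).
#' @param universe character vector: all genes with detectable expression.
#' @param namespace restrict to terms of this namespace (default
#'   `"biological_process"`; `NULL` keeps all).
#' @return data.frame of class `"go_enrichment"` with columns `term_id`,
#'   `term_name`, `study_count`, `population_count`,
#'   `parent_population_count`, `parent_study_count`, `p`, `enriched`
#'   (p <= 0.05).
#' @export
parent_child_fisher <- function(dag, annotations, study, universe,
                                namespace = "biological_process") {
  bad <- setdiff(study, universe)
  if (length(bad)) stop("study gene(s) outside the universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  annotations <- annotations[intersect(names(annotations), universe)]
  term_genes <- new.env(parent = emptyenv())
  for (g in names(annotations)) {
    for (t in annotations[[g]]) term_genes[[t]] <- c(term_genes[[t]], g)
  }
  keep <- dag$term_ids
  if (!is.null(namespace)) keep <- keep[dag$namespace %in% namespace | is.na(dag$namespace)]
  study <- unique(study)
  rows <- lapply(keep, function(t) {
    genes_t <- unique(term_genes[[t]])
    study_count <- length(intersect(genes_t, study))
    parents <- dag$parents[[t]]
    if (!length(parents)) {
      return(data.frame(term_id = t, study_count = study_count,
                        population_count = length(genes_t),
                        parent_population_count = NA_integer_,
                        parent_study_count = NA_integer_,
                        p = 1, stringsAsFactors = FALSE))
    }
    pool <- unique(unlist(lapply(parents, function(p) term_genes[[p]]), use.names = FALSE))
    genes_t_pool <- intersect(genes_t, pool)
    draws <- length(intersect(study, pool))
    obs <- length(intersect(genes_t_pool, study))
    p <- if (draws == 0 || length(genes_t_pool) == length(pool)) 1 else {
      stats::phyper(obs - 1, length(genes_t_pool),
                    length(pool) - length(genes_t_pool), draws,
                    lower.tail = FALSE)
    }
    data.frame(term_id = t, study_count = study_count,
               population_count = length(genes_t),
               parent_population_count = length(pool),
               parent_study_count = draws, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$term_name <- dag$term_name[match(out$term_id, dag$term_ids)]
  out$enriched <- out$p <= 0.05
  out <- out[, c("term_id", "term_name", "study_count", "population_count",
                 "parent_population_count", "parent_study_count", "p", "enriched")]
  class(out) <- c("go_enrichment", "data.frame")
  out
}

#' Keep significantly enriched terms
#'
#' @param results a `"go_enrichment"` data.frame.
#' @param alpha p-value cutoff, inclusive (default 0.05).
#' @return The rows with `p <= alpha`, sorted ascending by p.
#' @export
filter_enriched <- function(results, alpha = 0.05) {
  out <- results[!is.na(results$p) & results$p <= alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
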