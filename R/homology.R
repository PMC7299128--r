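#' Filter alignment hits for credible homology
#'
#' Keeps hits satisfying all three of: E-value at or below `max_evalue`
#' (default 1e-6), query coverage at or above `min_coverage` (default 0.80)
#' and percent similarity at or above `min_similarity` (default 35). Query
#' coverage is the aligned query span `(q_end - q_start + 1) / query_length`
#' (positions 1-based inclusive); multiple hits per query are judged
#' independently.
#'
#' @param hits a `"hit_table"` data.frame from [read_hit_table()].
#' @param query_lengths named vector of query lengths; may be omitted when
#'   the table carries a `query_length` column.
#' @param max_evalue,min_coverage,min_similarity the three thresholds.
#' @return The rows of `hits` passing all filters, with `coverage` added.
#' @export
filter_hits <- function(hits, query_lengths = NULL,
                        max_evalue = 1e-6, min_coverage = 0.80,
                        min_similarity = 35) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (!nrow(hits)) {
    hits$coverage <- numeric(0)
    return(hits)
  }
  if (is.null(hits$query_length)) {
    if (is.null(query_lengths)) {
      stop("query lengths required for coverage filtering: supply query_lengths or a 13-column hit table")
    }
    qlen <- query_lengths[hits$query_id]
    if (anyNA(qlen)) {
      stop("missing query length for query ", hits$query_id[which(is.na(qlen))[1]])
    }
    hits$query_length <- as.numeric(qlen)
  }
  hits$coverage <- (hits$q_end - hits$q_start + 1) / hits$query_length
  keep <- hits$evalue <= max_evalue &
    hits$coverage >= min_coverage &
    hits$percent_similarity >= min_similarity
  hits[keep, , drop = FALSE]
}

#' Classify genes as homologous or species-specific
#'
#' A gene is homologous when its orthogroup contains at least one gene of the
#' other species; failing that, when it has a passing protein hit against the
#' other species' proteome; otherwise it is species-specific. Evidence
#' records the first satisfied rule, orthogroup membership taking precedence.
#'
#' @param gene_ids character vector: the gene universe of `species`.
#' @param species the species these genes belong to.
#' @param orthogroups an `"orthogroup_table"` covering (at least) the two
#'   focal species.
#' @param passing_hits filtered hit table (see [filter_hits()]) of `species`
#'   proteins vs the other species' proteome; may be `NULL`.
#' @param other_species the alternate species label; defaults to the other
#'   label in `orthogroups$species`.
#' @return data.frame of class `"homology_classification"` with columns
#'   `gene_id`, `species`, `label` (`"homologous"`/`"species_specific"`) and
#'   `evidence` (`"orthogroup"`, `"protein_hit"` or `"none"`).
#' @export
classify_genes <- function(gene_ids, species, orthogroups, passing_hits = NULL,
                           other_species = NULL) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  if (is.null(other_species)) {
    other_species <- setdiff(orthogroups$species, species)[1]
  }
  if (is.na(other_species)) stop("cannot determine the alternate species")
  shared_og <- vapply(orthogroups$genes_by_species,
                      function(g) length(g[[other_species]]) > 0, logical(1))
  genes_in_shared <- unlist(lapply(orthogroups$genes_by_species[shared_og],
                                   function(g) g[[species]]), use.names = FALSE)
  has_og <- gene_ids %in% genes_in_shared
  has_hit <- if (!is.null(passing_hits) && nrow(passing_hits)) {
    gene_ids %in% passing_hits$query_id
  } else rep(FALSE, length(gene_ids))
  evidence <- ifelse(has_og, "orthogroup", ifelse(has_hit, "protein_hit", "none"))
  out <- data.frame(gene_id = gene_ids, species = species,
                    label = ifelse(evidence == "none", "species_specific", "homologous"),
                    evidence = evidence, stringsAsFactors = FALSE)
  class(out) <- c("homology_classification", "data.frame")
  out
}

#' Rescue species-specific calls with protein-vs-genome hits
#'
#' Genes called species-specific whose protein has a passing hit against the
#' other species' *genome* sequence (same E-value/coverage/similarity
#' filters) are promoted to homologous with evidence `"genome_rescue"`;
#' already-homologous genes are untouched, so the step is idempotent.
#'
#' @param classification a `"homology_classification"` data.frame.
#' @param passing_genome_hits filtered protein-vs-genome hit table.
#' @return The updated classification.
#' @export
rescue_with_genome_hits <- function(classification, passing_genome_hits) {
  stopifnot(inherits(classification, "homology_classification"))
  if (is.null(passing_genome_hits) || !nrow(passing_genome_hits)) return(classification)
  rescue <- classification$label == "species_specific" &
    classification$gene_id %in% passing_genome_hits$query_id
  classification$label[rescue] <- "homologous"
  classification$evidence[rescue] <- "genome_rescue"
  classification
}

#' Extract one-to-one orthologs
#'
#' Returns the pairs from orthogroups containing exactly one gene of each of
#' the two focal species (other species in the table, if any, are ignored).
#'
#' @param orthogroups an `"orthogroup_table"`.
#' @param species_a,species_b the two focal species; default the table's
#'   first two.
#' @return data.frame with columns `orthogroup_id`, `gene_a`, `gene_b`.
#' @export
extract_one_to_one <- function(orthogroups, species_a = NULL, species_b = NULL) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  if (is.null(species_a)) species_a <- orthogroups$species[1]
  if (is.null(species_b)) species_b <- orthogroups$species[2]
  single <- vapply(orthogroups$genes_by_species, function(g) {
    length(g[[species_a]]) == 1 && length(g[[species_b]]) == 1
  }, logical(1))
  data.frame(
    orthogroup_id = orthogroups$orthogroup_id[single],
    gene_a = vapply(orthogroups$genes_by_species[single], function(g) g[[species_a]], character(1)),
    gene_b = vapply(orthogroups$genes_by_species[single], function(g) g[[species_b]], character(1)),
    stringsAsFactors = FALSE)
}

#' Pearson chi-square on a 2x2 table
#'
#' \eqn{\sum (O - E)^2 / E} with expected counts from the margins, no
#' continuity correction, 1 degree of freedom.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return Object of class `"contingency_result"`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p`.
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: a table margin is zero")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  structure(list(observed = tab, expected = expected, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 contingency test\n")
  print(x$observed)
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Enrichment of species-specific genes among preferential genes
#'
#' Builds the 2x2 table (rows: preferentially sporophyte-expressed or not;
#' columns: homologous or species-specific) over the classified gene universe
#' and applies the Pearson chi-square test.
#'
#' @param classification a `"homology_classification"` data.frame: the
#'   universe of expressed genes for one species.
#' @param preferential character vector of preferentially sporophyte-expressed
#'   gene ids (subset of the universe).
#' @return A `"contingency_result"` (see [pearson_chi_square()]), with the
#'   observed table carrying informative dimnames.
#' @export
chi_square_enrichment <- function(classification, preferential) {
  stopifnot(inherits(classification, "homology_classification"))
  pref <- classification$gene_id %in% preferential
  hom <- classification$label == "homologous"
  tab <- matrix(c(sum(pref & hom), sum(pref & !hom),
                  sum(!pref & hom), sum(!pref & !hom)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("preferential", "not_preferential"),
                                c("homologous", "species_specific")))
  pearson_chi_square(tab)
}
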