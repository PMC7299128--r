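#' Construct a validated count matrix
#'
#' Bundles an integer gene x sample count matrix with its sample metadata.
#' The sample sheet is the single source of truth for sample annotation: the
#' matrix columns must match `samples$sample_id` exactly and are reordered to
#' the sheet's order.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All cells must be non-negative
#'   integers.
#' @param samples data.frame with columns `sample_id`, `species`, `phase`
#'   (`"gametophyte"` or `"sporophyte"`), `stage` (1..4 for sporophyte
#'   samples, free label otherwise) and `replicate` (positive integer).
#' @return An object of class `"count_matrix"`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) {
    stop("duplicate gene id(s) in count matrix: ", paste(unique(dup), collapse = ", "))
  }
  samples <- validate_sample_sheet(samples)
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples)) {
    miss_in_sheet <- setdiff(colnames(counts), samples$sample_id)
    miss_in_counts <- setdiff(samples$sample_id, colnames(counts))
    stop("counts/sample sheet mismatch",
         if (length(miss_in_sheet)) paste0("; in counts only: ", paste(miss_in_sheet, collapse = ", ")),
         if (length(miss_in_counts)) paste0("; in sheet only: ", paste(miss_in_counts, collapse = ", ")))
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  check_integer_counts(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "species", "phase", "stage", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing)) stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (!all(samples$phase %in% c("gametophyte", "sporophyte"))) {
    stop("phase must be 'gametophyte' or 'sporophyte'")
  }
  spo <- samples$phase == "sporophyte"
  stage_num <- suppressWarnings(as.integer(as.character(samples$stage[spo])))
  if (any(is.na(stage_num)) || !all(stage_num >= 1)) {
    stop("sporophyte samples must carry an integer stage >= 1")
  }
  rep_num <- suppressWarnings(as.integer(samples$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1)) stop("replicate must be a positive integer")
  samples$replicate <- rep_num
  samples$stage <- as.character(samples$stage)
  rownames(samples) <- NULL
  samples
}

check_integer_counts <- function(counts) {
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  }
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$species), collapse = ", ")))
  tab <- table(x$samples$phase)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its sample sheet
#'
#' The counts file is TSV with a header row of sample ids and gene ids in the
#' first column; the sample sheet is TSV with columns `sample_id`, `species`,
#' `phase`, `stage`, `replicate`. Columns are reordered to sample-sheet order;
#' gene order is preserved as read.
#'
#' @param path_counts path to the genes x samples TSV.
#' @param path_samples path to the sample sheet TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path_counts, path_samples) {
  raw <- utils::read.delim(path_counts, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v) & !anyNA(body[[j]])) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric count '%s' at gene '%s', sample '%s'",
                   body[[j]][i], gene_ids[i], names(body)[j]))
    }
    body[[j]] <- v
  }
  mat <- as.matrix(body)
  rownames(mat) <- gene_ids
  samples <- utils::read.delim(path_samples, stringsAsFactors = FALSE)
  count_matrix(mat, samples)
}

#' Write a count matrix and sample sheet to TSV
#'
#' @param x a [count_matrix()].
#' @param path_counts,path_samples output paths.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, path_counts, path_samples) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path_counts)
  write_table(x$samples, path_samples)
  invisible(x)
}

.hit_columns <- c("query_id", "subject_id", "percent_similarity", "alignment_length",
                  "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bitscore")

#' Read a tabular protein alignment hit file
#'
#' Reads the 12-column tab-separated alignment format (BLAST `-outfmt 6`
#' dialect), optionally with a 13th `query_length` column. Positions are
#' 1-based inclusive. No filtering is applied at read time; see
#' [filter_hits()].
#'
#' @param path path to the hit table (no header).
#' @return data.frame of class `"hit_table"` with columns `query_id`,
#'   `subject_id`, `percent_similarity`, `alignment_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `evalue`,
#'   `bitscore`, and `query_length` when present in the file.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12), .hit_columns))
    class(df) <- c("hit_table", "data.frame")
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L || !(ncols[1] %in% c(12L, 13L))) {
    stop("hit table must have 12 (or 13, with query length) tab-separated columns; found ",
         paste(unique(ncols), collapse = "/"))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2], stringsAsFactors = FALSE)
  numeric_cols <- .hit_columns[-(1:2)]
  for (i in seq_along(numeric_cols)) {
    v <- suppressWarnings(as.numeric(m[, i + 2]))
    if (anyNA(v)) {
      stop(sprintf("unparseable numeric field '%s' in column %s of hit table",
                   m[which(is.na(v))[1], i + 2], numeric_cols[i]))
    }
    df[[numeric_cols[i]]] <- v
  }
  if (ncols[1] == 13L) {
    v <- suppressWarnings(as.numeric(m[, 13]))
    if (anyNA(v)) stop("unparseable query_length in hit table")
    df$query_length <- v
  }
  bad <- df$q_start > df$q_end
  if (any(bad)) stop("q_start > q_end for query ", df$query_id[which(bad)[1]])
  if (any(df$evalue < 0)) stop("negative evalue in hit table")
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read an orthogroup table
#'
#' Reads the `Orthogroups.tsv` dialect: a header line, an orthogroup-id
#' column, and one comma-separated gene-list column per species. Only the
#' columns named in `species` are consumed; empty cells become empty gene
#' lists. Each gene may belong to at most one orthogroup.
#'
#' @param path path to the TSV.
#' @param species character vector of species column names to keep.
#' @return Object of class `"orthogroup_table"`: list with `orthogroup_id`
#'   (character vector) and `genes_by_species` (per orthogroup, a named list
#'   of gene-id vectors, one entry per species).
#' @export
read_orthogroups <- function(path, species) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(species, names(df)[-1])
  if (length(missing)) stop("orthogroup table lacks species column(s): ",
                            paste(missing, collapse = ", "))
  og_ids <- as.character(df[[1]])
  genes <- lapply(seq_len(nrow(df)), function(i) {
    out <- lapply(species, function(sp) {
      cell <- df[[sp]][i]
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(out) <- species
    out
  })
  orthogroup_table(og_ids, genes, species)
}

#' Construct an orthogroup table
#'
#' @param orthogroup_id character vector of orthogroup ids.
#' @param genes_by_species list (one element per orthogroup) of named lists of
#'   gene-id character vectors, one per species.
#' @param species the species labels.
#' @return An `"orthogroup_table"` object.
#' @export
orthogroup_table <- function(orthogroup_id, genes_by_species, species) {
  stopifnot(length(orthogroup_id) == length(genes_by_species))
  all_genes <- unlist(genes_by_species, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup)) {
    stop("gene id(s) listed in more than one orthogroup: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  structure(list(orthogroup_id = as.character(orthogroup_id),
                 genes_by_species = genes_by_species,
                 species = species),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("orthogroup_table: %d orthogroups over species %s\n",
              length(x$orthogroup_id), paste(x$species, collapse = ", ")))
  invisible(x)
}

#' @export
length.orthogroup_table <- function(x) length(x$orthogroup_id)

#' Write an orthogroup table to TSV
#'
#' @param x an `"orthogroup_table"`.
#' @param path output path.
#' @return Invisibly, `x`.
#' @export
write_orthogroups <- function(x, path) {
  stopifnot(inherits(x, "orthogroup_table"))
  cols <- lapply(x$species, function(sp) {
    vapply(x$genes_by_species, function(g) paste(g[[sp]], collapse = ","), character(1))
  })
  df <- data.frame(Orthogroup = x$orthogroup_id, stats::setNames(cols, x$species),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
  invisible(x)
}

#' Write a data frame as TSV
#'
#' UTF-8, tab-separated, header row, newline-terminated, rows in input order.
#' Fields containing a tab or newline are rejected (there is no quoting in
#' the TSV dialect used throughout).
#'
#' @param records a data.frame.
#' @param path output path.
#' @return Invisibly, `records`.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (nm in names(records)) {
    v <- records[[nm]]
    if (is.character(v) || is.factor(v)) {
      if (any(grepl("[\t\n]", as.character(v)))) {
        stop("field in column '", nm, "' contains a tab or newline; cannot write TSV")
      }
    }
  }
  if (any(grepl("[\t\n]", names(records)))) stop("column name contains a tab or newline")
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(records)
}

#' Read a TSV written by [write_table()]
#'
#' @param path path to the file.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a query-length table
#'
#' Two-column TSV (no header): sequence id, length in residues. Used to
#' supply query lengths for coverage filtering when the hit table lacks a
#' 13th column.
#'
#' @param path path to the table.
#' @return Named numeric vector of lengths.
#' @export
read_query_lengths <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("query-length table must have two columns: id, length")
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(len) || any(len <= 0)) stop("query lengths must be positive numbers")
  stats::setNames(len, as.character(df[[1]]))
}
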