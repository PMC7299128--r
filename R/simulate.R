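#' Default temporal archetypes
#'
#' Twelve distinct stage-profile shapes over four sporophyte stages, given as
#' positive expression multipliers (each normalized to mean 1 so a gene's
#' overall sporophyte mean is unchanged by its archetype). Four shapes peak
#' at stage 1 (early phase), four at stages 2 or 3 (mid), four at stage 4
#' (late) — mirroring the early/intermediate/late condensation used for the
#' real clusters. The shapes were chosen to be mutually well separated after
#' row standardization (minimum pairwise Euclidean distance ~1.15 on the
#' z-score scale), so planted cluster labels are identifiable, and none has
#' two comparable non-adjacent peaks, so every archetype maps to a single
#' major phase.
#'
#' @return List with `profiles` (12 x 4 matrix) and `major` (character
#'   vector: `"MC1_early"`, `"MC2_mid"` or `"MC3_late"` per archetype).
#' @export
default_archetypes <- function() {
  raw <- rbind(
    c(1.7116, 0.2639, 1.1367, 0.8878),   # early spike, partial recovery
    c(1.5180, 1.2430, 0.1380, 1.1010),   # early peak, stage-3 trough
    c(1.5334, 1.2593, 1.0593, 0.1480),   # slow decline, late shutdown
    c(1.6670, 0.5150, 0.4710, 1.3470),   # early peak, late rebound
    c(0.1180, 1.4616, 1.2337, 1.1867),   # off early, then sustained
    c(0.8318, 1.8895, 0.6268, 0.6518),   # sharp stage-2 peak
    c(0.7788, 0.7298, 1.8925, 0.5989),   # sharp stage-3 peak
    c(0.9650, 0.1790, 1.5680, 1.2880),   # stage-2 trough, stage-3 peak
    c(0.6218, 0.7528, 0.7298, 1.8955),   # late spike
    c(0.8630, 1.3050, 0.2250, 1.6070),   # stage-3 trough, late peak
    c(1.1800, 0.2350, 0.9110, 1.6740),   # early dip, late accumulation
    c(0.2420, 0.8230, 1.3310, 1.6040))   # monotone rise
  profiles <- raw / rowMeans(raw)
  rownames(profiles) <- paste0("arch", seq_len(nrow(profiles)))
  colnames(profiles) <- as.character(1:4)
  major <- c(rep("MC1_early", 4), rep("MC2_mid", 4), rep("MC3_late", 4))
  list(profiles = profiles, major = major)
}

#' Simulation configuration
#'
#' Collects and validates the parameters of the two-species count simulator.
#' Defaults emulate the canonical study design: four sporophyte stages with
#' three replicates each, a handful of gametophyte reference samples, twelve
#' temporal archetypes grouped into early/mid/late phases, negative-binomial
#' counts with moderate biological dispersion, and planted fractions of
#' heterochronic shifts and sporophyte-preferential genes.
#'
#' @param n_shared_orthologs number of one-to-one ortholog pairs.
#' @param n_specific_per_species species-specific genes per species (these
#'   carry temporal archetypes like the orthologs).
#' @param n_flat_per_species stably expressed background genes per species
#'   (no temporal archetype, no cross-species homology evidence). Real
#'   transcriptomes are dominated by genes without strong stage dynamics;
#'   this majority is what makes median-of-ratios normalization well posed,
#'   so the generator emulates it.
#' @param n_stages sporophyte stages (>= 2; the major-phase machinery
#'   assumes 4).
#' @param n_replicates replicates per sporophyte stage.
#' @param n_gametophyte_samples gametophyte samples per species.
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param baseline_mean expected normalized count of an unperturbed gene.
#' @param archetypes list as from [default_archetypes()].
#' @param shift_fraction fraction of orthologs whose species-B archetype is
#'   moved to a different major phase (planted heterochrony).
#' @param de_fraction fraction of each species' genes planted as
#'   preferentially sporophyte-expressed.
#' @param de_log2fc planted sporophyte-vs-gametophyte log2 fold change.
#' @param seed integer seed; all randomness flows from it.
#' @param species the two species labels (species A is the one whose data
#'   get clustered natively).
#' @return Validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_shared_orthologs = 1000,
                              n_specific_per_species = 300,
                              n_flat_per_species = 2500,
                              n_stages = 4,
                              n_replicates = 3,
                              n_gametophyte_samples = 6,
                              nb_dispersion = 0.05,
                              baseline_mean = 500,
                              archetypes = default_archetypes(),
                              shift_fraction = 0.3,
                              de_fraction = 0.15,
                              de_log2fc = 3,
                              seed = 1,
                              species = c("spA", "spB")) {
  cfg <- list(n_shared_orthologs = as.integer(n_shared_orthologs),
              n_specific_per_species = as.integer(n_specific_per_species),
              n_flat_per_species = as.integer(n_flat_per_species),
              n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              n_gametophyte_samples = as.integer(n_gametophyte_samples),
              nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
              archetypes = archetypes, shift_fraction = shift_fraction,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              seed = as.integer(seed), species = species)
  if (cfg$n_stages < 2) stop("n_stages must be >= 2")
  if (cfg$n_shared_orthologs < 1) stop("need at least one shared ortholog")
  if (cfg$shift_fraction < 0 || cfg$shift_fraction > 1 ||
      cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("shift_fraction and de_fraction must lie in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$baseline_mean <= 0) stop("baseline_mean must be positive")
  if (length(cfg$species) != 2 || anyDuplicated(cfg$species)) {
    stop("exactly two distinct species labels required")
  }
  if (ncol(cfg$archetypes$profiles) != cfg$n_stages) {
    stop("archetype profiles must have one column per stage")
  }
  if (cfg$n_replicates < 2) stop("n_replicates must be >= 2")
  if (cfg$n_gametophyte_samples < 2) stop("n_gametophyte_samples must be >= 2")
  structure(cfg, class = "sim_config")
}

# expected counts for one species given per-gene archetype and DE status;
# returns list(mu = genes x samples matrix, samples = sample sheet, sf)
.species_mean_model <- function(cfg, gene_ids, arch_idx, de_lfc, species,
                                arch = cfg$archetypes$profiles) {
  n_spo <- cfg$n_stages * cfg$n_replicates
  n_gam <- cfg$n_gametophyte_samples
  stage <- rep(seq_len(cfg$n_stages), each = cfg$n_replicates)
  samples <- data.frame(
    sample_id = c(sprintf("%s_s%d_r%d", species, stage, rep(seq_len(cfg$n_replicates), cfg$n_stages)),
                  sprintf("%s_g_r%d", species, seq_len(n_gam))),
    species = species,
    phase = c(rep("sporophyte", n_spo), rep("gametophyte", n_gam)),
    stage = c(as.character(stage), paste0("g", seq_len(n_gam))),
    replicate = c(rep(seq_len(cfg$n_replicates), cfg$n_stages), seq_len(n_gam)),
    stringsAsFactors = FALSE)
  sf <- exp(stats::runif(nrow(samples), log(0.5), log(2)))
  names(sf) <- samples$sample_id
  # per-gene per-sample mean: sporophyte = baseline * archetype(stage) * 2^lfc,
  # gametophyte = baseline
  spo_mu <- cfg$baseline_mean * arch[arch_idx, stage, drop = FALSE] * 2^de_lfc
  gam_mu <- matrix(cfg$baseline_mean, length(gene_ids), n_gam)
  mu <- cbind(spo_mu, gam_mu)
  mu <- sweep(mu, 2, sf, "*")
  dimnames(mu) <- list(gene_ids, samples$sample_id)
  list(mu = mu, samples = samples, sf = sf)
}

.draw_counts <- function(mu, dispersion) {
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a two-species developmental expression data set
#'
#' Generates NB-distributed counts for two species over the configured
#' sporophyte stages and gametophyte samples, with shared one-to-one
#' orthologs (emitted both as singleton orthogroups and as reciprocal
#' filter-passing protein hits), species-specific genes (no cross-species
#' hits), planted temporal archetypes, planted heterochronic major-phase
#' shifts in species B, and planted sporophyte-preferential fold changes.
#' Planting is exact: `round(shift_fraction * n_shared_orthologs)` orthologs
#' are shifted and `round(de_fraction * n_genes)` genes per species are
#' differentially expressed. All randomness flows from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List of class `"two_species_sim"` with elements `counts_a`,
#'   `counts_b` ([count_matrix()]), `orthogroups`, `hits_ab`, `hits_ba`
#'   (filter-passing reciprocal hit tables), `query_lengths_a`,
#'   `query_lengths_b`, `truth` (per-gene ground-truth data.frame),
#'   `size_factors_a`, `size_factors_b` (the true planted factors) and
#'   `config`.
#' @export
simulate_two_species <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_arch <- nrow(cfg$archetypes$profiles)
  major <- cfg$archetypes$major

  ns <- cfg$n_shared_orthologs
  sp <- cfg$species
  mk_ids <- function(s) c(sprintf("%s_g%04d", s, seq_len(ns)),
                          sprintf("%s_x%04d", s, seq_len(cfg$n_specific_per_species)),
                          sprintf("%s_f%04d", s, seq_len(cfg$n_flat_per_species)))
  genes_a <- mk_ids(sp[1])
  genes_b <- mk_ids(sp[2])
  n_genes <- length(genes_a)
  n_dyn <- ns + cfg$n_specific_per_species
  flat_idx <- n_arch + 1L   # internal flat profile appended to the archetypes

  # archetypes: species A free; species B equal unless the ortholog is shifted;
  # background genes are flat in both species
  arch_a <- c(sample.int(n_arch, n_dyn, replace = TRUE),
              rep(flat_idx, cfg$n_flat_per_species))
  arch_b <- arch_a
  n_shift <- round(cfg$shift_fraction * ns)
  shifted_idx <- if (n_shift > 0) sample.int(ns, n_shift) else integer(0)
  for (i in shifted_idx) {
    other <- which(major != major[arch_a[i]])
    arch_b[i] <- other[sample.int(length(other), 1)]
  }
  shifted <- seq_len(n_genes) %in% shifted_idx

  # planted sporophyte-preferential genes, independently per species
  n_de <- round(cfg$de_fraction * n_genes)
  de_a <- seq_len(n_genes) %in% sample.int(n_genes, n_de)
  de_b <- seq_len(n_genes) %in% sample.int(n_genes, n_de)
  lfc_a <- ifelse(de_a, cfg$de_log2fc, 0)
  lfc_b <- ifelse(de_b, cfg$de_log2fc, 0)

  arch_profiles <- rbind(cfg$archetypes$profiles,
                         flat = rep(1, cfg$n_stages))
  model_a <- .species_mean_model(cfg, genes_a, arch_a, lfc_a, sp[1], arch_profiles)
  model_b <- .species_mean_model(cfg, genes_b, arch_b, lfc_b, sp[2], arch_profiles)
  counts_a <- count_matrix(.draw_counts(model_a$mu, cfg$nb_dispersion), model_a$samples)
  counts_b <- count_matrix(.draw_counts(model_b$mu, cfg$nb_dispersion), model_b$samples)

  og_ids <- sprintf("OG%06d", seq_len(ns))
  genes_by_species <- lapply(seq_len(ns), function(i) {
    stats::setNames(list(genes_a[i], genes_b[i]), sp)
  })
  orthogroups <- orthogroup_table(og_ids, genes_by_species, sp)

  qlen <- as.integer(round(stats::runif(ns, 200, 800)))
  mk_hits <- function(q, s, qlen) {
    df <- data.frame(query_id = q, subject_id = s,
                     percent_similarity = round(stats::runif(ns, 60, 95), 1),
                     alignment_length = qlen, mismatches = 0L, gap_opens = 0L,
                     q_start = 1L, q_end = qlen, s_start = 1L, s_end = qlen,
                     evalue = 1e-50, bitscore = round(qlen * 1.9, 1),
                     query_length = qlen, stringsAsFactors = FALSE)
    class(df) <- c("hit_table", "data.frame")
    df
  }
  hits_ab <- mk_hits(genes_a[seq_len(ns)], genes_b[seq_len(ns)], qlen)
  hits_ba <- mk_hits(genes_b[seq_len(ns)], genes_a[seq_len(ns)], qlen)
  n_rest <- n_genes - ns
  qlen_a <- stats::setNames(c(qlen, as.integer(round(stats::runif(n_rest, 200, 800)))), genes_a)
  qlen_b <- stats::setNames(c(qlen, as.integer(round(stats::runif(n_rest, 200, 800)))), genes_b)

  major_ext <- c(major, NA_character_)
  truth <- data.frame(
    gene_a = genes_a, gene_b = genes_b,
    orthogroup_id = c(og_ids, rep(NA_character_, n_genes - ns)),
    species_specific = c(rep(FALSE, ns), rep(TRUE, n_genes - ns)),
    background = arch_a == flat_idx,
    archetype_a = rownames(arch_profiles)[arch_a],
    archetype_b = rownames(arch_profiles)[arch_b],
    major_a = major_ext[arch_a], major_b = major_ext[arch_b],
    shifted = shifted,
    de_planted_a = de_a, de_planted_b = de_b,
    true_log2fc_a = lfc_a, true_log2fc_b = lfc_b,
    stringsAsFactors = FALSE)
  # species-specific rows describe two unrelated genes, one per species;
  # pair-level fields (orthogroup, shifted) are only meaningful for orthologs
  truth$shifted[truth$species_specific] <- NA

  structure(list(counts_a = counts_a, counts_b = counts_b,
                 orthogroups = orthogroups,
                 hits_ab = hits_ab, hits_ba = hits_ba,
                 query_lengths_a = qlen_a, query_lengths_b = qlen_b,
                 truth = truth,
                 size_factors_a = model_a$sf, size_factors_b = model_b$sf,
                 mean_model_a = model_a$mu, mean_model_b = model_b$mu,
                 config = cfg),
            class = "two_species_sim")
}

#' @export
print.two_species_sim <- function(x, ...) {
  cat(sprintf("two_species_sim: %d ortholog pairs + %d specific genes/species, seed %d\n",
              x$config$n_shared_orthologs, x$config$n_specific_per_species,
              x$config$seed))
  invisible(x)
}

#' Summarize a planted ground truth
#'
#' Recounts the truth table: shifted/conserved ortholog pairs, planted DE
#' genes per species, species-specific genes.
#'
#' @param truth the `truth` data.frame of a [simulate_two_species()] result
#'   (or an empty data.frame).
#' @return One-row data.frame with counts and the shifted fraction.
#' @export
truth_summary <- function(truth) {
  if (is.null(truth) || !nrow(truth)) {
    return(data.frame(n_orthologs = 0L, n_shifted = 0L, n_conserved = 0L,
                      shifted_fraction = NA_real_, n_de_a = 0L, n_de_b = 0L,
                      n_specific_per_species = 0L))
  }
  ortho <- truth[!truth$species_specific, , drop = FALSE]
  data.frame(n_orthologs = nrow(ortho),
             n_shifted = sum(ortho$shifted),
             n_conserved = sum(!ortho$shifted),
             shifted_fraction = if (nrow(ortho)) mean(ortho$shifted) else NA_real_,
             n_de_a = sum(truth$de_planted_a),
             n_de_b = sum(truth$de_planted_b),
             n_specific_per_species = sum(truth$species_specific),
             n_background = if (!is.null(truth$background)) sum(truth$background) else 0L)
}
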