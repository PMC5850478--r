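# Seeded synthetic-data generators emulating the study system: a two-species
# strain collection with tandem-repeat polyprotein ORFs, ELISA-like secretion
# tables with plate effects, binomial mating-competition counts, and qPCR Ct
# triples. Every generator records its ground truth so downstream estimates
# can be checked against known values.

#' Variant mature-peptide presets
#'
#' Single-residue variants of the canonical peptide observed at repeat-array
#' edges: an R-for-Q substitution and an I-for-M substitution.
#' @export
VARIANT_PEPTIDES <- c("WHWLRLKPGQPMY", "WHWLQLKPGQPIY")

# deterministic-template coding of a peptide: alphabetically first codon per
# residue (used for leader/spacer templates, which carry no class signal)
.template_coding <- function(peptide) {
  paste(vapply(strsplit(peptide, "")[[1L]],
               function(aa) sort(codons_for(aa))[1L], character(1L)),
        collapse = "")
}

# one uniformly random synonymous coding of a peptide (uses current RNG)
.random_coding <- function(peptide) {
  paste(vapply(strsplit(peptide, "")[[1L]], function(aa) {
    cods <- codons_for(aa)
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1L)), collapse = "")
}

# k distinct random synonymous codings, none colliding with `exclude`
.sample_codings <- function(peptide, k, exclude = character(0)) {
  if (k > count_synonymous_codings(peptide))
    stop("requested pool size exceeds the number of synonymous codings (",
         count_synonymous_codings(peptide), ")")
  out <- character(0)
  tries <- 0L
  while (length(out) < k) {
    cand <- .random_coding(peptide)
    if (!(cand %in% out) && !(cand %in% exclude)) out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 1000L * k) stop("could not sample distinct codings")
  }
  out
}

#' Configuration for the synthetic strain collection
#'
#' Defaults emulate the study collection: two species with disjoint
#' synonymous coding pools (7 classes in one, 9 in the other), 71 and 62
#' strains grouped into lineages, repeat numbers 2-6 and 2-5, and rare
#' single-residue variant repeats confined to array edges (one variant
#' peptide per species). The ORF scaffold is leader (82 codons, a
#' prepro-like placeholder with no tryptophan, so it cannot shadow the
#' repeat motif) + per repeat an 8-codon Lys-Arg-initiated spacer + the
#' 13-codon repeat + a stop codon, giving ORF length `249 + 63 n` nt.
#'
#' @param species Character vector of species names.
#' @param n_strains,n_lineages,pool_size,repeat_min,repeat_max Per-species
#'   integer vectors (recycled).
#' @param canonical_peptide Canonical mature peptide.
#' @param variant_peptides One variant peptide per species (recycled).
#' @param variant_prob Probability a strain carries one variant repeat.
#' @param variant_edge_only Restrict variant repeats to array edges.
#' @param leader_peptide,spacer_peptide Scaffold peptide templates.
#' @param seed RNG seed.
#' @return A `collection_config` list.
#' @export
collection_config <- function(species = c("cerevisiae_like", "paradoxus_like"),
                              n_strains = c(71L, 62L),
                              n_lineages = c(6L, 5L),
                              pool_size = c(7L, 9L),
                              repeat_min = c(2L, 2L),
                              repeat_max = c(6L, 5L),
                              canonical_peptide = CANONICAL_PEPTIDE,
                              variant_peptides = VARIANT_PEPTIDES,
                              variant_prob = 0.05,
                              variant_edge_only = TRUE,
                              leader_peptide = paste0(
                                "MRFPSIFTAVLFAASSALA",  # signal-like
                                "APVNTTTEDETAQIPAEAVIGYSDLEGDFDVAVLPFSNSTNNGLLFINTTIASIAAKEEGVSL"),
                              spacer_peptide = "KREAEAEA",
                              seed = 1L) {
  ns <- length(species)
  cfg <- list(species = species,
              n_strains = rep_len(as.integer(n_strains), ns),
              n_lineages = rep_len(as.integer(n_lineages), ns),
              pool_size = rep_len(as.integer(pool_size), ns),
              repeat_min = rep_len(as.integer(repeat_min), ns),
              repeat_max = rep_len(as.integer(repeat_max), ns),
              canonical_peptide = canonical_peptide,
              variant_peptides = rep_len(variant_peptides, ns),
              variant_prob = variant_prob,
              variant_edge_only = isTRUE(variant_edge_only),
              leader_peptide = leader_peptide,
              spacer_peptide = spacer_peptide,
              seed = as.integer(seed))
  stopifnot(all(cfg$repeat_min >= 1L), all(cfg$repeat_max >= cfg$repeat_min),
            variant_prob >= 0, variant_prob <= 1)
  if (any(cfg$pool_size > count_synonymous_codings(canonical_peptide)))
    stop("pool size exceeds the number of synonymous codings of the peptide (",
         count_synonymous_codings(canonical_peptide), ")")
  if (grepl("W", leader_peptide) || grepl("W", spacer_peptide))
    stop("leader/spacer templates must not contain tryptophan (repeat-motif shadowing)")
  structure(cfg, class = "collection_config")
}

#' Generate a synthetic strain collection with known repeat arrays
#'
#' Builds one polyprotein ORF per strain: scaffold leader, then for each of
#' `n` repeats a spacer plus a 39-nt unit drawn from the species' coding
#' pool, then a stop. Pools are disjoint between species (no shared classes,
#' emulating the absence of transspecific repeat polymorphism). Each lineage
#' is seeded with a base repeat number; member strains deviate by one with
#' small probability, so some lineages segregate repeat-number variation.
#' With probability `variant_prob` a strain carries the species' variant
#' repeat at one array edge (or at any position when `variant_edge_only` is
#' `FALSE`). Fully deterministic given the config seed.
#'
#' @param config A [collection_config()].
#' @return List with `orfs` (list of [orf_record()]), `metadata` (strain_id,
#'   species, lineage, n_repeats), `truth` (one row per planted unit:
#'   codon_start 0-based, nt_seq, pool class id, is_edge, is_variant),
#'   `pools` (per-species coding vectors), and `config`.
#' @export
generate_collection <- function(config = collection_config()) {
  stopifnot(inherits(config, "collection_config"))
  set.seed(config$seed)
  leader_nt <- .template_coding(config$leader_peptide)
  spacer_nt <- .template_coding(config$spacer_peptide)
  n_leader <- nchar(leader_nt) %/% 3L
  n_spacer <- nchar(spacer_nt) %/% 3L
  k <- nchar(config$canonical_peptide)

  pools <- list()
  variant_codings <- character(length(config$species))
  used <- character(0)
  for (s in seq_along(config$species)) {
    pools[[config$species[s]]] <- .sample_codings(config$canonical_peptide,
                                                  config$pool_size[s], used)
    used <- c(used, pools[[config$species[s]]])
    variant_codings[s] <- .random_coding(config$variant_peptides[s])
  }

  orfs <- list()
  meta <- list()
  truth <- list()
  for (s in seq_along(config$species)) {
    sp <- config$species[s]
    pool <- pools[[sp]]
    lineage_of <- rep_len(seq_len(config$n_lineages[s]), config$n_strains[s])
    base_n <- sample(config$repeat_min[s]:config$repeat_max[s],
                     config$n_lineages[s], replace = TRUE)
    for (i in seq_len(config$n_strains[s])) {
      lin <- lineage_of[i]
      n <- base_n[lin] + sample(c(-1L, 0L, 1L), 1L, prob = c(0.15, 0.7, 0.15))
      n <- min(max(n, config$repeat_min[s]), config$repeat_max[s])
      cls <- sample(seq_along(pool), n, replace = TRUE)
      unit_nt <- pool[cls]
      class_id <- paste0(sp, ".", cls)
      is_variant <- rep(FALSE, n)
      if (stats::runif(1L) < config$variant_prob) {
        pos <- if (config$variant_edge_only) {
          if (n == 1L) 1L else sample(c(1L, n), 1L)
        } else sample.int(n, 1L)
        unit_nt[pos] <- variant_codings[s]
        class_id[pos] <- paste0(sp, ".var")
        is_variant[pos] <- TRUE
      }
      strain <- sprintf("%s_L%02d_S%03d", sp, lin, i)
      seqs <- paste0(leader_nt,
                     paste(paste0(spacer_nt, unit_nt), collapse = ""), "TAA")
      orfs[[length(orfs) + 1L]] <- orf_record(strain, seqs, species = sp,
                                              lineage = paste0(sp, "_L", lin))
      meta[[length(meta) + 1L]] <- data.frame(
        strain_id = strain, species = sp, lineage = paste0(sp, "_L", lin),
        n_repeats = n, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        strain_id = strain, unit_index = seq_len(n),
        codon_start = n_leader + n_spacer + (seq_len(n) - 1L) * (n_spacer + k),
        nt_seq = unit_nt, class_id = class_id,
        is_edge = seq_len(n) %in% c(1L, n), is_variant = is_variant,
        stringsAsFactors = FALSE)
    }
  }
  list(orfs = orfs,
       metadata = do.call(rbind, meta),
       truth = do.call(rbind, truth),
       pools = pools,
       variant_codings = stats::setNames(variant_codings, config$species),
       config = config)
}

#' Generate ELISA-like secretion measurements
#'
#' Per strain, plate and a-factor treatment:
#' `value = P(n) * a_factor_fold^[plus_a] * plate_effect * exp(noise)`,
#' with `P(n)` from the trade-off model, log-normal plate effects shared
#' within a plate, and log-normal measurement noise. Every strain appears on
#' every plate under both treatments (a balanced design).
#'
#' @param strains Data frame with `strain_id` and `n_repeats`.
#' @param tradeoff A [tradeoff_params()] object (generating truth).
#' @param a_factor_fold True fold-increase of secretion under a-factor
#'   exposure (default 2.6, a typical pheromone-response magnitude).
#' @param n_plates Number of ELISA plates.
#' @param plate_sd,noise_sd Log-scale standard deviations.
#' @param seed RNG seed.
#' @return Long-format data frame: `strain_id`, `n_repeats`, `plate`,
#'   `treatment` (plus_a / minus_a), `value`, `assay`.
#' @export
generate_secretion <- function(strains, tradeoff = tradeoff_params(c = 1e6),
                               a_factor_fold = 2.6, n_plates = 3L,
                               plate_sd = 0.15, noise_sd = 0.2, seed = 1L) {
  stopifnot(all(c("strain_id", "n_repeats") %in% names(strains)),
            a_factor_fold > 0, plate_sd >= 0, noise_sd >= 0)
  set.seed(seed)
  plate_eff <- exp(stats::rnorm(n_plates, 0, plate_sd))
  grid <- expand.grid(i = seq_len(nrow(strains)), plate = seq_len(n_plates),
                      treatment = c("plus_a", "minus_a"),
                      stringsAsFactors = FALSE)
  mu <- production(strains$n_repeats[grid$i], tradeoff) *
    ifelse(grid$treatment == "plus_a", a_factor_fold, 1) *
    plate_eff[grid$plate]
  data.frame(strain_id = strains$strain_id[grid$i],
             n_repeats = strains$n_repeats[grid$i],
             plate = paste0("plate", grid$plate),
             treatment = grid$treatment,
             value = mu * exp(stats::rnorm(nrow(grid), 0, noise_sd)),
             assay = "secretion", stringsAsFactors = FALSE)
}

#' Generate competitive mating counts
#'
#' Matings are split binomially between focal and competitor in proportion
#' to their secretion rates: `focal ~ Binomial(mating_pairs, s_f / (s_f +
#' s_c))`, so the expected mating-success ratio equals the secretion ratio.
#'
#' @param s_focal,s_competitor Positive secretion means (vectorised over
#'   competitions).
#' @param mating_pairs Total matings per competition.
#' @param seed RNG seed.
#' @return Data frame with `focal`, `competitor`, `p_true`.
#' @export
generate_mating <- function(s_focal, s_competitor, mating_pairs = 100L,
                            seed = 1L) {
  stopifnot(all(s_focal > 0), all(s_competitor > 0), mating_pairs > 0)
  set.seed(seed)
  p <- s_focal / (s_focal + s_competitor)
  focal <- stats::rbinom(length(p), mating_pairs, p)
  data.frame(focal = focal, competitor = mating_pairs - focal, p_true = p)
}

#' Generate qPCR Ct triples (target plus two reference genes)
#'
#' `Ct_target = baseline - log2(abundance) + noise`; the two reference-gene
#' Cts sit at the baseline with independent noise, so [qpcr_relative()] with
#' efficiency 2 recovers `abundance` up to noise.
#'
#' @param abundance True relative abundances (vectorised over samples).
#' @param baseline_ct Reference Ct level.
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param replicates Technical replicates per sample.
#' @param seed RNG seed.
#' @return Data frame with `sample`, `replicate`, `ct_target`, `ct_ref1`,
#'   `ct_ref2`, `abundance_true`.
#' @export
generate_qpcr <- function(abundance, baseline_ct = 20, noise_sd = 0.2,
                          replicates = 3L, seed = 1L) {
  stopifnot(all(abundance > 0), noise_sd >= 0, replicates >= 1L)
  set.seed(seed)
  grid <- expand.grid(sample = seq_along(abundance),
                      replicate = seq_len(replicates))
  nr <- nrow(grid)
  data.frame(sample = grid$sample, replicate = grid$replicate,
             ct_target = baseline_ct - log2(abundance[grid$sample]) +
               stats::rnorm(nr, 0, noise_sd),
             ct_ref1 = baseline_ct + stats::rnorm(nr, 0, noise_sd),
             ct_ref2 = baseline_ct + stats::rnorm(nr, 0, noise_sd),
             abundance_true = abundance[grid$sample])
}
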