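# End-to-end orchestration: simulate a collection, decompose and classify
# its arrays, score codon optimality, run the concerted-evolution simulator,
# fit the trade-off model, and compute phenotype statistics -- writing
# plain-file outputs (FASTA/TSV/JSON) plus a run manifest with seeds and
# checksums so a run can be reproduced and verified.

#' Demo pipeline configuration
#'
#' A small, fast configuration: 50 strains (25 per species), 3 lineages per
#' species, pools of 5 and 6 synonymous codings, and modest simulation
#' sizes. All stage seeds derive from the single `seed`.
#'
#' @param seed Master seed.
#' @return Nested configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    collection = collection_config(
      n_strains = c(25L, 25L), n_lineages = c(3L, 3L),
      pool_size = c(5L, 6L), seed = seed),
    tradeoff = tradeoff_params(c = 1e6, beta = 1.28, L0 = 249, lam = 63),
    secretion = list(a_factor_fold = 2.6, n_plates = 3L, plate_sd = 0.15,
                     noise_sd = 0.2, seed = seed + 101L),
    evolution = list(params = evo_params(crossover_rate = 0.05,
                                         conversion_rate = 0.05,
                                         seed = seed + 202L),
                     generations = 200L),
    mating = list(mating_pairs = 100L, seed = seed + 303L),
    qpcr = list(baseline_ct = 20, noise_sd = 0.2, replicates = 3L,
                seed = seed + 404L)
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages, in dependency order: `simulate` (generate the strain collection),
#' `decompose` (repeat detection, classification, collection summary),
#' `optimality` (tRNA-availability ranking of repeat classes, using the
#' bundled synthetic anticodon table), `evolve` (concerted-evolution
#' simulation started from the decomposed arrays), `tradeoff` (secretion
#' generation and trade-off fit), `phenostats` (least-squares means, fold
#' response, mating success, qPCR normalisation). A `manifest.json` records
#' the configuration, seeds, package version and MD5 checksums of every
#' output file.
#'
#' @param config Configuration list, e.g. [demo_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (dependencies must already have
#'   been produced in `out_dir`).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = demo_config(), out_dir,
                         stages = c("simulate", "decompose", "optimality",
                                    "evolve", "tradeoff", "phenostats")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  need <- function(stage, obj, file) {
    if (!is.null(res[[obj]])) return(invisible())
    if (!file.exists(file.path(out_dir, file)))
      stop("stage '", stage, "' requires missing upstream output: ", file)
  }

  if ("simulate" %in% stages) {
    res$collection <- generate_collection(config$collection)
    write_orf_fasta(res$collection$orfs, file.path(out_dir, "orfs.fasta"))
    write_tsv(res$collection$metadata, file.path(out_dir, "metadata.tsv"))
    write_tsv(res$collection$truth, file.path(out_dir, "truth.tsv"))
  }

  if ("decompose" %in% stages) {
    need("decompose", "collection", "orfs.fasta")
    orfs <- if (!is.null(res$collection)) res$collection$orfs else
      read_orf_fasta(file.path(out_dir, "orfs.fasta"))
    metadata <- if (!is.null(res$collection)) res$collection$metadata else
      utils::read.delim(file.path(out_dir, "metadata.tsv"))
    arrays <- lapply(orfs, function(o) decompose(o, find_repeats(o)))
    cat0 <- build_catalog(arrays)
    res$arrays <- cat0$arrays
    res$catalog <- cat0$catalog
    res$summary <- collection_summary(cat0$arrays, metadata)
    array_table(cat0$arrays, file.path(out_dir, "arrays.tsv"))
    write_tsv(cat0$catalog, file.path(out_dir, "catalog.tsv"))
    jsonlite::write_json(res$summary[c("by_species", "by_lineage",
                                       "shared_classes",
                                       "n_lineages_with_repeat_number_change")],
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  if ("optimality" %in% stages) {
    need("optimality", "catalog", "catalog.tsv")
    catalog <- if (!is.null(res$catalog)) res$catalog else
      utils::read.delim(file.path(out_dir, "catalog.tsv"))
    trna <- read_trna_table(system.file("extdata",
                                        "trna_anticodon_counts_synthetic.tsv",
                                        package = "polyrepeat"))
    res$optimality <- rank_repeats(catalog[catalog$synonymous, ], trna)
    write_tsv(res$optimality$ranking, file.path(out_dir, "optimality.tsv"))
    write_tsv(cbind(class_label = rownames(res$optimality$per_codon),
                    as.data.frame(res$optimality$per_codon)),
              file.path(out_dir, "optimality_per_codon.tsv"))
  }

  if ("evolve" %in% stages) {
    need("evolve", "arrays", "arrays.tsv")
    init <- if (!is.null(res$arrays))
      lapply(res$arrays, function(a) a$units$nt_seq)
    else {
      at <- utils::read.delim(file.path(out_dir, "arrays.tsv"))
      lapply(strsplit(at$array_string, ""), identity)
    }
    init <- Filter(function(u) length(u) >= 2L, init)
    res$evolution <- simulate_lineages(init, config$evolution$params,
                                       config$evolution$generations)
    write_tsv(res$evolution$events, file.path(out_dir, "evolution_events.tsv"))
    jsonlite::write_json(res$evolution$stats[c("n_crossovers", "edge_retention",
                                               "internal_change_fraction")],
                         file.path(out_dir, "evolution_stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("tradeoff" %in% stages) {
    need("tradeoff", "collection", "metadata.tsv")
    metadata <- if (!is.null(res$collection)) res$collection$metadata else
      utils::read.delim(file.path(out_dir, "metadata.tsv"))
    sec <- do.call(generate_secretion,
                   c(list(strains = metadata, tradeoff = config$tradeoff),
                     config$secretion))
    res$secretion <- sec
    write_tsv(sec, file.path(out_dir, "secretion.tsv"))
    minus <- sec[sec$treatment == "minus_a", ]
    fit <- fit_beta(data.frame(n = minus$n_repeats, production = minus$value),
                    L0 = config$tradeoff$L0, lam = config$tradeoff$lam)
    # full-length polyprotein production is secretion per repeat; its
    # log-log slope against ORF length estimates -beta
    sl <- loglog_slope(data.frame(
      length_nt = config$tradeoff$L0 + config$tradeoff$lam * minus$n_repeats,
      production = minus$value / minus$n_repeats))
    res$tradeoff_fit <- list(
      c = fit$c, beta = fit$beta, se_beta = fit$se_beta,
      loglog_slope_fulllength = sl$slope,
      optimum = optimal_repeat_number(config$tradeoff, n_max = 20L))
    jsonlite::write_json(res$tradeoff_fit, file.path(out_dir, "tradeoff_fit.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  if ("phenostats" %in% stages) {
    need("phenostats", "secretion", "secretion.tsv")
    sec <- if (!is.null(res$secretion)) res$secretion else
      utils::read.delim(file.path(out_dir, "secretion.tsv"))
    sec$group <- paste0("n", sec$n_repeats)
    lsm <- lsmeans_plate(sec, response = "value", group = "group",
                         plate = "plate", treatment = "treatment",
                         transform = "log")
    fold <- fold_response(sec)
    # mating between extreme repeat-number groups, driven by secretion means
    gm <- vapply(split(sec$value, sec$n_repeats),
                 function(v) exp(mean(log(v))), numeric(1L))
    mat <- do.call(generate_mating,
                   c(list(s_focal = gm[length(gm)], s_competitor = gm[1L]),
                     config$mating))
    ms <- mating_success(mat$focal[1L], mat$competitor[1L])
    qt <- do.call(generate_qpcr, c(list(abundance = c(1, 2.1)), config$qpcr))
    qrel <- vapply(split(qt, qt$sample), function(d)
      mean(qpcr_relative(d$ct_target, d$ct_ref1, d$ct_ref2)), numeric(1L))
    res$phenostats <- list(lsmeans = lsm$means, pairwise = lsm$pairwise,
                           a_factor_fold = fold,
                           mating = c(ms, list(counts = mat)),
                           qpcr_relative = qrel)
    write_tsv(lsm$means, file.path(out_dir, "lsmeans.tsv"))
    jsonlite::write_json(list(a_factor_fold = fold$fold,
                              mating_ratio = ms$ratio,
                              qpcr_relative = as.list(qrel)),
                         file.path(out_dir, "phenostats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("polyrepeat")),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = stages,
    seed = config$seed,
    config = config,
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  res$manifest <- manifest
  invisible(res)
}
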