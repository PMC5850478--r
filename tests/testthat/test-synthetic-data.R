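# Generator ground truth and estimator-generator consistency.

test_that("collection generation is deterministic under the seed", {
  cfg <- collection_config(n_strains = c(10L, 10L), seed = 42L)
  c1 <- generate_collection(cfg)
  c2 <- generate_collection(cfg)
  expect_identical(vapply(c1$orfs, `[[`, "", "sequence"),
                   vapply(c2$orfs, `[[`, "", "sequence"))
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_collection(collection_config(n_strains = c(10L, 10L),
                                              seed = 43L))
  expect_false(identical(vapply(c1$orfs, `[[`, "", "sequence"),
                         vapply(c3$orfs, `[[`, "", "sequence")))
})

test_that("ORF scaffold gives length 249 + 63 n, matching default L0 and lam", {
  col <- generate_collection(collection_config(n_strains = c(6L, 6L), seed = 2L))
  lens <- vapply(col$orfs, function(o) nchar(o$sequence), integer(1L))
  expect_equal(lens, 249L + 63L * col$metadata$n_repeats)
})

test_that("decomposition recovers every planted unit (positions and classes)", {
  col <- generate_collection(collection_config(n_strains = c(15L, 15L),
                                               variant_prob = 0.3, seed = 6L))
  for (i in seq_along(col$orfs)) {
    o <- col$orfs[[i]]
    u <- find_repeats(o)
    tru <- col$truth[col$truth$strain_id == o$strain_id, ]
    expect_equal(u$codon_start, tru$codon_start)
    expect_equal(u$nt_seq, tru$nt_seq)
  }
  # class partition: units with equal truth class id get equal labels
  arrays <- lapply(col$orfs, function(o) decompose(o, find_repeats(o)))
  labeled <- build_catalog(arrays)$arrays
  lab <- unlist(lapply(labeled, function(a) a$units$class_label))
  expect_equal(length(unique(paste(col$truth$class_id, lab))),
               length(unique(col$truth$class_id)))
})

test_that("variant units occur only at array edges when edge-restricted", {
  col <- generate_collection(collection_config(n_strains = c(40L, 40L),
                                               variant_prob = 0.5, seed = 14L))
  v <- col$truth[col$truth$is_variant, ]
  expect_gt(nrow(v), 0L)
  expect_true(all(v$is_edge))
  # and the decomposed arrays agree
  arrays <- lapply(col$orfs, function(o) decompose(o, find_repeats(o)))
  for (a in arrays) {
    nonsyn <- a$units$peptide != CANONICAL_PEPTIDE
    expect_true(all(a$units$is_edge[nonsyn]))
  }
})

test_that("variant-free configuration yields only synonymous units", {
  col <- generate_collection(collection_config(n_strains = c(10L, 10L),
                                               variant_prob = 0, seed = 4L))
  expect_false(any(col$truth$is_variant))
  arrays <- lapply(col$orfs, function(o) decompose(o, find_repeats(o)))
  cat <- build_catalog(arrays)$catalog
  expect_true(all(cat$synonymous))
})

test_that("oversized coding pools are rejected", {
  expect_error(generate_collection(collection_config(pool_size = c(1e6, 5))),
               "pool size")
})

test_that("noise-free secretion is exactly multiplicative in n and treatment", {
  strains <- data.frame(strain_id = paste0("s", 1:4), n_repeats = 1:4)
  tab <- generate_secretion(strains, tradeoff_params(c = 10, beta = 0,
                                                     L0 = 249, lam = 63),
                            a_factor_fold = 2.6, n_plates = 2L,
                            plate_sd = 0, noise_sd = 0, seed = 1L)
  minus <- tab[tab$treatment == "minus_a", ]
  expect_equal(minus$value, 10 * minus$n_repeats)
  plus <- tab[tab$treatment == "plus_a", ]
  expect_equal(plus$value, 2.6 * 10 * plus$n_repeats)
})

test_that("a saturating trade-off produces the rise-and-plateau group profile", {
  strains <- data.frame(strain_id = paste0("s", 1:8), n_repeats = 1:8)
  p <- tradeoff_params(c = 1e5, beta = 1.28, L0 = 6 * 0.28 * 63, lam = 63)
  tab <- generate_secretion(strains, p, n_plates = 1L, plate_sd = 0,
                            noise_sd = 0, seed = 1L)
  m <- tapply(tab$value[tab$treatment == "minus_a"],
              tab$n_repeats[tab$treatment == "minus_a"], mean)
  expect_true(all(diff(m[1:5]) > 0))       # increases 1 -> 5
  expect_lt(m[["8"]], m[["6"]])            # declines past the optimum
})

test_that("fold_response recovers the generating a-factor fold", {
  strains <- data.frame(strain_id = paste0("s", 1:6), n_repeats = rep(4L, 6L))
  tab <- generate_secretion(strains, a_factor_fold = 2.6, noise_sd = 0.2,
                            plate_sd = 0.15, seed = 31L)
  fr <- fold_response(tab)
  expect_gt(fr$ci_hi, fr$ci_lo)
  expect_lt(abs(log(fr$fold) - log(2.6)), 0.25)
})

test_that("mating counts follow the secretion-proportional binomial model", {
  # expected mating ratio equals the secretion ratio (4.3 here)
  m <- generate_mating(4.3, 1, mating_pairs = 200000L, seed = 3L)
  expect_equal(m$p_true, 4.3 / 5.3)
  expect_lt(abs(m$focal / m$competitor - 4.3), 0.1)
  # equal secretion: ratio concentrates at 1
  m2 <- generate_mating(2, 2, mating_pairs = 200000L, seed = 4L)
  expect_lt(abs(m2$focal / m2$competitor - 1), 0.05)
  # convergence: larger competitions estimate the odds better on average
  err_at <- function(pairs, seeds) mean(vapply(seeds, function(s) {
    g <- generate_mating(3, 1, mating_pairs = pairs, seed = s)
    abs(g$focal / g$competitor - 3)
  }, numeric(1L)))
  expect_lt(err_at(20000L, 1:20), err_at(200L, 1:20))
})

test_that("qPCR generation inverts through qpcr_relative", {
  q0 <- generate_qpcr(c(1, 2.1), noise_sd = 0, replicates = 1L, seed = 1L)
  rel <- qpcr_relative(q0$ct_target, q0$ct_ref1, q0$ct_ref2)
  expect_equal(rel, c(1, 2.1), tolerance = 1e-12)
  # with noise the log-scale estimator is unbiased over replicates
  ests <- vapply(1:100, function(s) {
    q <- generate_qpcr(2.1, noise_sd = 0.2, replicates = 3L, seed = s)
    exp(mean(log(qpcr_relative(q$ct_target, q$ct_ref1, q$ct_ref2))))
  }, numeric(1L))
  expect_lt(abs(mean(log(ests)) - log(2.1)), 0.05)
})
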