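# Repeat detection, array decomposition and classification.

test_that("find_repeats locates planted canonical units at exact positions", {
  orf <- orf_record("s1", paste0("ATGGCT", "AAGAGA", R_UNIT,
                                 "AAGAGA", R_UNIT, "TAA"))
  u <- find_repeats(orf)
  expect_equal(u$codon_start, c(4L, 19L))
  expect_equal(u$n_mismatches, c(0L, 0L))
  expect_equal(unique(nchar(u$nt_seq)), 39L)
  expect_equal(u$peptide, rep(CANONICAL_PEPTIDE, 2L))
  expect_equal(u$is_edge, c(TRUE, TRUE))
})

test_that("max_mismatch controls detection of single-residue variant units", {
  # mutate CAA -> CGA at codon 5 of the second unit: peptide WHWLRLKPGQPMY
  var <- paste0(substr(R_UNIT, 1L, 12L), "CGA", substr(R_UNIT, 16L, 39L))
  orf <- orf_record("s2", paste0("ATGGCT", "AAGAGA", R_UNIT,
                                 "AAGAGA", var, "TAA"))
  expect_equal(nrow(find_repeats(orf, max_mismatch = 0L)), 1L)
  u1 <- find_repeats(orf, max_mismatch = 1L)
  expect_equal(nrow(u1), 2L)
  expect_equal(u1$n_mismatches, c(0L, 1L))
  expect_equal(u1$peptide[2L], "WHWLRLKPGQPMY")
})

test_that("an ORF without repeat-matching windows yields an empty unit list", {
  orf <- orf_record("s3", "ATGGCTGCTGCTTAA")
  expect_equal(nrow(find_repeats(orf)), 0L)
  expect_error(decompose(orf), "no repeat units")
  deg <- decompose(orf, allow_empty = TRUE)
  expect_equal(reassemble(deg), orf$sequence)
})

test_that("invalid coding sequences are rejected naming the strain", {
  expect_error(orf_record("bad1", "ATGGCTTA"), "bad1.*divisible by 3")
  expect_error(orf_record("bad2", "GCTGCTTAA"), "bad2.*ATG")
  expect_error(orf_record("bad3", "ATGTAAGCTTAA"), "bad3.*internal stop")
  expect_error(orf_record("bad4", "ATGGCTGCT"), "bad4.*stop codon")
})

test_that("decompose splits leader, spacers and tail with exact arithmetic", {
  orf <- orf_record("s1", paste0("ATGGCT", "AAGAGA", R_UNIT,
                                 "AAGAGA", R_UNIT, "TAA"))
  a <- decompose(orf)
  expect_equal(nchar(a$leader_nt), 12L)
  expect_equal(nchar(a$spacers_nt), 6L)
  expect_equal(a$tail_nt, "TAA")
  expect_identical(reassemble(a), orf$sequence)
})

test_that("a single-unit array has no spacers and one double-edge unit", {
  orf <- orf_record("s1", paste0("ATGGCT", R_UNIT, "TAA"))
  a <- decompose(orf)
  expect_equal(length(a$spacers_nt), 0L)
  expect_equal(nrow(a$units), 1L)
  expect_true(a$units$is_edge)
})

test_that("catalog labels synonymous classes with letters, variants with v-labels", {
  set.seed(7)
  r1 <- R_UNIT
  r2 <- rand_coding(CANONICAL_PEPTIDE)
  rv <- rand_coding("WHWLRLKPGQPMY")
  mk <- function(id, units) {
    seqs <- paste0("ATGGCT", paste(paste0("AAGAGA", units), collapse = ""), "TAA")
    decompose(orf_record(id, seqs))
  }
  out <- build_catalog(list(mk("a", c(r1, r1)), mk("b", c(r1, r2, rv))))
  expect_equal(out$arrays[[1L]]$array_string, "AA")
  expect_equal(out$arrays[[2L]]$array_string, "ABv1")
  cat <- out$catalog
  expect_equal(cat$class_label[match(rv, cat$nt_seq)], "v1")
  expect_false(cat$synonymous[match(rv, cat$nt_seq)])
})

test_that("class partition is invariant under input permutation", {
  set.seed(11)
  col <- generate_collection(collection_config(n_strains = c(12L, 12L),
                                               n_lineages = c(2L, 2L),
                                               pool_size = c(4L, 4L),
                                               variant_prob = 0.3, seed = 5L))
  arrays <- lapply(col$orfs, function(o) decompose(o, find_repeats(o)))
  part_of <- function(arrs) {
    out <- build_catalog(arrs)
    # partition: group unit nt sequences by label, order-free
    sp <- split(out$catalog$nt_seq, out$catalog$class_label)
    unname(lapply(sp, sort))[order(vapply(lapply(sp, sort), `[`, "", 1L))]
  }
  p0 <- part_of(arrays)
  for (rep in 1:5) {
    pp <- part_of(sample(arrays))
    expect_identical(pp, p0)
  }
})

test_that("letter sequence extends past Z without collision", {
  lab <- polyrepeat:::.latin_label(1:60)
  expect_equal(lab[1:3], c("A", "B", "C"))
  expect_equal(lab[26:28], c("Z", "AA", "AB"))
  expect_equal(anyDuplicated(lab), 0L)
})

test_that("count_synonymous_codings matches degeneracy products", {
  expect_equal(count_synonymous_codings("M"), 1)
  expect_equal(count_synonymous_codings("MW"), 1)
  expect_equal(count_synonymous_codings("WHWLQLKPGQPMY"), 73728)
  expect_error(count_synonymous_codings("MXZ"), "unknown residue")
  # observed distinct synonymous classes can never exceed the bound
  col <- generate_collection(collection_config(n_strains = c(8L, 8L),
                                               pool_size = c(5L, 5L), seed = 3L))
  arrays <- lapply(col$orfs, function(o) decompose(o, find_repeats(o)))
  cat <- build_catalog(arrays)$catalog
  expect_lte(sum(cat$synonymous), count_synonymous_codings(CANONICAL_PEPTIDE))
})

test_that("collection_summary reports ranges, class counts and sharing", {
  cfg <- collection_config(n_strains = c(30L, 30L), n_lineages = c(3L, 3L),
                           pool_size = c(5L, 6L), repeat_min = c(2L, 2L),
                           repeat_max = c(6L, 5L), variant_prob = 0,
                           seed = 21L)
  col <- generate_collection(cfg)
  arrays <- lapply(col$orfs, function(o) decompose(o, find_repeats(o)))
  labeled <- build_catalog(arrays)$arrays
  s <- collection_summary(labeled, col$metadata)
  truth_range <- range(col$metadata$n_repeats[
    col$metadata$species == "cerevisiae_like"])
  i <- match("cerevisiae_like", s$by_species$group)
  expect_equal(c(s$by_species$repeat_min[i], s$by_species$repeat_max[i]),
               truth_range)
  # class counts match the number of pool codings actually used
  used <- length(unique(col$truth$nt_seq[
    col$truth$strain_id %in%
      col$metadata$strain_id[col$metadata$species == "cerevisiae_like"]]))
  expect_equal(s$by_species$n_synonymous_classes[i], used)
  # disjoint pools -> nothing shared
  expect_equal(s$shared_classes$n_shared_classes, 0L)
  # lineage repeat-number change count matches metadata ground truth
  truth_change <- sum(vapply(split(col$metadata$n_repeats, col$metadata$lineage),
                             function(x) length(unique(x)) > 1L, logical(1L)))
  expect_equal(s$n_lineages_with_repeat_number_change, truth_change)
  expect_error(collection_summary(labeled, col$metadata[-1L, ]),
               "absent from metadata")
})

test_that("one uniform lineage has a repeat-number change count of zero", {
  mk <- function(id) decompose(orf_record(
    id, paste0("ATGGCT", "AAGAGA", R_UNIT, "AAGAGA", R_UNIT, "TAA")))
  arrays <- build_catalog(list(mk("x1"), mk("x2"), mk("x3")))$arrays
  meta <- data.frame(strain_id = c("x1", "x2", "x3"), species = "sp",
                     lineage = "L1")
  s <- collection_summary(arrays, meta)
  expect_equal(s$n_lineages_with_repeat_number_change, 0L)
})

test_that("FASTA round trip preserves sequences and grouping fields", {
  col <- generate_collection(collection_config(n_strains = c(5L, 5L), seed = 9L))
  tmp <- tempfile(fileext = ".fasta")
  write_orf_fasta(col$orfs, tmp)
  back <- read_orf_fasta(tmp)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(col$orfs, `[[`, "", "sequence"))
  expect_equal(vapply(back, `[[`, "", "species"),
               vapply(col$orfs, `[[`, "", "species"))
})
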