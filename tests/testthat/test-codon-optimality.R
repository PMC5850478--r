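# Wobble-adjusted tRNA availability and repeat-rate ranking.

test_that("a single anticodon decodes exactly its wobble set", {
  tab <- build_wobble_availability(c(CAU = 10))
  expect_equal(unname(tab$availability[["ATG"]]), 10)
  expect_equal(sum(tab$availability > 0), 1L)  # C34 reads G only
})

test_that("an A34 (inosine) anticodon covers the U/C/A-ending codons of its box", {
  tab <- build_wobble_availability(c(AGC = 4))  # alanine box GCN
  expect_equal(unname(tab$availability[c("GCT", "GCC", "GCA")]), rep(4, 3L))
  expect_equal(unname(tab$availability[["GCG"]]), 0)
})

test_that("U34 reads both purines and G34 reads both pyrimidines", {
  tab <- build_wobble_availability(c(UUC = 3, GAA = 5))
  # UUC decodes GAA/GAG (Glu); GAA decodes TTT/TTC (Phe)
  expect_equal(unname(tab$availability[c("GAA", "GAG")]), c(3, 3))
  expect_equal(unname(tab$availability[c("TTT", "TTC")]), c(5, 5))
})

test_that("strict rules restrict decoding to Watson-Crick partners", {
  tab <- build_wobble_availability(c(AGC = 4, UUC = 3), rules = "strict")
  expect_equal(unname(tab$availability[["GCT"]]), 4)
  expect_equal(unname(tab$availability[c("GCC", "GCA")]), c(0, 0))
  expect_equal(unname(tab$availability[c("GAA", "GAG")]), c(3, 0))
})

test_that("availability is linear in gene copy counts", {
  counts <- c(AGC = 4, UUC = 3, CAU = 7, GAA = 2)
  t1 <- build_wobble_availability(counts)
  t2 <- build_wobble_availability(2 * counts)
  expect_equal(t2$availability, 2 * t1$availability)
})

test_that("malformed anticodons are rejected", {
  expect_error(build_wobble_availability(c(AX = 1)), "malformed")
  expect_error(build_wobble_availability(c(ACGU = 1)), "malformed")
})

test_that("wobble-decoded stop codons are never counted", {
  # UCA: codon1 = comp(A)=T, codon2 = comp(C)=G, U34 -> thirds A/G:
  # TGA (stop, dropped) and TGG (Trp, kept)
  tab <- build_wobble_availability(c(UCA = 6))
  expect_false("TGA" %in% names(tab$availability))
  expect_equal(unname(tab$availability[["TGG"]]), 6)
})

test_that("repeat_rate is the mean availability, order-invariant", {
  tr <- read_trna_table(system.file("extdata",
                                    "trna_anticodon_counts_synthetic.tsv",
                                    package = "polyrepeat"))
  # uniform table -> rate equals the constant
  unif <- tr
  unif$availability[] <- 7
  expect_equal(repeat_rate(R_UNIT, unif), 7)
  # permuting codon order leaves the mean unchanged
  set.seed(3)
  cods <- substring(R_UNIT, seq(1, 37, 3), seq(3, 39, 3))
  perm <- paste(sample(cods), collapse = "")
  expect_equal(repeat_rate(perm, tr), repeat_rate(R_UNIT, tr))
  expect_error(repeat_rate(paste0(substr(R_UNIT, 1, 36), "TAA"), tr), "stop")
})

test_that("replacing a codon by a higher-availability synonym raises the rate", {
  tr <- read_trna_table(system.file("extdata",
                                    "trna_anticodon_counts_synthetic.tsv",
                                    package = "polyrepeat"))
  cods <- substring(R_UNIT, seq(1, 37, 3), seq(3, 39, 3))
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  done <- FALSE
  for (i in seq_along(cods)) {
    syn <- names(gc)[gc == gc[[cods[i]]]]
    better <- syn[tr$availability[syn] > tr$availability[[cods[i]]]]
    if (length(better)) {
      new <- cods
      new[i] <- better[1L]
      expect_gt(repeat_rate(paste(new, collapse = ""), tr),
                repeat_rate(R_UNIT, tr))
      done <- TRUE
      break
    }
  }
  expect_true(done)
})

test_that("extremal codings bracket natural codings and rank first/last", {
  tr <- read_trna_table(system.file("extdata",
                                    "trna_anticodon_counts_synthetic.tsv",
                                    package = "polyrepeat"))
  ex <- extremal_codings(CANONICAL_PEPTIDE, tr)
  rO <- repeat_rate(ex$optimal, tr)
  rW <- repeat_rate(ex$worst, tr)
  expect_gte(rO, rW)
  set.seed(13)
  for (i in 1:20) {
    r <- repeat_rate(rand_coding(CANONICAL_PEPTIDE), tr)
    expect_lte(r, rO)
    expect_gte(r, rW)
  }
  cat <- data.frame(class_label = c("O", "W", "N"),
                    nt_seq = c(ex$optimal, ex$worst, R_UNIT))
  rk <- rank_repeats(cat, tr)
  expect_equal(rk$ranking$class_label[1L], "O")
  expect_equal(rk$ranking$class_label[3L], "W")
  expect_equal(dim(rk$per_codon), c(3L, 13L))
  # heatmap rows are consistent with the rate column
  expect_equal(rowMeans(rk$per_codon), stats::setNames(rk$ranking$rate,
                                                       rk$ranking$class_label))
})

test_that("rank order is invariant under strictly monotone rescaling", {
  tr <- read_trna_table(system.file("extdata",
                                    "trna_anticodon_counts_synthetic.tsv",
                                    package = "polyrepeat"))
  set.seed(4)
  cat <- data.frame(class_label = LETTERS[1:6],
                    nt_seq = replicate(6, rand_coding(CANONICAL_PEPTIDE)))
  r1 <- rank_repeats(cat, tr)$ranking$class_label
  tr2 <- tr
  tr2$availability <- 3 * tr$availability + 1  # strictly monotone
  r2 <- rank_repeats(cat, tr2)$ranking$class_label
  expect_identical(r1, r2)
})

test_that("a precomputed codon TSV loads and must cover all sense codons", {
  tmp <- tempfile(fileext = ".tsv")
  sense <- polyrepeat:::.sense_codons()
  write_tsv(data.frame(codon = sense, availability = seq_along(sense)), tmp)
  tab <- read_trna_table(tmp)
  expect_s3_class(tab, "trna_table")
  expect_equal(length(tab$availability), 61L)
  write_tsv(data.frame(codon = sense[-1L],
                       availability = seq_along(sense[-1L])), tmp)
  expect_error(read_trna_table(tmp), "missing sense codons")
})
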