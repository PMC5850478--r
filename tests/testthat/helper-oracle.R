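# Independent oracles and fixture builders used across tests.

# Exhaustive codon-aligned window scan, independent of the package's
# detection path: translates every window with Biostrings and reports all
# 0-based codon starts within max_mismatch of the target peptide.
oracle_scan <- function(seq_nt, peptide, max_mismatch) {
  k <- nchar(peptide)
  n_codons <- nchar(seq_nt) %/% 3L
  if (n_codons < k) return(integer(0))
  canon <- strsplit(peptide, "")[[1L]]
  starts <- 0:(n_codons - k)
  windows <- substring(seq_nt, 3L * starts + 1L, 3L * (starts + k))
  aas <- as.character(Biostrings::translate(Biostrings::DNAStringSet(windows)))
  keep <- !grepl("*", aas, fixed = TRUE)
  mm <- vapply(strsplit(aas, ""), function(a) sum(a != canon), integer(1L))
  starts[keep & mm <= max_mismatch]
}

# independent degeneracy table and random synonymous coding
.gc_dna <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})
rand_coding <- function(peptide) {
  paste(vapply(strsplit(peptide, "")[[1L]], function(aa) {
    cods <- names(.gc_dna)[.gc_dna == aa]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1L)), collapse = "")
}

# build one random ORF with n planted repeat units (possibly 0), short
# random leader/spacers free of tryptophan codons, returning the sequence
# and the planted 0-based codon starts
make_random_orf <- function(n_units, peptide = CANONICAL_PEPTIDE,
                            variant_prob = 0.1,
                            variants = VARIANT_PEPTIDES) {
  filler_aas <- c("A", "D", "E", "G", "K", "L", "N", "P", "Q", "R", "S", "T")
  rand_filler <- function(n_codons) {
    if (n_codons == 0L) return("")
    paste(vapply(sample(filler_aas, n_codons, replace = TRUE), function(aa) {
      cods <- names(.gc_dna)[.gc_dna == aa]
      sample(cods, 1L)
    }, character(1L)), collapse = "")
  }
  leader_codons <- sample(3:15, 1L)
  leader <- paste0("ATG", rand_filler(leader_codons - 1L))
  seq <- leader
  starts <- integer(0)
  pos <- leader_codons
  for (i in seq_len(n_units)) {
    spacer_codons <- sample(2:8, 1L)
    pep <- if (stats::runif(1L) < variant_prob) sample(variants, 1L) else peptide
    seq <- paste0(seq, rand_filler(spacer_codons), rand_coding(pep))
    pos <- pos + spacer_codons
    starts <- c(starts, pos)
    pos <- pos + nchar(peptide)
  }
  seq <- paste0(seq, rand_filler(sample(0:4, 1L)), "TAA")
  list(sequence = seq, starts = starts, n_units = n_units)
}

# canonical repeat coding used in hand-built examples (translates to
# WHWLQLKPGQPMY under the standard code)
R_UNIT <- "TGGCATTGGTTGCAACTAAAACCAGGCCAACCAATGTAC"
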