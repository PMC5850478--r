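# Genetic-code helpers shared across modules. The standard code is taken from
# Biostrings::GENETIC_CODE; codons are DNA-alphabet, uppercase.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

.sense_codons <- function() {
  gc <- .codon_table()
  names(gc)[gc != "*"]
}

#' Translate an in-frame nucleotide string
#'
#' @param nt Uppercase A/C/G/T string whose length is divisible by 3.
#' @return Single-letter amino-acid string; stop codons translate to `*`.
#' @keywords internal
translate_nt <- function(nt) {
  if (nchar(nt) %% 3L != 0L) stop("sequence length not divisible by 3")
  gc <- .codon_table()
  codons <- substring(nt, seq(1L, nchar(nt), by = 3L), seq(3L, nchar(nt), by = 3L))
  aa <- gc[codons]
  if (anyNA(aa)) stop("non-ACGT codon in sequence: ", codons[which(is.na(aa))[1L]])
  paste(aa, collapse = "")
}

#' Synonymous codons for one amino acid
#' @keywords internal
codons_for <- function(aa) {
  gc <- .codon_table()
  names(gc)[gc == aa]
}

#' Number of distinct synonymous nucleotide codings of a peptide
#'
#' Product over residues of the standard genetic code's codon degeneracy;
#' an upper bound on how many synonymous repeat classes can ever be observed
#' for a given mature peptide.
#'
#' @param peptide Peptide string over the 20 standard residues.
#' @return Integer-valued count (returned as double to avoid overflow).
#' @examples
#' count_synonymous_codings("M")             # 1
#' count_synonymous_codings("WHWLQLKPGQPMY") # 73728
#' @export
count_synonymous_codings <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) >= 1L)
  gc <- .codon_table()
  deg <- table(gc[gc != "*"])
  res <- strsplit(peptide, "")[[1L]]
  bad <- setdiff(res, names(deg))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  prod(as.numeric(deg[res]))
}

# Hamming distance between equal-length strings
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Split an in-frame nt string into codons
.codons_of <- function(nt) {
  substring(nt, seq(1L, nchar(nt), by = 3L), seq(3L, nchar(nt), by = 3L))
}
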