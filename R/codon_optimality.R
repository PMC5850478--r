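# Codon-optimality scoring of repeat codings by wobble-adjusted tRNA
# availability: the gene copy number of every tRNA able to decode a codon,
# summed under a fixed wobble rule set, then averaged over the 13 codons of
# a repeat. The score is comparative (decoding-speed proxy), not an absolute
# translation rate.

# Wobble rule sets: which codon third bases (DNA alphabet) an anticodon
# first base (position 34) can read. "strict" is Watson-Crick only.
.wobble_rules <- list(
  standard = list(A = c("T", "C", "A"),  # A34 read as inosine: U, C, A
                  C = "G",
                  G = c("C", "T"),       # G:U wobble
                  U = c("A", "G")),      # U:G wobble
  strict = list(A = "T", C = "G", G = "C", U = "A")
)

.complement_rna_to_dna <- c(A = "T", C = "G", G = "C", U = "A")

#' Build a wobble-adjusted tRNA availability table
#'
#' Converts per-anticodon tRNA gene copy counts into per-codon availability:
#' for each sense codon, the sum of gene copies of all anticodons that can
#' decode it. Codon positions 1-2 pair with anticodon positions 3-2 by
#' Watson-Crick rules; at the codon third position the rule set applies
#' (default: standard pairs, G:U wobble, and anticodon A34 treated as
#' inosine reading U/C/A). Copy numbers are used unweighted.
#'
#' @param counts Named numeric vector (names = RNA-alphabet anticodons,
#'   5'->3') or data frame with columns `anticodon`, `copies`.
#' @param rules `"standard"` (default) or `"strict"` (Watson-Crick only).
#' @param source Free-text provenance label stored on the table.
#' @return A `trna_table`: list with `availability` (named numeric over all
#'   61 sense codons) and `source`.
#' @export
build_wobble_availability <- function(counts, rules = c("standard", "strict"),
                                      source = "anticodon counts") {
  rules <- match.arg(rules)
  if (is.data.frame(counts)) {
    stopifnot(all(c("anticodon", "copies") %in% names(counts)))
    counts <- stats::setNames(as.numeric(counts$copies), counts$anticodon)
  }
  stopifnot(is.numeric(counts), length(counts) >= 1L, all(counts >= 0))
  ac <- toupper(names(counts))
  ac <- gsub("T", "U", ac)
  if (any(nchar(ac) != 3L) || any(grepl("[^ACGU]", ac)))
    stop("malformed anticodon(s): ",
         paste(names(counts)[nchar(ac) != 3L | grepl("[^ACGU]", ac)], collapse = ", "))

  rule <- .wobble_rules[[rules]]
  sense <- .sense_codons()
  avail <- stats::setNames(numeric(length(sense)), sense)
  for (i in seq_along(ac)) {
    a <- strsplit(ac[i], "")[[1L]]
    codon12 <- paste0(.complement_rna_to_dna[a[3L]], .complement_rna_to_dna[a[2L]])
    third <- rule[[a[1L]]]
    codons <- paste0(codon12, third)
    codons <- intersect(codons, sense)  # wobble-decoded stops are not counted
    avail[codons] <- avail[codons] + counts[i]
  }
  structure(list(availability = avail, source = source, rules = rules),
            class = "trna_table")
}

#' Load a tRNA availability table from TSV
#'
#' Accepts either a precomputed codon table (columns `codon`,
#' `availability`) or raw anticodon gene counts (columns `anticodon`,
#' `copies`), in which case [build_wobble_availability()] is applied.
#'
#' @param path TSV path.
#' @param rules Wobble rule set for anticodon input.
#' @return A `trna_table`.
#' @export
read_trna_table <- function(path, rules = "standard") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (all(c("codon", "availability") %in% names(tab))) {
    sense <- .sense_codons()
    codons <- gsub("U", "T", toupper(tab$codon))
    miss <- setdiff(sense, codons)
    if (length(miss)) stop("codon table missing sense codons: ",
                           paste(miss, collapse = ", "))
    avail <- stats::setNames(as.numeric(tab$availability), codons)[sense]
    if (any(avail < 0)) stop("negative availability")
    structure(list(availability = avail, source = path, rules = "as supplied"),
              class = "trna_table")
  } else if (all(c("anticodon", "copies") %in% names(tab))) {
    build_wobble_availability(tab, rules = rules, source = path)
  } else {
    stop("TSV must have columns codon+availability or anticodon+copies")
  }
}

#' @export
print.trna_table <- function(x, ...) {
  cat("<trna_table>", length(x$availability), "sense codons; rules:",
      x$rules, "; source:", x$source, "\n")
  invisible(x)
}

#' Mean tRNA availability of a repeat coding
#'
#' The "rate" score of one 39-nt repeat unit: the arithmetic mean of
#' per-codon tRNA availability over its 13 codons.
#'
#' @param nt_seq 39-nt repeat coding with no stop codon.
#' @param table A `trna_table`.
#' @return Numeric score.
#' @export
repeat_rate <- function(nt_seq, table) {
  stopifnot(inherits(table, "trna_table"))
  if (nchar(nt_seq) %% 3L != 0L) stop("repeat length not divisible by 3")
  codons <- .codons_of(toupper(nt_seq))
  gc <- .codon_table()
  if (any(gc[codons] == "*")) stop("repeat coding contains a stop codon")
  mean(table$availability[codons])
}

#' Rank repeat classes by codon optimality
#'
#' Sorts catalog classes by descending mean tRNA availability (ties broken
#' alphabetically by class label) and returns the per-codon availability
#' matrix behind the ranking (rows = classes, columns = codon positions).
#'
#' @param catalog Class catalog data frame (from [build_catalog()]`$catalog`)
#'   or any data frame with `class_label` and `nt_seq`.
#' @param table A `trna_table`.
#' @return List with `ranking` (data frame `class_label`, `nt_seq`, `rate`)
#'   and `per_codon` (numeric matrix).
#' @export
rank_repeats <- function(catalog, table) {
  stopifnot(all(c("class_label", "nt_seq") %in% names(catalog)))
  rates <- vapply(catalog$nt_seq, repeat_rate, numeric(1L), table = table)
  per_codon <- t(vapply(catalog$nt_seq, function(s)
    unname(table$availability[.codons_of(s)]),
    numeric(nchar(catalog$nt_seq[1L]) %/% 3L)))
  rownames(per_codon) <- catalog$class_label
  ord <- order(-rates, catalog$class_label)
  ranking <- data.frame(class_label = catalog$class_label[ord],
                        nt_seq = catalog$nt_seq[ord],
                        rate = unname(rates[ord]),
                        stringsAsFactors = FALSE)
  list(ranking = ranking, per_codon = per_codon[ord, , drop = FALSE])
}

#' Extremal synonymous codings under an availability table
#'
#' Builds the optimal ("O": per-residue argmax availability codon) and worst
#' ("W": per-residue argmin) synonymous codings of a peptide, the synthetic
#' constructs used to bracket natural repeat codings.
#'
#' @param peptide Peptide string.
#' @param table A `trna_table`.
#' @return List with `optimal` and `worst` nucleotide strings.
#' @export
extremal_codings <- function(peptide, table) {
  res <- strsplit(peptide, "")[[1L]]
  pick <- function(aa, f) {
    cods <- codons_for(aa)
    cods[f(table$availability[cods])]
  }
  list(optimal = paste(vapply(res, pick, character(1L), f = which.max), collapse = ""),
       worst = paste(vapply(res, pick, character(1L), f = which.min), collapse = ""))
}
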