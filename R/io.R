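# File input/output: FASTA ORF collections and TSV exports.
# FASTA headers follow the convention strain_id|species|lineage.

#' Read a collection of polyprotein ORFs from FASTA
#'
#' Headers of the form `strain|species|lineage` populate the grouping
#' fields; headers without `|` yield records with only a strain id.
#'
#' @param path FASTA file of ORF nucleotide sequences.
#' @return List of [orf_record()] objects.
#' @export
read_orf_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    parts <- strsplit(names(ss)[i], "|", fixed = TRUE)[[1L]]
    orf_record(strain_id = parts[1L],
               sequence = as.character(ss[[i]]),
               species = if (length(parts) >= 2L) parts[2L] else NA_character_,
               lineage = if (length(parts) >= 3L) parts[3L] else NA_character_)
  })
}

#' Write a collection of ORFs to FASTA
#'
#' @param orfs List of [orf_record()] objects.
#' @param path Output path.
#' @export
write_orf_fasta <- function(orfs, path) {
  ss <- Biostrings::DNAStringSet(vapply(orfs, function(o) o$sequence, character(1L)))
  names(ss) <- vapply(orfs, function(o)
    paste(c(o$strain_id, o$species, o$lineage)[!is.na(c(o$strain_id, o$species, o$lineage))],
          collapse = "|"), character(1L))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Export labeled repeat arrays as a table
#'
#' One row per ORF with repeat count, array string, and 1-based closed
#' nucleotide intervals of each unit (`start1-end1;start2-end2;...`).
#'
#' @param arrays Labeled arrays from [build_catalog()].
#' @param path Optional TSV output path.
#' @return The table, invisibly if written.
#' @export
array_table <- function(arrays, path = NULL) {
  tab <- do.call(rbind, lapply(arrays, function(a) {
    s <- 3L * a$units$codon_start + 1L
    e <- s + nchar(a$units$nt_seq) - 1L
    data.frame(strain_id = a$orf$strain_id,
               n_repeats = nrow(a$units),
               array_string = a$array_string,
               unit_positions_nt_1based = paste(paste0(s, "-", e), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a long-format phenotype table from TSV
#'
#' Expected columns (subset by assay): `strain_id` or `group`,
#' `plate` or `replicate`, `treatment` (plus_a / minus_a / none), `value`,
#' `assay`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
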