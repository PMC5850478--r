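# Decomposition of polyprotein ORFs into mature-peptide-encoding tandem
# repeat arrays, classification of repeat codings, and collection summaries.
#
# The canonical system is the yeast alpha-factor precursor: a 13-residue
# mature peptide (WHWLQLKPGQPMY) encoded by 39-nt in-frame units repeated
# 1-8 times within one ORF, separated by short spacers.

#' Canonical mature alpha-factor peptide
#' @export
CANONICAL_PEPTIDE <- "WHWLQLKPGQPMY"

#' Construct and validate an ORF record
#'
#' An ORF record holds one strain allele of the polyprotein gene. The
#' sequence must be a complete coding sequence: starts with ATG, length a
#' multiple of 3, ends in a stop codon, and has no internal in-frame stop.
#'
#' @param strain_id Strain identifier.
#' @param sequence Uppercase A/C/G/T coding sequence.
#' @param species,lineage Optional grouping labels.
#' @return An object of class `orf_record`.
#' @export
orf_record <- function(strain_id, sequence, species = NA_character_,
                       lineage = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("ORF for strain ", strain_id, " contains non-ACGT characters")
  if (nchar(sequence) %% 3L != 0L)
    stop("ORF for strain ", strain_id, " has length not divisible by 3")
  if (substr(sequence, 1L, 3L) != "ATG")
    stop("ORF for strain ", strain_id, " does not begin with ATG")
  pep <- translate_nt(sequence)
  n_aa <- nchar(pep)
  if (substr(pep, n_aa, n_aa) != "*")
    stop("ORF for strain ", strain_id, " does not end with a stop codon")
  if (grepl("\\*", substr(pep, 1L, n_aa - 1L)))
    stop("ORF for strain ", strain_id, " contains an internal stop codon")
  structure(list(strain_id = strain_id, species = species, lineage = lineage,
                 sequence = sequence, peptide = substr(pep, 1L, n_aa - 1L)),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat("<orf_record>", x$strain_id, "-", nchar(x$sequence), "nt,",
      nchar(x$peptide), "codons\n")
  invisible(x)
}

#' Find mature-peptide-encoding repeat units in an ORF
#'
#' Scans codon-aligned windows of `nchar(canonical_peptide)` codons and
#' reports every window whose translation differs from the canonical peptide
#' in at most `max_mismatch` residues. Overlaps are resolved greedily left to
#' right: after accepting a window the scan resumes at the codon following
#' it. Real arrays have spacers of two or more codons between units, so the
#' greedy result coincides with an exhaustive window scan on biological
#' input; greedy resolution only matters for adversarial overlapping hits.
#'
#' Detection is codon-aligned in the ATG-anchored reading frame only; the
#' repeats are in-frame units of the proprotein, so no frame-shifted or
#' reverse-strand search is performed.
#'
#' @param orf An [orf_record()].
#' @param canonical_peptide Mature peptide to search for (default
#'   [CANONICAL_PEPTIDE]).
#' @param max_mismatch Maximum residue mismatches per unit (0-2; default 1,
#'   since observed variant repeats differ by a single residue).
#' @return A data frame of units with columns `codon_start` (0-based codon
#'   index), `nt_seq`, `peptide`, `n_mismatches`, `class_label` (filled by
#'   [build_catalog()]), `is_edge`.
#' @export
find_repeats <- function(orf, canonical_peptide = CANONICAL_PEPTIDE,
                         max_mismatch = 1L) {
  stopifnot(inherits(orf, "orf_record"))
  stopifnot(max_mismatch >= 0L, max_mismatch <= 2L)
  k <- nchar(canonical_peptide)
  canon <- strsplit(canonical_peptide, "")[[1L]]
  pep <- strsplit(orf$peptide, "")[[1L]]  # excludes the stop
  n_codons <- length(pep)

  starts <- integer(0)
  mism <- integer(0)
  i <- 0L  # 0-based codon index
  while (i + k <= n_codons) {
    m <- sum(pep[(i + 1L):(i + k)] != canon)
    if (m <= max_mismatch) {
      starts <- c(starts, i)
      mism <- c(mism, m)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }

  nt_seq <- if (length(starts)) {
    substring(orf$sequence, 3L * starts + 1L, 3L * (starts + k))
  } else character(0)
  units <- data.frame(
    codon_start = starts,
    nt_seq = nt_seq,
    peptide = vapply(starts, function(s)
      paste(pep[(s + 1L):(s + k)], collapse = ""), character(1L)),
    n_mismatches = mism,
    class_label = rep(NA_character_, length(starts)),
    is_edge = rep(FALSE, length(starts)),
    stringsAsFactors = FALSE
  )
  if (nrow(units) > 0L) units$is_edge[c(1L, nrow(units))] <- TRUE
  units
}

#' Decompose an ORF into a repeat array
#'
#' Splits the ORF into leader, repeat units, inter-unit spacers and tail such
#' that concatenating `leader_nt`, the units interleaved with `spacers_nt`,
#' and `tail_nt` reconstructs the input sequence byte for byte.
#'
#' @param orf An [orf_record()].
#' @param units Units from [find_repeats()] on the same ORF.
#' @param allow_empty If `TRUE`, an ORF with zero units yields a degenerate
#'   array whose leader is the whole sequence; if `FALSE` (default) this is
#'   an error.
#' @return An object of class `repeat_array`.
#' @export
decompose <- function(orf, units = find_repeats(orf), allow_empty = FALSE) {
  stopifnot(inherits(orf, "orf_record"), is.data.frame(units))
  n <- nrow(units)
  if (n == 0L) {
    if (!allow_empty)
      stop("no repeat units found in strain ", orf$strain_id,
           " (set allow_empty = TRUE for a degenerate array)")
    return(structure(list(orf = orf, units = units, array_string = "",
                          leader_nt = orf$sequence, spacers_nt = character(0),
                          tail_nt = ""), class = "repeat_array"))
  }
  units <- units[order(units$codon_start), , drop = FALSE]
  nt_start <- 3L * units$codon_start + 1L
  nt_end <- nt_start + nchar(units$nt_seq) - 1L
  if (n > 1L && any(nt_start[-1L] <= nt_end[-n]))
    stop("internal error: overlapping repeat units for strain ", orf$strain_id)
  units$is_edge <- FALSE
  units$is_edge[c(1L, n)] <- TRUE
  leader <- substr(orf$sequence, 1L, nt_start[1L] - 1L)
  spacers <- if (n > 1L)
    substring(orf$sequence, nt_end[-n] + 1L, nt_start[-1L] - 1L)
  else character(0)
  tail_nt <- substr(orf$sequence, nt_end[n] + 1L, nchar(orf$sequence))
  arr <- structure(list(orf = orf, units = units, array_string = NA_character_,
                        leader_nt = leader, spacers_nt = spacers,
                        tail_nt = tail_nt), class = "repeat_array")
  stopifnot(identical(reassemble(arr), orf$sequence))
  arr
}

#' Reassemble a repeat array into its ORF sequence
#'
#' @param array A `repeat_array`.
#' @return The reconstructed nucleotide string (equal to the input ORF).
#' @export
reassemble <- function(array) {
  stopifnot(inherits(array, "repeat_array"))
  n <- nrow(array$units)
  if (n == 0L) return(array$leader_nt)
  mid <- character(2L * n - 1L)
  mid[seq(1L, 2L * n - 1L, by = 2L)] <- array$units$nt_seq
  if (n > 1L) mid[seq(2L, 2L * n - 2L, by = 2L)] <- array$spacers_nt
  paste0(array$leader_nt, paste(mid, collapse = ""), array$tail_nt)
}

#' @export
print.repeat_array <- function(x, ...) {
  cat("<repeat_array>", x$orf$strain_id, "-", nrow(x$units), "units",
      if (!is.na(x$array_string)) paste0("[", x$array_string, "]") else "",
      "\n")
  invisible(x)
}

# Latin labels: A..Z, AA, AB, ... (presentation-only identifiers)
.latin_label <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Build a repeat-class catalog and label arrays
#'
#' Assigns one class label per distinct unit nucleotide sequence across a
#' set of repeat arrays. Synonymous classes (unit peptide equal to the
#' canonical peptide) receive Latin-letter labels A, B, C, ... in order of
#' first appearance; nonsynonymous classes receive labels v1, v2, ...
#' (ASCII-safe stand-ins for the Greek letters conventionally used in repeat
#' diagrams). Label identity is presentation-only: it depends on input
#' order, but the induced partition of sequences into classes does not.
#'
#' To obtain species-specific catalogs (letters restarted per species), call
#' this function once per species subset.
#'
#' @param arrays List of `repeat_array` objects sharing one canonical peptide.
#' @param canonical_peptide The canonical mature peptide.
#' @return List with `catalog` (data frame: `class_label`, `nt_seq`,
#'   `peptide`, `synonymous`, `n_occurrences`, `edge_fraction`) and `arrays`
#'   (the input arrays with `class_label` and `array_string` filled in).
#' @export
build_catalog <- function(arrays, canonical_peptide = CANONICAL_PEPTIDE) {
  stopifnot(is.list(arrays), all(vapply(arrays, inherits, logical(1L), "repeat_array")))
  seqs <- unlist(lapply(arrays, function(a) a$units$nt_seq), use.names = FALSE)
  peps <- unlist(lapply(arrays, function(a) a$units$peptide), use.names = FALSE)
  edges <- unlist(lapply(arrays, function(a) a$units$is_edge), use.names = FALSE)
  first <- !duplicated(seqs)
  uniq_seq <- seqs[first]
  uniq_pep <- peps[first]
  syn <- uniq_pep == canonical_peptide
  labels <- character(length(uniq_seq))
  labels[syn] <- .latin_label(seq_len(sum(syn)))
  labels[!syn] <- paste0("v", seq_len(sum(!syn)))
  names(labels) <- uniq_seq

  occ <- table(factor(seqs, levels = uniq_seq))
  edge_frac <- vapply(uniq_seq, function(s) mean(edges[seqs == s]), numeric(1L))
  catalog <- data.frame(
    class_label = labels,
    nt_seq = uniq_seq,
    peptide = uniq_pep,
    synonymous = syn,
    n_occurrences = as.integer(occ),
    edge_fraction = edge_frac,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  arrays <- lapply(arrays, function(a) {
    a$units$class_label <- unname(labels[a$units$nt_seq])
    a$array_string <- paste(a$units$class_label, collapse = "")
    a
  })
  list(catalog = catalog, arrays = arrays)
}

#' Summarise a labeled repeat-array collection
#'
#' Collection-level statistics over decomposed, labeled arrays: per-group
#' (species and lineage) repeat-number range and class counts, classes
#' shared between groups, the number of lineages whose members differ in
#' repeat number, and per-class edge occupancy. Counts are per ORF (one
#' array per record), not per strain.
#'
#' @param arrays Labeled arrays (from [build_catalog()]).
#' @param metadata Data frame with columns `strain_id`, `species`, `lineage`.
#' @param canonical_peptide The canonical mature peptide.
#' @return List with `by_species`, `by_lineage`, `shared_classes` (pairwise
#'   between species), `n_lineages_with_repeat_number_change`, and
#'   `edge_occupancy`.
#' @export
collection_summary <- function(arrays, metadata,
                               canonical_peptide = CANONICAL_PEPTIDE) {
  stopifnot(all(c("strain_id", "species", "lineage") %in% names(metadata)))
  ids <- vapply(arrays, function(a) a$orf$strain_id, character(1L))
  missing_ids <- setdiff(ids, metadata$strain_id)
  if (length(missing_ids))
    stop("strain(s) absent from metadata: ", paste(missing_ids, collapse = ", "))
  meta <- metadata[match(ids, metadata$strain_id), ]

  per_orf <- data.frame(
    strain_id = ids,
    species = meta$species,
    lineage = meta$lineage,
    n_repeats = vapply(arrays, function(a) nrow(a$units), integer(1L)),
    stringsAsFactors = FALSE
  )
  unit_df <- do.call(rbind, lapply(seq_along(arrays), function(i) {
    u <- arrays[[i]]$units
    if (nrow(u) == 0L) return(NULL)
    data.frame(species = meta$species[i], lineage = meta$lineage[i],
               class_label = u$class_label, nt_seq = u$nt_seq,
               synonymous = u$peptide == canonical_peptide,
               is_edge = u$is_edge, stringsAsFactors = FALSE)
  }))

  group_stats <- function(var) {
    do.call(rbind, lapply(split(seq_len(nrow(per_orf)), per_orf[[var]]), function(idx) {
      g <- per_orf[[var]][idx[1L]]
      ug <- unit_df[unit_df[[var]] == g, ]
      data.frame(group = g,
                 n_orfs = length(idx),
                 repeat_min = min(per_orf$n_repeats[idx]),
                 repeat_max = max(per_orf$n_repeats[idx]),
                 n_synonymous_classes = length(unique(ug$nt_seq[ug$synonymous])),
                 n_nonsynonymous_classes = length(unique(ug$nt_seq[!ug$synonymous])),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }

  species <- unique(per_orf$species)
  shared <- if (length(species) >= 2L) {
    pairs <- utils::combn(species, 2L, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(p) {
      s1 <- unique(unit_df$nt_seq[unit_df$species == p[1L]])
      s2 <- unique(unit_df$nt_seq[unit_df$species == p[2L]])
      sh <- intersect(s1, s2)
      data.frame(species_1 = p[1L], species_2 = p[2L],
                 n_shared_classes = length(sh),
                 shared_classes = paste(unique(unit_df$class_label[
                   unit_df$nt_seq %in% sh]), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else NULL

  lin_change <- sum(vapply(split(per_orf$n_repeats, per_orf$lineage),
                           function(x) length(unique(x)) > 1L, logical(1L)))

  edge_occ <- do.call(rbind, lapply(split(unit_df, unit_df$class_label), function(u) {
    data.frame(class_label = u$class_label[1L], n_occurrences = nrow(u),
               edge_fraction = mean(u$is_edge), stringsAsFactors = FALSE)
  }))
  row.names(edge_occ) <- NULL

  list(per_orf = per_orf,
       by_species = group_stats("species"),
       by_lineage = group_stats("lineage"),
       shared_classes = shared,
       n_lineages_with_repeat_number_change = lin_change,
       edge_occupancy = edge_occ)
}
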