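# Forward simulation of concerted evolution of repeat arrays: unequal
# crossing over between misaligned sister arrays, gene conversion between
# units, and synonymous point mutation. Unique flanking sequence around the
# array means crossover junctions fall strictly between internal repeats, so
# edge units are never exchanged by crossover -- the mechanism behind the
# observation that repeat-number change affects internal repeats while edge
# repeats are conserved.

# Arrays are represented as ordered unit vectors: either single-character
# class labels (possibly packed into one string, "ABBC") or 39-nt unit
# sequences. Helpers to move between the two forms:
.as_units <- function(x) {
  # a short pure-letter single string is a packed label array like "ABBC";
  # anything longer (e.g. a 39-nt unit sequence) is a one-unit array
  if (length(x) == 1L && nchar(x) > 1L && nchar(x) <= 12L &&
      grepl("^[A-Za-z]+$", x)) strsplit(x, "")[[1L]] else x
}
.as_input_form <- function(units, template) {
  if (length(template) == 1L && nchar(template) > 1L && nchar(template) <= 12L &&
      grepl("^[A-Za-z]+$", template)) paste(units, collapse = "") else units
}

#' Unequal crossing over between two repeat arrays
#'
#' Splices two equal-length arrays misaligned by `d` units at junction `j`
#' (counting unit boundaries from the array start, 1-based): the expanded
#' product takes the first `j` units of `x` followed by units `j - d + 1`
#' onward of `y` (length `n + d`); the contracted product takes the first
#' `j - d` units of `y` followed by units `j + 1` onward of `x` (length
#' `n - d`). The junction must satisfy `d + 1 <= j <= n - 1` so that both
#' products begin with a first unit and end with a last unit of a parent:
#' this encodes the unique-flank constraint that forbids exchanges within
#' edge repeats.
#'
#' @param x,y Arrays of equal repeat number `n >= 3`: character vectors of
#'   unit labels/sequences, or single packed label strings like `"ABBC"`.
#' @param d Misalignment offset, `1 <= d <= n - 2`.
#' @param j Junction, `d + 1 <= j <= n - 1`.
#' @return List with `product1` (n + d units) and `product2` (n - d units),
#'   in the same form as the input.
#' @examples
#' unequal_crossover("ABBC", "ABBC", d = 1, j = 2)  # "ABBBC" and "ABC"
#' @export
unequal_crossover <- function(x, y, d, j) {
  ux <- .as_units(x); uy <- .as_units(y)
  n <- length(ux)
  if (length(uy) != n) stop("arrays must have equal repeat number")
  if (n < 2L) stop("crossover requires at least 2 repeats")
  if (d < 1L || d > n - 1L) stop("offset d out of range [1, n-1]")
  if (j < d + 1L || j > n - 1L)
    stop("junction j out of range [d+1, n-1]: ",
         "the unique-flank constraint keeps junctions strictly internal")
  product1 <- c(ux[seq_len(j)], uy[(j - d + 1L):n])
  product2 <- c(uy[seq_len(j - d)], ux[(j + 1L):n])
  stopifnot(length(product1) == n + d, length(product2) == n - d)
  list(product1 = .as_input_form(product1, x),
       product2 = .as_input_form(product2, x))
}

#' Gene conversion between two units of one array
#'
#' Replaces the recipient unit's sequence/label by the donor's; repeat
#' number is unchanged. Indices are 1-based.
#'
#' @param array Unit vector or packed label string.
#' @param donor_index,recipient_index Distinct unit indices.
#' @return The converted array, in the same form as the input.
#' @examples
#' gene_conversion("AB", 1, 2)  # "AA"
#' @export
gene_conversion <- function(array, donor_index, recipient_index) {
  u <- .as_units(array)
  n <- length(u)
  if (donor_index < 1L || donor_index > n || recipient_index < 1L ||
      recipient_index > n) stop("unit index out of range")
  if (donor_index == recipient_index) stop("donor and recipient must differ")
  u[recipient_index] <- u[donor_index]
  .as_input_form(u, array)
}

#' Evolution simulation parameters
#'
#' @param crossover_rate,conversion_rate Expected events per array per
#'   generation (Poisson).
#' @param mutation_rate Substitutions per third-position site per generation
#'   (applies only when units are nucleotide sequences).
#' @param max_offset Maximum crossover misalignment in units.
#' @param seed RNG seed; identical seed and parameters give identical event
#'   logs.
#' @param retain `"one"`: after each crossover one product, chosen at
#'   random, continues the lineage. `"both"`: the second product founds a
#'   new lineage (population-style run).
#' @param mutation_mode `"synonymous"`: third-position changes restricted to
#'   those preserving the encoded residue; `"any"`: any third-position base
#'   change.
#' @return An `evo_params` list.
#' @export
evo_params <- function(crossover_rate = 0.05, conversion_rate = 0.05,
                       mutation_rate = 0, max_offset = 2L, seed = 1L,
                       retain = c("one", "both"),
                       mutation_mode = c("synonymous", "any")) {
  stopifnot(crossover_rate >= 0, conversion_rate >= 0, mutation_rate >= 0,
            max_offset >= 1L)
  structure(list(crossover_rate = crossover_rate,
                 conversion_rate = conversion_rate,
                 mutation_rate = mutation_rate,
                 max_offset = as.integer(max_offset),
                 seed = as.integer(seed),
                 retain = match.arg(retain),
                 mutation_mode = match.arg(mutation_mode)),
            class = "evo_params")
}

.is_nt_units <- function(u) {
  all(nchar(u) %% 3L == 0L) && !any(grepl("[^ACGT]", u)) && all(nchar(u) >= 3L)
}

# one synonymous (or arbitrary) third-position mutation at codon ci of unit u
.mutate_third <- function(unit, ci, mode) {
  codon <- substr(unit, 3L * ci - 2L, 3L * ci)
  gc <- .codon_table()
  if (mode == "synonymous") {
    cands <- codons_for(gc[[codon]])
    cands <- cands[substr(cands, 1L, 2L) == substr(codon, 1L, 2L) & cands != codon]
  } else {
    third <- setdiff(c("A", "C", "G", "T"), substr(codon, 3L, 3L))
    cands <- paste0(substr(codon, 1L, 2L), third)
    cands <- cands[gc[cands] != "*"]
  }
  if (!length(cands)) return(unit)
  new <- if (length(cands) == 1L) cands else sample(cands, 1L)
  paste0(substr(unit, 1L, 3L * ci - 3L), new,
         substr(unit, 3L * ci + 1L, nchar(unit)))
}

#' Simulate repeat-array lineages under concerted evolution
#'
#' Each lineage carries one array. Per generation, Poisson numbers of
#' unequal-crossover and gene-conversion events are applied (crossover
#' between two copies of the lineage's array, i.e. sister chromatids or
#' alleles, with offset drawn uniformly on `[1, min(max_offset, n - 2)]`
#' and junction uniformly on its valid range); optional synonymous point
#' mutation acts on codon third positions when units are nucleotide
#' sequences. Arrays with fewer than 3 repeats cannot undergo crossover
#' (no strictly internal junction exists) and such draws are logged as
#' skipped.
#'
#' @param initial_arrays List of arrays (unit vectors or packed label
#'   strings).
#' @param params An [evo_params()] object.
#' @param generations Number of generations (>= 1).
#' @param snapshot_every Record array snapshots every this many generations.
#' @return List with `final` (arrays), `snapshots`, `events` (log data
#'   frame), and `stats`: `edge_retention` and `internal_change_fraction`
#'   over crossover events, and the final repeat-number distribution.
#' @export
simulate_lineages <- function(initial_arrays, params = evo_params(),
                              generations, snapshot_every = max(1L, generations %/% 10L)) {
  stopifnot(inherits(params, "evo_params"), generations >= 1L)
  set.seed(params$seed)
  arrays <- lapply(initial_arrays, .as_units)
  ev <- list()
  snapshots <- list(`0` = arrays)
  log1 <- function(gen, lin, type, d = NA, j = NA, donor = NA, recipient = NA,
                   n_before, n_after, edges_retained = NA, internal_only = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      generation = gen, lineage = lin, type = type, d = d, j = j,
      donor = donor, recipient = recipient, n_before = n_before,
      n_after = n_after, edges_retained = edges_retained,
      internal_only = internal_only, stringsAsFactors = FALSE)
  }

  for (gen in seq_len(generations)) {
    lin <- 1L
    while (lin <= length(arrays)) {
      arr <- arrays[[lin]]
      n <- length(arr)
      # unequal crossing over
      for (e in seq_len(stats::rpois(1L, params$crossover_rate))) {
        n <- length(arr)
        if (n < 3L) { log1(gen, lin, "crossover_skipped", n_before = n, n_after = n); next }
        d <- sample.int(min(params$max_offset, n - 2L), 1L)
        j <- if (d + 1L == n - 1L) n - 1L else sample((d + 1L):(n - 1L), 1L)
        pr <- unequal_crossover(arr, arr, d, j)
        p1 <- .as_units(pr$product1); p2 <- .as_units(pr$product2)
        edges_ok <- identical(p1[1L], arr[1L]) &&
          identical(p1[length(p1)], arr[n]) &&
          identical(p2[1L], arr[1L]) && identical(p2[length(p2)], arr[n])
        internal <- (j - d) >= 1L && j <= n - 1L
        if (params$retain == "both") {
          arrays[[length(arrays) + 1L]] <- p2
          arr <- p1
        } else {
          arr <- if (stats::runif(1L) < 0.5) p1 else p2
        }
        if (length(arr) < 1L) arr <- p1[1L]  # defensive clamp, logged below
        log1(gen, lin, "crossover", d = d, j = j, n_before = n,
             n_after = length(arr), edges_retained = edges_ok,
             internal_only = internal)
      }
      # gene conversion
      for (e in seq_len(stats::rpois(1L, params$conversion_rate))) {
        n <- length(arr)
        if (n < 2L) { log1(gen, lin, "conversion_skipped", n_before = n, n_after = n); next }
        pair <- sample.int(n, 2L)
        arr <- .as_units(gene_conversion(arr, pair[1L], pair[2L]))
        log1(gen, lin, "conversion", donor = pair[1L], recipient = pair[2L],
             n_before = n, n_after = n)
      }
      # synonymous point mutation on third positions
      if (params$mutation_rate > 0 && .is_nt_units(arr)) {
        n_codons <- nchar(arr[1L]) %/% 3L
        hits <- which(stats::runif(length(arr) * n_codons) < params$mutation_rate)
        for (h in hits) {
          ui <- (h - 1L) %/% n_codons + 1L
          ci <- (h - 1L) %% n_codons + 1L
          arr[ui] <- .mutate_third(arr[ui], ci, params$mutation_mode)
          log1(gen, lin, "mutation", donor = ui, recipient = ci,
               n_before = length(arr), n_after = length(arr))
        }
      }
      arrays[[lin]] <- arr
      lin <- lin + 1L
    }
    if (gen %% snapshot_every == 0L || gen == generations)
      snapshots[[as.character(gen)]] <- arrays
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(generation = integer(0), lineage = integer(0),
               type = character(0), d = numeric(0), j = numeric(0),
               donor = numeric(0), recipient = numeric(0),
               n_before = integer(0), n_after = integer(0),
               edges_retained = logical(0), internal_only = logical(0))
  xo <- events[events$type == "crossover", ]
  stats_out <- list(
    n_crossovers = nrow(xo),
    edge_retention = if (nrow(xo)) mean(xo$edges_retained) else NA_real_,
    internal_change_fraction = if (nrow(xo)) mean(xo$internal_only) else NA_real_,
    repeat_number_distribution = table(vapply(arrays, length, integer(1L)))
  )
  list(final = arrays, snapshots = snapshots, events = events, stats = stats_out)
}
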