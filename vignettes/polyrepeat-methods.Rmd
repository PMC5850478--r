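---
title: "Methods: repeat-array decomposition, concerted evolution, and the translational trade-off"
author: "polyrepeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-array decomposition, concerted evolution, and the translational trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrepeat)
```

## The system

The yeast mating pheromone α-factor is a 13-residue peptide (WHWLQLKPGQPMY)
that is not encoded once but as a tandem array of 39-nt repeat units inside
the polyprotein precursor gene *MFα1*. One ORF carries a prepro leader, then
for each mature peptide a short Lys-Arg-initiated spacer plus the 13-codon
repeat, then a stop. Natural isolates differ both in the *number* of repeats
(roughly 2–6 units) and in the *synonymous coding* of each unit, and those
differences propagate to pheromone secretion rate, mating success and, via
transcript length, translation. `polyrepeat` implements the computational
side of this system: repeat-array decomposition and classification, codon
optimality scoring, a concerted-evolution simulator, a length-dependent
production model, the phenotype statistics used around such assays, and a
seeded synthetic-data generator that ties them together with known ground
truth.

## Repeat detection and array decomposition

Detection is deliberately narrow: the mature peptide is a required input and
the scan is codon-aligned in the single ATG-anchored reading frame, because
the repeats are in-frame units of a proprotein. `find_repeats()` slides a
13-codon window over the translated ORF and accepts every window within
`max_mismatch` residues of the canonical peptide (default 1, because the
observed variant repeats differ by exactly one residue). Overlaps are
resolved greedily left to right; genuine arrays separate units by spacers of
at least two codons, so on biological input the greedy result coincides with
an exhaustive scan of all windows — an equivalence the test suite checks
against an independent brute-force oracle on 1,000 randomized ORFs.
`decompose()` then splits the ORF into leader, units, spacers and tail under
a strict round-trip invariant: reassembly must reproduce the input sequence
byte for byte.

Classification (`build_catalog()`) assigns one label per distinct unit
nucleotide sequence: Latin letters A, B, C, … (then AA, AB, …) for
synonymous codings and v1, v2, … for codings whose peptide deviates from the
canonical one. Labels are assigned by first appearance in input order and
are presentation-only: permuting the input may permute labels but can never
merge or split classes, which is the property the tests pin down. Letter
restarts per species are obtained by building one catalog per species
subset.

## Codon optimality

Each repeat coding is scored by wobble-adjusted tRNA availability: per-codon
availability is the summed gene copy number of every tRNA that can decode
the codon, and a repeat's "rate" score is the arithmetic mean over its 13
codons. The default wobble rule set pairs codon positions 1–2 by
Watson–Crick rules and, at the third position, allows the standard pairs,
G:U wobble in both orientations, and anticodon A34 read as inosine (decoding
U, C and A). Copy numbers are used unweighted — no tAI-style selective
constraint weights — because the score is used only comparatively, to rank
codings; a `strict` Watson–Crick rule set is selectable because published
wobble conventions differ. The bundled table
(`trna_anticodon_counts_synthetic.tsv`) is an explicitly synthetic stand-in
with full sense-codon coverage and arbitrary copy numbers; real analyses
should supply organism-specific counts (either raw anticodon counts or a
precomputed codon table).

`extremal_codings()` constructs the per-residue argmax/argmin codings, the
synthetic "optimal" and "worst" sequences that bracket every natural coding
under any availability table; the tests verify the bracketing and the
invariance of the ranking under strictly monotone rescaling of the table.

## Concerted evolution by unequal crossing over

Tandem arrays homogenize and change length through unequal crossing over
and gene conversion. `unequal_crossover(x, y, d, j)` splices two
equal-length arrays misaligned by `d` units at junction `j`, producing one
expanded (`n + d`) and one contracted (`n − d`) product. The junction range
`d + 1 ≤ j ≤ n − 1` encodes the unique-flank constraint: because the
sequence flanking the array is single-copy, exchange points cannot fall
within the edge repeats, so both products begin and end with parental edge
units. Two consequences are exact, not statistical: repeat counts sum to
`2n` per event, and edge classes are retained in every crossover — the
mechanism behind the empirical signature that repeat-number change affects
internal repeats while edge repeats (including the edge-confined variant
units) are conserved. Gene conversion copies one unit over another without
length change; iterated conversion is absorbing and drives arrays to a
single class, the fully homogenized state. An optional synonymous point
mutation process acts on codon third positions only, since the observed
class catalog is dominated by synonymous variation.

A design point the underlying biology leaves open is whether one or both
crossover products persist; `simulate_lineages()` exposes both (`retain =
"one"` keeps a random product, `"both"` founds a new lineage). Rates are
per-array per-generation Poisson intensities with documented arbitrary
defaults (0.05), since only the qualitative pattern — not rates — is
claimed. Under the junction constraint a minimal valid crossover needs 3
repeats; smaller arrays skip the event (logged), so the contracted product
can never drop below 2 units and a defensive 1-unit clamp exists only as a
logged no-op. Identical seeds and parameters reproduce identical event
logs.

## The length-dependent translational trade-off

A transcript with `n` repeats has ORF length `L(n) = L0 + λ n`. Each
completed translation of the polyprotein releases `n` peptides, but
translation output falls with transcript length — empirically, protein
production is roughly a reciprocal function of ORF length, and log-log
slopes of full-length production against length near −1.2 to −1.3 have been
measured in this system. The model adopted is the simplest form consistent
with a log-log slope:

  P(n) = c · n · (L0 + λ n)^(−β)

with defaults β = 1.28 (the slope magnitude implied by the isogenic
repeat-number panel), L0 = 249 nt and λ = 63 nt (a 13-codon repeat plus an
8-codon spacer). For β ≤ 1, P is strictly increasing (asymptote c/λ at
β = 1); for β > 1 there is an interior optimum at n\* = L0/(λ(β − 1)).
`optimal_repeat_number()` always verifies the calculus against direct
evaluation over `1..n_max`. Note that with the default L0 and λ the
stationary point sits far above natural repeat numbers; the rise-and-plateau
regime around ~6 repeats corresponds to a smaller non-repeat length (e.g.
`L0 = 6·0.28·63 ≈ 106` at β = 1.28), and the package treats that
calibration as a scenario, not a claim.

Two estimators are provided. `loglog_slope()` is plain OLS of log
production on log length — the descriptive statistic used to compare
wildtype and *asc1* strains. `fit_beta()` exploits that the model is linear
after transformation, `log P − log n = log c − β log(L0 + λ n)`, and
returns (c, β) with standard errors. On noiseless model data both recover
the generating parameters to machine precision; a simulation study (100
replicates of 200 observations over n = 1..8 with log-normal noise of sd
0.1) recovers β = 1.28 within ±0.1 in ≥95% of replicates. A caution the
package preserves: the slope measured in the deletion experiment and the β
shaping the secretion curves are conceptually distinct estimates and are
reported separately, never conflated. In the pipeline, the log-log slope is
computed on full-length polyprotein production (secretion divided by `n`),
since `P(n)/n = c·L^(−β)` is the quantity whose slope against length is
−β.

`simulate_reinitiation()` is labelled a mechanism sketch: the proposed
explanation for length dependence is intrapolysomal ribosome reinitiation
("closed-loop" recycling favouring short transcripts). The event model —
memoryless fresh initiations at rate `k_on`, Bernoulli reinitiation with
probability `q(L)` per termination — is invented for transparency, not
measured; it exists because it has a closed form, `k_on/(1 − q)`, against
which the Monte-Carlo estimate is checked (within 3 SEs at q ∈ {0, 0.5,
0.9}), and because a length-decreasing `q(L)` reproduces length-decreasing
initiation rates qualitatively.

## Phenotype statistics

Secretion assays arrive as strain × plate × treatment tables with
multiplicative plate effects, so `lsmeans_plate()` fits the additive
fixed-effects model `value ~ group + plate (+ treatment)` — on the log
scale by default for secretion, because responses are reported as folds —
and reports least-squares (adjusted) means via emmeans, with Tukey HSD
pairwise comparisons on the studentized range at the model's residual
degrees of freedom. On balanced designs adjusted means equal raw group
means exactly, and additive plate shifts cancel from every contrast; both
are tested to machine precision. The compact-letter display (the lowercase
letters over group means in figures) uses the standard insert-and-absorb
algorithm, implemented in `cld_letters()`. An optional `group:treatment`
interaction is available but off by default; whether the original analyses
included one is unknowable from legends alone, so neither choice is
asserted.

The remaining statistics are deliberately small and exact in their
identities: `fold_response()` is a ratio of geometric means with a
log-scale Welch CI; `qpcr_relative()` is `E^(mean(ref Cts) − Ct_target)`
with two reference genes (efficiency default 2.0, configurable), invariant
to Ct origin and to reallocating Ct between the two references;
`mating_success()` is the focal/competitor ratio with a binomial-odds CI
(0 and ∞ handled with one-sided intervals); `relative_log_growth()` is the
difference of log-slope regressions, antisymmetric under role swap.

## The synthetic-data generator

The generator defines the study conditions the tests run under. Defaults:
two species with disjoint synonymous coding pools (7 and 9 classes), 71 and
62 strains in 6 and 5 lineages, repeat numbers 2–6 and 2–5; lineages are
seeded with a base repeat number and members deviate by ±1 with probability
0.3 total, so some lineages segregate repeat-number variation; one
single-residue variant peptide per species (WHWLRLKPGQPMY, WHWLQLKPGQPIY),
placed edge-only, carried by ~5% of strains. The scaffold leader is an
82-codon prepro-like placeholder (arbitrary sequence, deliberately free of
tryptophan so no leader window can come within one mismatch of the
canonical peptide) and spacers are 8-codon KR-initiated placeholders; both
are documented as arbitrary since real linker sequences are not modelled.
The scaffold makes ORF length exactly `249 + 63 n`, consistent with the
trade-off defaults. Secretion tables use the trade-off model with an
a-factor response fold of 2.6 (the average response magnitude; per-species
values around 2.2–2.8 are configurable), log-normal plate effects (sd 0.15)
and noise (sd 0.2), typical ELISA-scale variation. Mating counts are
binomial with success proportional to secretion, so the expected mating
ratio equals the secretion ratio (e.g. 4.3 when secretion differs
4.3-fold); qPCR Cts encode abundance as `baseline − log2(abundance)` plus
Gaussian cycle noise.

What the generator does *not* emulate: sequencing error, real linker/leader
sequence evolution, admixed ("mosaic") strains, correlated plate-by-strain
effects, qPCR efficiency drift, or selection. Passing tests therefore
demonstrate internal correctness and estimator-generator consistency under
these idealized conditions, not performance on raw laboratory data.

## Numerical choices and degenerate inputs

ORF validation rejects non-ACGT characters, length not divisible by 3,
missing ATG, internal stops and missing terminal stops, naming the strain.
Zero-unit ORFs raise an error from `decompose()` unless `allow_empty =
TRUE` returns a degenerate all-leader array. Ranking ties break
alphabetically by class label. Wobble-decoded stop codons are never counted
into availability. `fit_beta()` refuses designs with a single distinct
repeat number; `lsmeans_plate()` reports aliased terms on rank-deficient
designs rather than dropping them silently, and reduces to a plain mean for
a single group. Problem sizes used by the validation suite — 1,000 ORFs
for oracle equivalence, 10,000 crossover events, 100-replicate recovery
studies at 200 observations, a 50-strain demo pipeline — were chosen as the
smallest sizes at which the binomial/SE margins in the corresponding checks
are comfortably stable.

## Known limitations

- Repeat discovery requires the mature peptide; this is not a general
  tandem-repeat finder and does not align linker sequences.
- The availability score is comparative; absolute decoding rates are out of
  scope, as is codon-resolution elongation modelling (TASEP and kin).
- The crossover model is single-locus and selection-free; rates are not
  inferred from data.
- The trade-off functional form is an assumption consistent with a log-log
  slope; the package fits it but does not test it against alternatives.
- Label identity (which class is "A") is input-order dependent by design;
  only the partition is meaningful.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(demo_config(seed = 1L), out_dir = tempfile("demo"))
res$summary$by_species
res$tradeoff_fit[c("beta", "se_beta", "loglog_slope_fulllength")]
res$phenostats$a_factor_fold$fold
```

The README shows the printed output of this run.
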