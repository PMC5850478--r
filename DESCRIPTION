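Package: polyrepeat
Title: Tandem Mature-Peptide Repeats in Polyprotein Genes: Decomposition, Evolution and Translational Trade-Off
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing intragenic tandem repeats that encode mature
    peptides within polyprotein open reading frames, modelled on the yeast
    mating-pheromone precursor gene MFalpha1. Decomposes ORFs into arrays of
    39-nt alpha-factor-encoding repeat units, classifies synonymous and
    nonsynonymous repeat codings, scores codings by wobble-adjusted tRNA
    availability, forward-simulates concerted evolution of repeat arrays by
    unequal crossing over and gene conversion, fits a length-dependent
    translational trade-off model for peptide production, and computes the
    associated phenotype statistics (plate-adjusted least-squares means with
    Tukey HSD, pheromone-response fold changes, two-reference qPCR
    normalisation, competitive mating success, relative log growth). A
    seeded synthetic-data generator emulates a strain collection and its
    assays with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    emmeans,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
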