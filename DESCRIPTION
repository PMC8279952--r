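Package: dyadkin
Title: Maintenance and De Novo DNA-Methylation Kinetics from CpG-Dyad,
    Methylome and Long-Read Data
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies de novo DNA-methylation activity of the maintenance
    methyltransferase Dnmt1 from methylation-depleted embryonic stem cell
    rescue experiments. Provides pairwise methylome comparison in fixed
    windows and per element, a differentially methylated region (DMR) caller
    with length-matched randomly placed control regions and one-sided
    rank-sum enrichment over repeat annotation, long-read cross-validation
    of DMRs (deletion detection, CpG masking, per-region methylation with a
    minimum-CpG filter, coverage normalization), a discrete-generation
    hidden Markov model of CpG-dyad inheritance separating maintenance from
    de novo efficiency fitted to hairpin-bisulfite dyad counts, and
    permutation-FDR statistics for label-free interaction proteomics.
    Ships seeded synthetic-data generators emulating each experimental
    design so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
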