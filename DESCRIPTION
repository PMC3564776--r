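Package: ThermoComp
Title: Comparative Sequence-Composition Survey of Protein Thermostability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative surveys of protein thermoadaptation from
    sequence composition. Computes charged-versus-polar bias (CvP-bias),
    IVYWREL content, (E+K)/(Q+H) ratio, serine and charged content, mean
    hydropathy and codon-position GC statistics over per-species proteomes;
    builds reciprocal-best-hit orthologous sets from tabular similarity hits
    and trims their alignments to shared gap-free fragments; ranks species
    per orthologous set and accumulates rank sums; evaluates measures by ROC
    discrimination of thermophile/mesophile protein sets; correlates proteome
    means with body temperature and melting-temperature differences; and fits
    Boltzmann sigmoids to thermal-shift fluorescence curves to estimate Tm.
    A fully seeded synthetic-data generator produces proteomes, orthologous
    sets, coding sequences with controlled third-position GC, labelled
    homolog pairs and melt curves with known parameters so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
biocViews: Sequencing, Proteomics, Classification, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
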