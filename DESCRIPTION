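Package: polysloc
Title: Origin and Segregation of Homeologous S-Loci in Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for tracing the parental origin and inheritance
    of self-incompatibility haplogroups at the two homeologous S-loci of an
    allotetraploid plant. Provides corrected nucleotide distances
    (Jukes-Cantor, Kimura two-parameter, Nei-Gojobori Ka/Ks), identity-based
    haplogroup classification and parental-origin assignment, neighbor-joining
    phylogeny with Newick output, exact-rational F2 class distributions under
    disomic and tetrasomic inheritance models with chi-square goodness-of-fit
    model comparison, categorical association statistics (Cramer's V, Fisher's
    exact test, Evanno's delta-K), molecular-clock divergence dating with
    confidence-interval propagation, and a seeded synthetic-data generator
    emulating haplogroup sequence panels, allotetraploid genotype panels and
    F2 populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
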