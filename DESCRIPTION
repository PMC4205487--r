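Package: karyevol
Title: Ancestral Karyotype Reconstruction by Chromosomal Rearrangement Parsimony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parsimony reconstruction of ancestral karyotypes on a phylogeny
    under a chromosomal rearrangement event model (centric fusion, fission,
    pericentric inversion) with an independent ordered character for counts
    of CMA3-positive chromosome pairs. Parses karyotype formula strings
    (e.g. "18m-sm+26st-a"), computes minimal event distances and their
    unique event decompositions on the biarmed/uniarmed pair lattice, runs
    Sankoff (generalized) parsimony with enumeration of all most
    parsimonious ancestral state assignments, and simulates karyotype
    evolution along trees under Poisson event sampling for recovery
    experiments. Ships the five-species Nannacara-Ivanacara-Cleithracara
    dwarf cichlid dataset as a worked fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
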