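Package: pseudobipolar
Title: Pseudo-Bipolar Fungal Mating Systems: Meiosis Simulation, Marker
    Segregation and MAT Gene Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing fungal mating systems in which the two MAT
    compatibility regions (pheromone receptor and HD1/HD2 homeodomain genes)
    reside on one chromosome with infrequent but not suppressed recombination
    between them ("pseudo-bipolar"). Provides a two-checkpoint mating
    compatibility model with closed-form and Monte-Carlo sib-mating
    (inbreeding) odds for bipolar, tetrapolar and pseudo-bipolar
    architectures; a meiosis and cross simulator over a physical marker map
    with crossover hotspots, gene-conversion tracts, binucleate basidiospore
    packaging and asynchronous spore recovery; segregation analysis of
    progeny genotype tables (parental-origin assignment, diploid detection,
    crossover and gene-conversion calling by minimal-event parsimony,
    recombination fractions and kb/cM map densities, MAT-cohesion summaries,
    scaffold-orientation inference); Nei-Gojobori (1986) pairwise dN/dS with
    sliding-window and domain-partition averaging over codon alignments; and
    a strain-table survey classifying mating-system architecture from
    receptor-HD allele associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
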