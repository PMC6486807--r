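Package: plastidyn
Title: Structural Dynamics and Comparative Evolution of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying structural evolution of plastomes that carry
    large direct (DR) or inverted (IR) repeat pairs. Implements signed
    locally-collinear-block encoding of gene orders with breakpoint and
    Hannenhalli-Pevzner inversion distances, exact detection of dispersed
    direct/inverted repeat pairs, a repeat-mediated homologous-recombination
    model that enumerates full-length isomers and subgenomic molecules and
    classifies plastomes as DR, IR or IR/DR-coexisting, pairwise dN/dS
    estimation under a GY94-type codon model with F3x4 frequencies together
    with Nei-Gojobori counting and rank-sum group contrasts, two-state Mk
    ancestral-state reconstruction over tree samples, and correlation of
    repeat counts with rearrangement distances by Pearson tests and
    phylogenetically independent contrasts. A synthetic-data module generates
    every input the pipeline consumes (plastome architectures with planted
    repeats, inversion histories, codon alignments with known rates, Yule
    trees, Mk characters and Brownian tip values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
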