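Package: organphylo
Title: Intragenus Phylotyping of Organelle Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Marker discovery and strain typing for small circular organelle
    (plastid and mitochondrial) genomes of closely related algal strains.
    Screens every genic and intergenic region for interspecies phylogenetic
    markers by sensitivity (percent nucleotide difference), specificity
    (mean maximum-parsimony bootstrap support) and consistency with a
    reference tree built from concatenated protein-coding genes; discovers
    intraspecies multi-locus sequence typing (MLST) loci by a sliding-window
    segregating-site scan of whole-genome pairwise alignments; detects
    perfect microsatellites (SSRs) for strain-level identification; and
    estimates Nei-Gojobori (NG86) Ka/Ks with Jukes-Cantor correction.
    Includes a seeded simulator of annotated organelle-like genomes evolved
    along a known tree with rate hotspots, purifying selection, triplet
    indels and planted SSRs, used as the test harness for every analysis
    step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
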