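Package: breedsnp
Title: Breed-Specific SNP Database Construction and Validation from
    RNA-Seq Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to build and validate breed-specific single-nucleotide
    polymorphism (SNP) databases from per-sample RNA-seq variant calls in
    a multi-breed, multi-age cattle cohort. Implements stringent
    depth-and-accuracy call filtering with reduction reporting, four-way
    breed-occurrence categorization (ANY, breed-specific, and their
    breed-unique counterparts), de-novo SNP flagging at reference-N
    positions, reference-error candidate detection, candidate-gene/QTL
    interval hit counting and ranking, Genepop-style exact
    population-genetics tests (Hardy-Weinberg and genic/genotypic
    differentiation by full enumeration or Markov chain, with Fisher's
    combined probability over loci), and a neighbor-joining SNP phylogeny
    with site bootstrap. A synthetic cohort generator with planted
    breed-unique variants provides ground truth for end-to-end checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
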