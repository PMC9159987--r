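Package: reticulator
Title: Reticulate Evolution Inference from Multilocus Genotypes in Apogamous Fern Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring reticulate (hybrid) evolution in polyploid,
    apogamous plant complexes from chloroplast haplotypes, nuclear allele
    genotypes, ploidy and spore counts. Provides ploidy-aware amplicon allele
    calling (barcode demultiplexing, primer trimming, identity clustering and
    the top-k / minimum-read retention rules), haplotype collapsing and
    lineage-group assignment, genotype assembly with the unassorted-allele
    convention, identification of parental versus hybrid genotypes, maternal
    lineage inference from chloroplast-nuclear co-occurrence, hybrid formula
    assignment, construction and export of the hybridization network
    (reticulogram), allele-trait association mining, and a forward simulator
    of hybridization with apogamy for end-to-end validation. Ships a packaged
    fixture transcribing the published genotype table of the Pteris fauriei
    species group.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
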