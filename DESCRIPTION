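Package: phosgwas
Title: K-mer Presence/Absence GWAS and Phosphorus-Efficiency Phenotyping for
    the Medicago sativa Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An alignment-free association-mapping and phenotyping toolkit for
    phosphorus-efficiency studies in alfalfa and related Medicago taxa. Counts
    canonical 31-mers from genotyping-by-sequencing reads, builds a
    presence/absence marker matrix, estimates kinship from it, and tests each
    k-mer with a linear mixed model and likelihood-ratio test. Significant
    k-mers are merged into fragments by exact overlap, mapped to a reference
    genome, and annotated with candidate genes inside 100 kb linkage windows.
    Phenotype-side tools compute shoot phosphorus content, phosphorus
    utilisation efficiency, stress tolerance indices, root dry matter response
    groups, and p-distance redundancy pruning; root-system-architecture traits
    are extracted from binary rhizotron scan masks. A seeded synthetic-data
    generator produces every input the pipeline needs, so the whole chain can
    be exercised and validated without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    png,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
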