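Package: clonehap
Title: Clonal Haplotype Reconstruction from Mixed Tumor Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the clonal haplotypes of a heterogeneous tumor
    sample from paired-end sequencing reads. Read-pairs are collapsed to
    variant-position extracts (VPEs), the clonal structure is estimated by
    clustering variant allele frequencies, VPEs are greedily assembled into
    short chains, founding-clone sites are phased through an error-aware
    weighted linkage graph and a greedy maximum spanning tree, and
    descendant-clone sites are phased after stripping the expected
    read-depth contribution of parental clones. Includes a paired-end
    tumor read simulator with known clonal haplotypes under a linear
    evolution model, and metrics for scoring reconstructions against
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    mclust,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    Rsamtools,
    vcfR
Config/testthat/edition: 3
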