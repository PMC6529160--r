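Package: pananchor
Title: Coverage-Based Gene Duplication Calling, Pan-Genome Classification
    and Genetic Anchoring of Plant Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing de novo plant genome assemblies between
    accessions of a species: per-gene relative read-depth statistics and
    duplication / presence-absence calling between two accessions,
    core/dispensable/TE gene classification across an accession panel,
    transposable-element overlap flagging of protein-coding genes,
    reciprocal-best-hit synteny comparison with outlier and structural-variant
    block detection, F2 recombination-fraction estimation with contig grouping,
    ordering and orientation into pseudochromosomes (AGP/FASTA output), and
    genome-distribution statistics (structural-variant clustering around
    centromeres, homotetramer enrichment in gap-homologous sequence). A
    synthetic-data module generates assemblies, depth tracks, accession
    panels, F2 genotype matrices and hit tables with known truth so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
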