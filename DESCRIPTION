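Package: BSRmap
Title: Bulked Segregant RNA-Seq Mapping and Fine Mapping of Recessive Loci
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping single recessive loci in F2 populations from
    bulked segregant RNA sequencing (BSR-Seq) and marker-based fine mapping.
    Implements the Euclidean-distance (ED) allele-frequency statistic with a
    power transform and top-quantile region calling, chi-squared tests of
    Mendelian segregation ratios, recombinant counting with Kosambi map
    distances and flanking-interval determination from recessive homozygotes,
    candidate-gene extraction and codon-level SNP effect annotation in the
    mapped interval, and relative expression analysis of candidate genes by
    the 2^-delta-delta-Ct method. A synthetic-data generator simulates F2
    meioses, phenotype-selected bulks with sequencing noise, marker genotype
    tables and qPCR cycle-threshold tables with known ground truth, so the
    whole pipeline can be exercised and validated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, VariantAnnotation, GeneExpression, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
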