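Package: zwscan
Title: Sex-Linked Region Discovery and Degeneration Analysis for Young ZW Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying young female-heterogametic (ZW) sex chromosome
    systems from population resequencing, phased haplotype assemblies and
    allele-tagged expression data. Provides sex-linked variant and region
    discovery (per-sex heterozygosity criteria, Weir-Cockerham FST and
    female:male log2 ratios in sliding windows, linkage-disequilibrium
    profiles, k-mer sex markers, haplotig phase assignment), evolutionary
    strata detection via changepoint analysis with Nei-Gojobori Ka/Ks dating
    of gametolog pairs, classification of W-linked gene copies into
    loss-of-function categories, dosage-compensation testing (TPM
    normalization, allele-specific expression ratios, Hartigan's dip test and
    one-dimensional Gaussian mixture decomposition), gametolog gene-tree
    topology classification, and a fully specified synthetic ZW-system
    generator with truth tables so that every stage can be validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn
Config/testthat/edition: 3
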