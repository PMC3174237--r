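Package: haplodiv
Title: Comparative SNP and Haplotype Diversity and LD Decay in Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative genetic-diversity and linkage-disequilibrium
    analysis of biallelic SNP genotypes on panels of inbred lines, as used in
    maize germplasm studies. Classifies SNPs into intergenic, intronic and
    exonic markers from gene models; builds gene-window, disjoint 3-SNP
    sliding-window and 10 kb proximity-chain haplotype loci with an
    all-or-nothing missing rule; computes allele frequencies, minor allele
    frequency, heterozygosity and polymorphic information content (PIC) per
    marker set and germplasm set; derives Rogers genetic distances and
    neighbor-joining trees with Newick export; and measures pairwise
    linkage disequilibrium (R squared with exact-test significance),
    per-chromosome significant-pair summaries and distance-binned decay
    curves with decay-distance estimation. A founder-copying genotype
    simulator with tunable founder diversity and recombination intensity
    provides a self-contained two-subpopulation test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
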