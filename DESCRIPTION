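Package: markermine
Title: Mining and Validation of Species-Diagnostic KASP and SCAR Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating species-diagnostic molecular
    markers from genotyping-by-sequencing panels of hybridizing taxa. Implements
    the quality-control cascade for a VCF-derived genotype matrix (depth masking,
    mapping-quality, missingness, minor-allele-frequency and exact
    Hardy-Weinberg filters), mining of fixed homozygous alleles unique to a
    target species with two-stage training-set refinement, screening of flanking
    sequence for KASP (allele-specific PCR) and SCAR (amplicon-size) assay
    primers, genotype calling from endpoint FAM/HEX fluorescence and gel band
    patterns including a merged two-locus dominant + codominant decision rule,
    and diagnostic performance statistics (concordance, sensitivity,
    specificity) with Wilson score intervals and hybrid indices. A synthetic
    panel simulator reproduces the statistical structure of a hybrid-swarm
    validation panel (fixed-difference loci, F1 and backcross hybrids, a
    morphologically cryptic hybrid, missingness and depth contamination) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
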