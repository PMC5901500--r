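Package: daequant
Title: Differential Allelic Expression from Sanger Chromatogram Peak Heights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies differential allelic expression (DAE) at heterozygous
    SNPs from Sanger chromatogram peak heights. Reads AB1/ABIF traces and a
    plain-text trace dialect, extracts allele peak pairs with quality control,
    computes natural-log allelic ratios, orients reverse-strand reads to a
    common forward-strand allele ordering, removes assay-specific dye bias by
    centering on the mean genomic-DNA ratio per sequencing direction, and
    combines directions per sample. Group differences (affected family vs.
    controls vs. gDNA) are tested with exact or asymptotic Kruskal-Wallis and
    pairwise Wilcoxon rank-sum tests under a closed testing procedure. Includes
    an upstream SNP eligibility screen (Hardy-Weinberg exact test, call rate,
    minor allele frequency, heterozygote counts per group) and a synthetic-data
    generator (peak tables, chromatograms, genotype tables with pedigree
    gene-dropping) with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
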