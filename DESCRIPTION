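Package: xqtl
Title: Comparative Transcriptome-Proteome Genetics for Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the joint genetic analysis of transcript and protein
    abundance measured across a panel of inbred strains. Provides quality
    filters for peptide and microarray data (missingness, tryptic-sequence,
    signal-to-noise and heritability filters, probe SNP masking, SVD-based
    trend removal), robust concordance statistics built on the biweight
    midcorrelation (gene-level peptide-probeset pairing, trait-correlation
    sharing, resampling-based group tests, pathway and isoform-cluster
    concordance), linear mixed-model genome-wide association with
    identity-by-state kinship and REML variance components, Storey q-value
    false discovery rates, linkage-disequilibrium pruning, local/distant QTL
    classification, hotspot scans and eQTL-pQTL overlap analysis. A synthetic
    inbred-panel generator with known ground truth makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
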