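Package: pgxpanel
Title: Star-Allele Diplotyping, CYP2D6 Structural Variant Detection and
    Analytical Validation for Targeted Pharmacogenomic Panels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-sequencing analysis stack for targeted pharmacogenomic
    (PGx) NGS panels. Implements deterministic star-allele diplotype
    calling from qualified single-sample VCF variants by exhaustive
    pairwise enumeration with perfect-match semantics; CYP2D6 copy-number
    and hybrid-allele detection from paralog-filtered, control-normalized
    read-depth profiles; haplotype concordance assessment against
    reference-material truth sets with nomenclature harmonization;
    analytical performance metrics (accuracy, PPA, NPA, PPV,
    repeatability, reproducibility) and per-gene coverage summaries; and
    multi-step prioritization of rare, potentially actionable variants.
    A seedable synthetic-data generator produces VCF and coverage
    fixtures for every analysis path, so the full stack is testable
    without protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
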