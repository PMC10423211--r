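Package: chtii
Title: Clonal Hematopoietic Mutation Detection in Tumor-Infiltrating Immune Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage pipeline for identifying potential immunosuppressive
    clonal hematopoietic (CH) mutations in tumor-infiltrating immune (TII)
    cells from matched tumor/normal-blood somatic variant calls. Reads a
    MAF-dialect variant table, applies call-quality gates, selects
    protein-altering variants, classifies clonally expanded somatic mutations
    by a dual variant-allele-fraction window (2% < VAF < 25% in both blood and
    tumor), filters candidates by cohort frequency, population rarity,
    hypermutable-gene membership and SIFT/PolyPhen deleteriousness consensus,
    checks immune-cell expression against a labelled single-cell count matrix,
    and tabulates top-level pathways affected by significantly differentially
    expressed genes between carrier and non-carrier samples. Supporting
    statistics (Wilson/Wald/Clopper-Pearson binomial proportion intervals,
    Welch t tests with Satterthwaite degrees of freedom, Benjamini-Hochberg
    FDR control) are implemented directly. A synthetic cohort generator with
    planted ground truth makes every stage testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
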