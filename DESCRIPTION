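Package: metapair
Title: Paired Mucosa-Feces Metagenome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing paired gut metagenome profiles from two body
    sites (rectal mucosa biopsies and feces). Provides a seeded synthetic
    paired-cohort generator with planted ground truth, gene-catalog relative
    abundance profiling with taxonomic and KEGG Orthology aggregation,
    Bray-Curtis distances with principal coordinate ordination, paired
    Wilcoxon signed-rank and paired t differential-abundance screens with
    leave-one-feature-out correlation diagnostics, phenotype-stratified
    rank-sum comparisons (age, gender, BMI, polyp risk), and signed
    reporter-score pathway enrichment with resampled background correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
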