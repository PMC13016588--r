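Package: snpsim
Title: Pairwise SNP-Similarity Learning for Rare-Disease Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a pairwise genomic-context similarity classifier from a
    small set of disease-associated SNPs plus a large background pool of
    variants associated with other traits, then predicts, ranks and filters
    novel candidate SNPs for rare diseases where cohort sizes preclude a
    conventional genome-wide association study. Provides parsers for the two
    GWAS-Catalog tab-separated export dialects, the engineered per-SNP and
    pairwise absolute-difference features, a constrained random-forest
    similarity model with cross-validation and linear baselines, top-k
    candidate ranking with recurrence- and significance-based filtering,
    plot-ready summary tables (Manhattan, recurrence, gene categories,
    chromosome distribution), and a synthetic-catalog simulator so the whole
    pipeline can be exercised without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    pROC,
    ranger,
    readr,
    tibble,
    withr,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
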