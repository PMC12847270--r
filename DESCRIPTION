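Package: paddysoilq
Title: Soil Quality Indices and Grey Relational Treatment Ranking for
    Paddy Co-Culture Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for long-term rice-eel
    co-culture fertilization experiments: water-stable aggregate
    stability indices (R0.25, mean weight diameter, geometric mean
    diameter) from wet-sieve fraction masses, alpha-diversity summaries
    (Gini-Simpson, Pielou evenness) from taxon count tables,
    treatment-effect summaries (percent change versus control, one-way
    ANOVA with Tukey HSD compact letter displays, Pearson correlation
    matrices), and grey relational analysis for ranking fertilization
    treatments. Includes a seeded synthetic-data generator emulating the
    5-treatment x 2-depth x 3-replicate randomized block design so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
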