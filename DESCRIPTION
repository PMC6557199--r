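Package: gennet
Title: Genetic and Epigenetic Network Identification from Stage-Wise Expression and Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs stage-specific genetic and epigenetic networks (GENs)
    from candidate protein-protein interactions and TF/miRNA/lncRNA
    regulations together with expression and DNA-methylation profiles.
    Per-node regression models with a methylation attenuation term are fit by
    sign-constrained least squares; false-positive candidate edges are pruned
    by information-criterion model-order detection; core sub-networks are
    extracted by principal network projection (SVD of the identified ability
    matrix); consecutive disease stages are compared through edge turnover,
    basal-level shifts (DNA-methylation and protein-modification flags) and
    one-way ANOVA; and compounds are ranked by signature-reversal scoring
    against a drug-gene correlation matrix. A synthetic-data generator with
    planted ground truth makes every step testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
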