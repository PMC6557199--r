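# gennet

Stage-specific **genetic and epigenetic network (GEN)** construction from
expression and DNA-methylation profiles.

Cancer progression studies profile tumors at successive clinical stages
(normal tissue, early, middle, advanced) and ask how the regulatory
wiring — protein–protein interactions (PPIs) and TF/miRNA/lncRNA
regulations — rewires from stage to stage, and where DNA methylation and
protein modifications intervene.  Candidate wiring mined from interaction
databases (BioGRID-style PPIs, TF–target, miRNA–target, lncRNA–target
collections) is full of false positives.  `gennet` prunes it against
data, per stage, and carries the result through core-network extraction,
stage comparison and drug-repurposing scoring.

## The models

Every node gets a per-sample regression equation.  Protein *j* with
interaction partners *g* follows a bilinear interactive model

    y_j[n] = Σ_g α_jg · y_g[n] · y_j[n] + b_j + v_j[n]

and gene *i* with TF regulators *j*, lncRNA regulators *q* and miRNA
regulators *p* follows

    x_i[n] = Σ_j β_ij y_j[n] M_i[n] + Σ_q τ_iq l_q[n] M_i[n]
             − Σ_p δ_ip x_i[n] r_p[n] M_i[n] + k_i M_i[n] + ε_i[n],

with δ_ip ≥ 0 (miRNAs only repress; the constraint is enforced in the
fit) and the methylation attenuation

    M(m) = 1 / (1 + (m / 0.5)²)  ∈ [0.2, 1]

applied to every binding-affinity term (m is the methylation beta value;
M(0) = 1, M(1) = 0.2).  miRNA and lncRNA nodes follow analogous
equations.  The constant terms (basal levels) k_i and b_j matter twice:
stage-to-stage shifts in a gene's basal level are read as DNA-methylation
events, shifts in a protein's basal level as post-translational
modification events.

The pipeline is:

1. **System identification** — sign-constrained least squares per node
   (`fit_constrained_lsq`), then **system-order detection**
   (`detect_order`): BIC model selection along a greedy forward path,
   with a model-stability constraint and an output-error backward
   validation that together reject the degenerate fits bilinear
   regressors allow.  `identify_stage` returns the pruned "real" network.
2. **Principal network projection (PNP)** — SVD of the identified
   ability matrix; each node is scored by the norms D_L/D_R of its
   row/column projections onto the top singular structure
   (`project_network`), and the top-ranked proteins and TFs plus their
   attached ncRNAs form the core network (`extract_core`).
3. **Stage comparison** — edge turnover, basal-shift flags and one-way
   ANOVA differential expression between consecutive stages
   (`compare_stages`).
4. **Drug scoring** — compounds ranked by how well their gene
   correlations reverse the disease signature without disturbing
   housekeeping genes (`score_drugs`, `select_combination`).

A first-class synthetic-data module (`sim_config`,
`generate_ground_truth`, `simulate_stage`, `make_candidate_with_decoys`)
plants a known network and simulates data that satisfy the model
equations exactly up to noise, so every claim above is testable.

## Worked example

```r
library(gennet)

methylation_effect(c(0, 0.25, 0.5, 1))
#> [1] 1.0 0.8 0.5 0.2

cfg  <- sim_config(seed = 3)            # 50-node study condition
gt   <- generate_ground_truth(cfg)
#> ground-truth GEN: 50 nodes, 81 true edges, 4 exogenous roots
cand <- make_candidate_with_decoys(gt)  # half the candidates are decoys
#> candidate GEN: 50 nodes, 162 edges
d    <- simulate_stage(gt, "early")     # 80 samples, noise sd 0.05
idn  <- identify_stage(cand, d)
#> identified GEN (early): 50 node estimates, 86 surviving edges
unlist(score_edge_recovery(idn, gt$network))[1:2]
#> precision    recall
#> 0.9418605 1.0000000

sc <- project_network(assemble_ability_matrix(idn), 0.85)
head(sc[order(-sc$combined), ], 3)
#>    node       D_L      D_R combined
#> 48  TF1 1.2460468 2.962000 3.213422
#> 50  TF3 1.2818779 2.192906 2.540088
#> 49  TF2 0.8014132 2.273698 2.410802
```

Of the 162 candidate edges (81 true + 81 decoys), identification keeps
86, recovering all 81 true edges with 5 false positives.  The projection
scores rank the three TFs first — they carry most of the network's
linking energy as regulators (large D_R).

The full pipeline (simulate → identify per stage → PNP → stage
comparison → drug scoring) runs as one seeded, logged, deterministic
call:

```r
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 11)), "run_dir")
```

or from the shell via `inst/scripts/gennet-pipeline.R`.  The vignette
(`vignettes/gen-network-identification.Rmd`) documents the models, the
order-detection scheme and the generator's design choices.

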