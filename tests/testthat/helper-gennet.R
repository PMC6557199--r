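## shared fixtures: all built in code at test time

tiny_nodes <- function() {
  data.frame(symbol = c("A", "B", "TF1", "G1", "miR1", "L1"),
             kind = c("protein", "protein", "tf", "gene", "mirna", "lncrna"),
             stringsAsFactors = FALSE)
}

tiny_network <- function() {
  candidate_network(
    tiny_nodes(),
    data.frame(source = c("A", "TF1", "miR1", "L1"),
               target = c("B", "G1", "G1", "G1"),
               edge_class = c("ppi", "tf_gene", "mirna_gene", "lncrna_gene")))
}

## deterministic small stage dataset over the tiny network's nodes
tiny_stage <- function(N = 6L, stage = "early", methyl_G1 = NULL) {
  syms <- tiny_nodes()$symbol
  set.seed(421)
  expr <- matrix(stats::rlnorm(length(syms) * N, 0, 0.3), length(syms), N,
                 dimnames = list(syms, paste0("s", seq_len(N))))
  methyl <- matrix(if (is.null(methyl_G1)) stats::runif(N, 0, 0.6) else methyl_G1,
                   1, N, dimnames = list("G1", colnames(expr)))
  stage_dataset(stage, expr, methyl)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

## small simulation scenario used by several files
small_cfg <- function(seed = 3L, n_samples = 40L,
                      edge_counts = c(ppi = 5L, tf_gene = 6L, tf_mirna = 3L,
                                      tf_lncrna = 2L, mirna_gene = 3L,
                                      mirna_mirna = 1L, mirna_lncrna = 1L,
                                      lncrna_gene = 2L),
                      ...) {
  sim_config(n_protein = 4L, n_tf = 2L, n_gene = 6L, n_mirna = 3L,
             n_lncrna = 2L, n_samples = n_samples,
             edge_counts = edge_counts, seed = seed, ...)
}
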