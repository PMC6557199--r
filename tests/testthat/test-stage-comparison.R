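fake_core <- function(edges, stage) {
  structure(list(stage = stage, nodes = NULL, edges = edges, scores = NULL),
            class = "core_network")
}
edge_df <- function(...) {
  v <- list(...)
  data.frame(source = vapply(v, `[[`, "", 1L),
             target = vapply(v, `[[`, "", 2L),
             edge_class = vapply(v, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

test_that("edge comparison is an exact three-way partition", {
  e1 <- edge_df(c("A", "B", "ppi"), c("TF1", "G1", "tf_gene"))
  e2 <- edge_df(c("TF1", "G1", "tf_gene"), c("M1", "G1", "mirna_gene"))
  st <- diff_edges(fake_core(e1, "early"), fake_core(e2, "middle"))
  expect_equal(nrow(st), 3L)
  get <- function(s, t) st$status[st$source == s & st$target == t]
  expect_equal(get("A", "B"), "former_only")
  expect_equal(get("TF1", "G1"), "common")
  expect_equal(get("M1", "G1"), "later_only")

  ## identical cores -> all common; disjoint -> sizes preserved
  st2 <- diff_edges(fake_core(e1, "a"), fake_core(e1, "b"))
  expect_true(all(st2$status == "common"))
  e3 <- edge_df(c("L1", "G1", "lncrna_gene"))
  st3 <- diff_edges(fake_core(e1, "a"), fake_core(e3, "b"))
  expect_equal(sum(st3$status == "former_only"), 2L)
  expect_equal(sum(st3$status == "later_only"), 1L)
  ## partition property
  expect_equal(nrow(st3), 3L)
})

fake_idn_basal <- function(basal, kinds) {
  est <- lapply(names(basal), function(s)
    structure(list(target = s, model_kind = "gene", abilities = numeric(0),
                   basal = basal[[s]], residual_variance = 0,
                   included = character(0), ic_trace = numeric(0),
                   warnings = character(0)), class = "node_estimate"))
  names(est) <- names(basal)
  nodes <- data.frame(symbol = names(basal), kind = kinds)
  structure(list(stage = "x", estimates = est,
                 pruned = candidate_network(nodes,
                                            data.frame(source = character(0),
                                                       target = character(0),
                                                       edge_class = character(0))),
                 errors = character(0)),
            class = "identified_network")
}

test_that("basal-shift flags use a strict threshold", {
  kinds <- c(rep("gene", 4), rep("protein", 2))
  b1 <- stats::setNames(c(1, 1, 1, 1, 2, 2), c("G1", "G2", "G3", "G4", "P1", "P2"))
  b2 <- b1 + c(0.8, 0.01, -0.02, 0, 0.9, 0)
  f <- flag_basal_shifts(fake_idn_basal(as.list(b1), kinds),
                         fake_idn_basal(as.list(b2), kinds),
                         theta_gene = 0.5, theta_protein = 0.5)
  expect_equal(f$methyl_flags, "G1")
  expect_equal(f$ptm_flags, "P1")
  ## delta exactly at the threshold is NOT flagged
  f2 <- flag_basal_shifts(fake_idn_basal(as.list(b1), kinds),
                          fake_idn_basal(as.list(b2), kinds),
                          theta_gene = 0.8, theta_protein = 0.9)
  expect_length(f2$methyl_flags, 0L)
  expect_length(f2$ptm_flags, 0L)
})

test_that("flags ignore node order and nodes absent from one stage", {
  kinds <- c("gene", "gene", "gene")
  b1 <- list(G1 = 1, G2 = 1, G3 = 1)
  b2r <- list(G3 = 1, G1 = 2, G2 = 1)    # reordered, G1 shifted
  f <- flag_basal_shifts(fake_idn_basal(b1, kinds),
                         fake_idn_basal(b2r, kinds),
                         theta_gene = 0.5, theta_protein = 0.5)
  expect_equal(f$methyl_flags, "G1")
  ## extra node on one side only is skipped
  b2e <- c(b2r, list(G9 = 50))
  f2 <- flag_basal_shifts(fake_idn_basal(b1, kinds),
                          fake_idn_basal(b2e, c(kinds, "gene")),
                          theta_gene = 0.5, theta_protein = 0.5)
  expect_equal(f2$methyl_flags, "G1")
})

test_that("two-group ANOVA matches the pooled t-test and handles degeneracy", {
  mk <- function(m, stage) stage_dataset(stage, m)
  ## identical groups -> p = 1 by convention
  x <- matrix(3, 1, 4, dimnames = list("G1", paste0("s", 1:4)))
  de <- anova_annotate(mk(x, "early"), mk(x, "middle"))
  expect_equal(de$p_value, 1)
  expect_equal(de$direction, "ns")

  ## well-separated groups with tiny jitter
  set.seed(2)
  a <- matrix(rnorm(8, 0, 1e-3), 1, 8, dimnames = list("G1", paste0("a", 1:8)))
  b <- matrix(rnorm(8, 5, 1e-3), 1, 8, dimnames = list("G1", paste0("b", 1:8)))
  de2 <- anova_annotate(mk(a, "early"), mk(b, "middle"))
  expect_lt(de2$p_value, 1e-6)
  expect_equal(de2$direction, "higher_in_later")

  ## F = t^2: p equals the equal-variance two-sample t-test p
  set.seed(3)
  g1 <- matrix(rnorm(10), 1, 10, dimnames = list("G1", paste0("x", 1:10)))
  g2 <- matrix(rnorm(12, 0.4), 1, 12, dimnames = list("G1", paste0("y", 1:12)))
  de3 <- anova_annotate(mk(g1, "early"), mk(g2, "middle"))
  tt <- t.test(g2[1, ], g1[1, ], var.equal = TRUE)
  expect_equal(de3$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("null ANOVA p-values give a calibrated type-I rate", {
  set.seed(77)
  n_rep <- 1000L
  hits <- 0L
  for (i in seq_len(n_rep)) {
    p <- gennet:::.anova_two_group(rnorm(20), rnorm(20))[["p"]]
    if (p < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("epigenetic enzymes are ineligible at their minimum-expression stage", {
  mk_stage <- function(vals) {
    matrix(rep(vals, times = 3), nrow = length(vals), ncol = 3,
           dimnames = list(names(vals), paste0("s", 1:3)))
  }
  enz <- data.frame(symbol = c("E1", "E2", "E3"),
                    modification_class = c("ubiquitination", "acetylation",
                                           "deacetylation"))
  stages <- list(
    mk_stage(c(E1 = 1, E2 = 5, E3 = 2)),
    mk_stage(c(E1 = 2, E2 = 5, E3 = 1)),
    mk_stage(c(E1 = 3, E2 = 5, E3 = 1)),
    mk_stage(c(E1 = 4, E2 = 5, E3 = 3)))
  el <- enzyme_eligibility(stages, enz)
  ## E1: means 1,2,3,4 -> ineligible only at the first stage
  expect_equal(unlist(el[el$symbol == "E1", paste0("eligible_", c("normal", "early", "middle", "advanced"))],
                      use.names = FALSE), c(FALSE, TRUE, TRUE, TRUE))
  ## E2: all equal -> ineligible everywhere
  expect_true(all(unlist(el[el$symbol == "E2", 3:6]) == FALSE))
  ## E3: means 2,1,1,3 -> tied minima both ineligible
  expect_equal(unlist(el[el$symbol == "E3", 3:6], use.names = FALSE),
               c(TRUE, FALSE, FALSE, TRUE))
  ## missing enzyme is skipped with a warning
  expect_warning(enzyme_eligibility(stages,
                                    data.frame(symbol = "NOPE",
                                               modification_class = "acetylation")),
                 "missing")
})
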