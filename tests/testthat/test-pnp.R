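## helpers to fabricate identified networks without running identification
fake_idn <- function(nodes, edges, abilities, stage = "early") {
  net <- candidate_network(nodes, edges)
  est <- list()
  for (tg in unique(abilities$target)) {
    ab <- abilities[abilities$target == tg, ]
    est[[tg]] <- structure(list(target = tg, model_kind = "gene",
                                abilities = stats::setNames(ab$ability,
                                                            ab$regulator),
                                basal = 0, residual_variance = 0,
                                included = ab$regulator,
                                ic_trace = numeric(0),
                                warnings = character(0)),
                           class = "node_estimate")
  }
  structure(list(stage = stage, estimates = est, pruned = net,
                 errors = character(0)),
            class = "identified_network")
}

test_that("the ability matrix places estimates at (target, regulator)", {
  nodes <- data.frame(symbol = c("TF1", "G1"), kind = c("tf", "gene"))
  idn <- fake_idn(nodes,
                  data.frame(source = "TF1", target = "G1",
                             edge_class = "tf_gene"),
                  data.frame(target = "G1", regulator = "TF1",
                             ability = 0.5))
  H <- assemble_ability_matrix(idn)
  expect_equal(dim(H), c(2L, 2L))
  expect_equal(H["G1", "TF1"], 0.5)
  expect_equal(sum(H != 0), 1L)

  ## one-sided PPI estimates are symmetrized
  nodes2 <- data.frame(symbol = c("A", "B"), kind = "protein")
  idn2 <- fake_idn(nodes2,
                   data.frame(source = "A", target = "B",
                              edge_class = "ppi"),
                   data.frame(target = "A", regulator = "B", ability = 0.3))
  H2 <- assemble_ability_matrix(idn2)
  expect_equal(H2["A", "B"], 0.3)
  expect_equal(H2["B", "A"], 0.3)

  ## a miRNA repression shows up with its negative coefficient
  nodes3 <- data.frame(symbol = c("M1", "G1"), kind = c("mirna", "gene"))
  idn3 <- fake_idn(nodes3,
                   data.frame(source = "M1", target = "G1",
                              edge_class = "mirna_gene"),
                   data.frame(target = "G1", regulator = "M1",
                              ability = -0.4))
  expect_equal(assemble_ability_matrix(idn3)["G1", "M1"], -0.4)
})

test_that("projection values match closed forms and the SVD oracle", {
  H <- diag(c(3, 4)); dimnames(H) <- list(c("a", "b"), c("a", "b"))
  s <- project_network(H, 1.0)
  expect_equal(attr(s, "rank"), 2L)
  expect_equal(s$D_L, c(3, 4))
  expect_equal(s$D_R, c(3, 4))

  ## rank-1 outer product at 85% energy keeps one component
  H2 <- matrix(c(1, 2, 2, 4), 2, 2, byrow = TRUE)
  dimnames(H2) <- list(c("a", "b"), c("a", "b"))
  s2 <- project_network(H2, 0.85)
  expect_equal(attr(s2, "rank"), 1L)
  expect_equal(s2$D_L, c(sqrt(5), 2 * sqrt(5)))
  expect_equal(s2$D_R, c(sqrt(5), 2 * sqrt(5)))

  ## random matrices: Gram-matrix oracle and Frobenius identity
  set.seed(5)
  for (i in 1:5) {
    H3 <- matrix(rnorm(400), 20, 20,
                 dimnames = list(paste0("n", 1:20), paste0("n", 1:20)))
    s3 <- project_network(H3, 1.0)
    expect_equal(s3$D_L, unname(sqrt(diag(H3 %*% t(H3)))), tolerance = 1e-8)
    expect_equal(s3$D_R, unname(sqrt(diag(t(H3) %*% H3))), tolerance = 1e-8)
    expect_lt(abs(sum(s3$D_L^2) - sum(H3^2)), 1e-9 * sum(H3^2))
    expect_lt(abs(sum(s3$D_R^2) - sum(H3^2)), 1e-9 * sum(H3^2))
  }

  expect_error(project_network(matrix(0, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b")))),
               "degenerate")
})

test_that("rank grows with the energy threshold and scores dominate", {
  set.seed(8)
  H <- matrix(rnorm(225), 15, 15,
              dimnames = list(paste0("n", 1:15), paste0("n", 1:15)))
  thresholds <- c(0.5, 0.7, 0.85, 0.95, 1.0)
  ranks <- integer(0); prev <- NULL
  for (th in thresholds) {
    s <- project_network(H, th)
    ranks <- c(ranks, attr(s, "rank"))
    if (!is.null(prev)) {
      expect_true(all(s$D_L >= prev$D_L - 1e-12))
      expect_true(all(s$D_R >= prev$D_R - 1e-12))
    }
    prev <- s
  }
  expect_true(all(diff(ranks) >= 0))
})

test_that("projection is equivariant under node relabeling", {
  set.seed(13)
  H <- matrix(rnorm(64), 8, 8,
              dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  s <- project_network(H, 0.9)
  perm <- sample(8)
  Hp <- H[perm, perm]
  sp <- project_network(Hp, 0.9)
  expect_equal(sp$D_L[match(s$node, sp$node)], s$D_L, tolerance = 1e-10)
  expect_equal(sp$D_R[match(s$node, sp$node)], s$D_R, tolerance = 1e-10)
})

test_that("core extraction takes top-K per class and attaches ncRNAs", {
  nodes <- data.frame(
    symbol = c(paste0("P", 1:5), "TF1", "M1", "M2", "L1", "G1"),
    kind = c(rep("protein", 5), "tf", "mirna", "mirna", "lncrna", "gene"))
  edges <- data.frame(
    source = c("P1", "P2", "M1", "M2", "L1", "TF1"),
    target = c("P2", "P3", "G1", "G1", "G1", "G1"),
    edge_class = c("ppi", "ppi", "mirna_gene", "mirna_gene",
                   "lncrna_gene", "tf_gene"))
  abilities <- data.frame(
    target = c("P2", "P3", "G1", "G1", "G1", "G1"),
    regulator = c("P1", "P2", "M1", "M2", "L1", "TF1"),
    ability = c(2, 1, -0.5, -0.4, 0.3, 0.8))
  idn <- fake_idn(nodes, edges, abilities)
  scores <- project_network(assemble_ability_matrix(idn), 1.0)
  core <- extract_core(idn, scores, K_protein = 2L, K_tf = 1L)
  picked <- core$nodes
  expect_equal(sum(picked$reason == "top_protein"), 2L)
  expect_equal(sum(picked$reason == "top_tf"), 1L)
  ## P1 and P2 carry the largest abilities -> highest combined scores
  expect_true(all(c("P1", "P2") %in%
                    picked$symbol[picked$reason == "top_protein"]))
  ## all ncRNA edges here point at the gene G1, which is not a selected
  ## anchor, so nothing is attached
  expect_length(picked$symbol[startsWith(picked$reason, "attached")], 0L)
  ## every core edge joins two core nodes
  expect_true(all(core$edges$source %in% picked$symbol &
                    core$edges$target %in% picked$symbol))
})

test_that("hub nodes rank first by combined projection score", {
  ## a hub regulating many targets with large abilities dominates
  n <- 12L
  nodes <- data.frame(symbol = c("HUB", paste0("G", 1:(n - 1))),
                      kind = c("tf", rep("gene", n - 1)))
  edges <- data.frame(source = "HUB", target = paste0("G", 1:(n - 1)),
                      edge_class = "tf_gene")
  abilities <- data.frame(target = paste0("G", 1:(n - 1)),
                          regulator = "HUB", ability = 2)
  idn <- fake_idn(nodes, edges, abilities)
  H <- assemble_ability_matrix(idn)
  s <- project_network(H, 1.0)
  expect_equal(s$node[which.max(s$combined)], "HUB")
})
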