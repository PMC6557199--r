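## Synthetic GEN generator with planted ground truth.
##
## The generator plants a sparse true network over proteins (some flagged
## TF), genes, miRNAs and lncRNAs, then simulates stage-wise expression and
## methylation data that satisfy the per-node interactive/regulatory model
## equations exactly up to the drawn noise.  Every implicit equation is
## solved in closed form:
##   protein:  y_j = (b_j + v_j) / (1 - sum alpha_jg y_g)
##   gene:     x_i = ((sum beta y + sum tau l + k_i) M_i + eps) /
##                   (1 + sum delta r_p M_i)
##   miRNA:    r_p = ((sum lambda y + e_p) M_p + omega) / (1 + sum psi r_z M_p)
##   lncRNA:   l_q = ((sum gamma y + f_q) M_q + eta)   / (1 + sum zeta r_p M_q)
## Proteins (and miRNAs) are evaluated in a fixed randomized order with
## previously drawn nodes treated as exogenous, so each equation uses only
## already-known regulators; a sample is rejected and redrawn when any
## denominator magnitude falls below the stability margin.
## Nodes of kind protein/miRNA/lncRNA with no true regulators are exogenous
## roots drawn lognormal(0, 0.4) (positive, right-skewed like expression
## data); their rows are inputs, not modeled equations.

#' Simulation configuration
#'
#' Defaults define a 50-node study condition: 9 non-TF proteins, 3 TFs,
#' 20 genes, 10 miRNAs, 8 lncRNAs, 80 samples per stage, noise sd 0.05 for
#' every kind, decoy fraction 0.5.  Abilities are drawn uniformly on
#' +/-[0.3, 1.0] (signed classes) or [0.3, 1.0] magnitude (miRNA
#' repression, stored as the nonpositive coefficient), basal levels on
#' [0.5, 2]; methylation beta values come from per-gene per-stage Beta
#' distributions (default Beta(2, 8)).
#'
#' @param n_protein,n_tf,n_gene,n_mirna,n_lncrna node counts per kind
#'   (`n_protein` counts non-TF proteins).
#' @param n_samples samples per stage.
#' @param edge_counts named integer vector of true-edge counts per class.
#' @param max_in_degree cap on directed regulators per target.
#' @param noise_sd scalar or named vector (protein, gene, mirna, lncrna).
#' @param decoy_fraction fraction of the candidate network that is decoy.
#' @param basal_shifts data.frame (`node`, `from_stage`, `to_stage`,
#'   `shift`): the basal level of `node` changes by `shift` between the two
#'   stages (applied from `to_stage` onward).
#' @param methyl_shape1,methyl_shape2 default Beta parameters for gene
#'   methylation.
#' @param stability_margin minimum allowed |denominator| in the closed-form
#'   solves.
#' @param max_retries per-sample redraw budget before a simulation error.
#' @param seed integer seed; fixed seed implies identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_protein = 9L, n_tf = 3L, n_gene = 20L,
                       n_mirna = 10L, n_lncrna = 8L,
                       n_samples = 80L,
                       edge_counts = c(ppi = 18L, tf_gene = 20L,
                                       tf_mirna = 10L, tf_lncrna = 8L,
                                       mirna_gene = 12L, mirna_mirna = 3L,
                                       mirna_lncrna = 4L, lncrna_gene = 6L),
                       max_in_degree = 3L,
                       noise_sd = 0.05,
                       decoy_fraction = 0.5,
                       basal_shifts = NULL,
                       methyl_shape1 = 2, methyl_shape2 = 8,
                       stability_margin = 0.1,
                       ppi_topology = c("random", "backbone"),
                       max_retries = 200L,
                       seed = 1L) {
  ppi_topology <- match.arg(ppi_topology)
  if (length(noise_sd) == 1L)
    noise_sd <- c(protein = noise_sd, gene = noise_sd,
                  mirna = noise_sd, lncrna = noise_sd)
  stopifnot(all(c("protein", "gene", "mirna", "lncrna") %in% names(noise_sd)),
            all(noise_sd >= 0),
            decoy_fraction >= 0, decoy_fraction < 1,
            n_protein + n_tf >= 1L, n_gene >= 1L)
  ec <- c(ppi = 0L, tf_gene = 0L, tf_mirna = 0L, tf_lncrna = 0L,
          mirna_gene = 0L, mirna_mirna = 0L, mirna_lncrna = 0L,
          lncrna_gene = 0L)
  ec[names(edge_counts)] <- as.integer(edge_counts)
  structure(list(n_protein = as.integer(n_protein), n_tf = as.integer(n_tf),
                 n_gene = as.integer(n_gene), n_mirna = as.integer(n_mirna),
                 n_lncrna = as.integer(n_lncrna),
                 n_samples = as.integer(n_samples),
                 edge_counts = ec, max_in_degree = as.integer(max_in_degree),
                 noise_sd = noise_sd, decoy_fraction = decoy_fraction,
                 basal_shifts = basal_shifts,
                 methyl_shape1 = methyl_shape1, methyl_shape2 = methyl_shape2,
                 stability_margin = stability_margin,
                 ppi_topology = ppi_topology,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.runif_signed <- function(n, lo = 0.3, hi = 1.0) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, lo, hi)
}

## sample `count` directed pairs from sources x targets, no self pairs,
## respecting an in-degree cap; errors when infeasible
.sample_pairs <- function(sources, targets, count, in_deg, cap) {
  if (count == 0L) return(data.frame(source = character(0), target = character(0)))
  univ <- expand.grid(source = sources, target = targets,
                      stringsAsFactors = FALSE)
  univ <- univ[univ$source != univ$target, , drop = FALSE]
  univ <- univ[sample.int(nrow(univ)), , drop = FALSE]
  out_s <- character(0); out_t <- character(0)
  for (i in seq_len(nrow(univ))) {
    tg <- univ$target[i]
    if (in_deg[tg] >= cap) next
    out_s <- c(out_s, univ$source[i]); out_t <- c(out_t, tg)
    in_deg[tg] <- in_deg[tg] + 1L
    if (length(out_s) == count) break
  }
  if (length(out_s) < count)
    stop("infeasible degree caps: cannot place ", count, " edges")
  df <- data.frame(source = out_s, target = out_t, stringsAsFactors = FALSE)
  attr(df, "in_deg") <- in_deg
  df
}

#' Generate a planted ground-truth GEN
#'
#' @param cfg a [sim_config()].
#' @return object of class `ground_truth_gen`: list with `network`
#'   (`candidate_network` of true edges), `abilities` (data.frame `target`,
#'   `regulator`, `edge_class`, `ability` on the model-coefficient scale,
#'   so miRNA abilities are negative), `basal` (node x stage matrix),
#'   `roots` (exogenous symbols), `protein_order`, `mirna_order`,
#'   `methyl_shape1`/`methyl_shape2` (gene x stage matrices), `noise_sd`,
#'   `config`.
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  prot <- if (cfg$n_protein) paste0("P", seq_len(cfg$n_protein)) else character(0)
  tfs  <- if (cfg$n_tf) paste0("TF", seq_len(cfg$n_tf)) else character(0)
  gene <- paste0("G", seq_len(cfg$n_gene))
  mir  <- if (cfg$n_mirna) paste0("MIR", seq_len(cfg$n_mirna)) else character(0)
  lnc  <- if (cfg$n_lncrna) paste0("LNC", seq_len(cfg$n_lncrna)) else character(0)
  proteins <- c(prot, tfs)
  nodes <- data.frame(
    symbol = c(prot, tfs, gene, mir, lnc),
    kind = c(rep("protein", length(prot)), rep("tf", length(tfs)),
             rep("gene", length(gene)), rep("mirna", length(mir)),
             rep("lncrna", length(lnc))),
    stringsAsFactors = FALSE)

  protein_order <- sample(proteins)
  mirna_order <- sample(mir)
  rank_p <- stats::setNames(seq_along(protein_order), protein_order)
  rank_m <- stats::setNames(seq_along(mirna_order), mirna_order)

  ec <- cfg$edge_counts
  in_deg <- stats::setNames(integer(nrow(nodes)), nodes$symbol)

  ## PPI: undirected pairs; the ability lives in the later node's equation.
  ## A backbone connects each protein to one earlier partner (signaling
  ## networks are connected; only the first protein in the simulation order
  ## is an exogenous input), then the remaining quota is random pairs.
  npairs <- choose(length(proteins), 2L)
  if (ec[["ppi"]] > npairs) stop("infeasible degree caps: too many PPI edges")
  n_backbone <- if (identical(cfg$ppi_topology, "random")) 0L else
    min(ec[["ppi"]], length(proteins) - 1L)
  bb_src <- character(0); bb_tgt <- character(0)
  if (n_backbone > 0L)
    for (i in seq_len(n_backbone) + 1L) {
      bb_src <- c(bb_src, protein_order[sample.int(i - 1L, 1L)])
      bb_tgt <- c(bb_tgt, protein_order[i])
    }
  ppi <- data.frame(source = bb_src, target = bb_tgt, stringsAsFactors = FALSE)
  n_extra <- ec[["ppi"]] - n_backbone
  if (n_extra > 0L) {
    pairs <- data.frame(source = t(utils::combn(proteins, 2L))[, 1L],
                        target = t(utils::combn(proteins, 2L))[, 2L],
                        stringsAsFactors = FALSE)
    key <- function(df) paste(pmin(df$source, df$target),
                              pmax(df$source, df$target))
    pairs <- pairs[!(key(pairs) %in% key(ppi)), , drop = FALSE]
    pick <- sample.int(nrow(pairs), n_extra)
    ppi <- rbind(ppi, pairs[pick, ])
  }

  ## TF backbone for noncoding RNAs: the first min(quota, count) miRNAs /
  ## lncRNAs each get one TF regulator, so they are transcriptionally
  ## driven rather than exogenous
  backbone_tf <- function(targets, quota) {
    k <- min(quota, length(targets))
    if (k == 0L || !length(tfs))
      return(data.frame(source = character(0), target = character(0)))
    data.frame(source = sample(tfs, k, replace = TRUE),
               target = targets[seq_len(k)], stringsAsFactors = FALSE)
  }
  bb_mir <- backbone_tf(mirna_order, ec[["tf_mirna"]])
  bb_lnc <- backbone_tf(if (length(lnc)) sample(lnc) else lnc, ec[["tf_lncrna"]])
  in_deg[bb_mir$target] <- in_deg[bb_mir$target] + 1L
  in_deg[bb_lnc$target] <- in_deg[bb_lnc$target] + 1L

  cls_specs <- list(
    tf_gene      = list(src = tfs, tgt = gene, extra = 0L),
    tf_mirna     = list(src = tfs, tgt = mir, extra = nrow(bb_mir)),
    tf_lncrna    = list(src = tfs, tgt = lnc, extra = nrow(bb_lnc)),
    mirna_gene   = list(src = mir, tgt = gene, extra = 0L),
    mirna_mirna  = list(src = mir, tgt = mir, extra = 0L),
    mirna_lncrna = list(src = mir, tgt = lnc, extra = 0L),
    lncrna_gene  = list(src = lnc, tgt = gene, extra = 0L))
  edges <- rbind(
    data.frame(source = ppi$source, target = ppi$target,
               edge_class = "ppi", stringsAsFactors = FALSE),
    data.frame(source = bb_mir$source, target = bb_mir$target,
               edge_class = rep("tf_mirna", nrow(bb_mir)),
               stringsAsFactors = FALSE),
    data.frame(source = bb_lnc$source, target = bb_lnc$target,
               edge_class = rep("tf_lncrna", nrow(bb_lnc)),
               stringsAsFactors = FALSE))
  for (cls in names(cls_specs)) {
    sp <- cls_specs[[cls]]
    want <- ec[[cls]] - sp$extra
    if (want <= 0L) next
    if (!length(sp$src) || !length(sp$tgt))
      stop("infeasible config: class ", cls, " requested without nodes")
    df <- .sample_pairs(sp$src, sp$tgt, want, in_deg, cfg$max_in_degree)
    in_deg <- attr(df, "in_deg")
    edges <- rbind(edges, data.frame(source = df$source, target = df$target,
                                     edge_class = cls, stringsAsFactors = FALSE))
  }
  edges <- edges[!duplicated(.edge_key(edges)), , drop = FALSE]
  ## mirna_mirna: drop any planted pair where regulator is not earlier in the
  ## simulation order in both directions; re-orient so source precedes target
  mm <- edges$edge_class == "mirna_mirna"
  if (any(mm)) {
    bad <- rank_m[edges$source[mm]] > rank_m[edges$target[mm]]
    i <- which(mm)[bad]
    tmp <- edges$source[i]
    edges$source[i] <- edges$target[i]
    edges$target[i] <- tmp
    edges <- edges[!duplicated(.edge_key(edges)) & edges$source != edges$target, ,
                   drop = FALSE]
  }
  network <- candidate_network(nodes, edges)

  ## directed abilities (model-coefficient scale)
  e <- network$edges
  ab <- data.frame(target = character(0), regulator = character(0),
                   edge_class = character(0), ability = numeric(0),
                   stringsAsFactors = FALSE)
  for (k in seq_len(nrow(e))) {
    cls <- e$edge_class[k]
    if (cls == "ppi") {
      later <- if (rank_p[e$source[k]] > rank_p[e$target[k]]) e$source[k] else e$target[k]
      earlier <- setdiff(c(e$source[k], e$target[k]), later)
      ab <- rbind(ab, data.frame(target = later, regulator = earlier,
                                 edge_class = "ppi",
                                 ability = .runif_signed(1L),
                                 stringsAsFactors = FALSE))
    } else if (startsWith(cls, "mirna")) {
      ab <- rbind(ab, data.frame(target = e$target[k], regulator = e$source[k],
                                 edge_class = cls,
                                 ability = -stats::runif(1L, 0.3, 1.0),
                                 stringsAsFactors = FALSE))
    } else {
      ab <- rbind(ab, data.frame(target = e$target[k], regulator = e$source[k],
                                 edge_class = cls,
                                 ability = .runif_signed(1L),
                                 stringsAsFactors = FALSE))
    }
  }

  ## roots: protein/miRNA/lncRNA nodes with no true (directed) regulators
  has_reg <- unique(ab$target)
  roots <- setdiff(nodes$symbol[nodes$kind != "gene"], has_reg)

  basal <- matrix(stats::runif(nrow(nodes), 0.5, 2), nrow = nrow(nodes),
                  ncol = length(STAGES),
                  dimnames = list(nodes$symbol, STAGES))
  if (!is.null(cfg$basal_shifts)) {
    bs <- cfg$basal_shifts
    for (k in seq_len(nrow(bs))) {
      to_i <- match(bs$to_stage[k], STAGES)
      if (is.na(to_i) || !bs$node[k] %in% rownames(basal))
        stop("invalid basal shift entry: ", bs$node[k])
      basal[bs$node[k], to_i:length(STAGES)] <-
        basal[bs$node[k], to_i:length(STAGES)] + bs$shift[k]
    }
  }
  ## methylation covers every transcribed node (genes and noncoding RNA
  ## promoters, as on the 450K array); proteins have no methylation row
  meth_nodes <- c(gene, mir, lnc)
  sh1 <- matrix(cfg$methyl_shape1, length(meth_nodes), length(STAGES),
                dimnames = list(meth_nodes, STAGES))
  sh2 <- matrix(cfg$methyl_shape2, length(meth_nodes), length(STAGES),
                dimnames = list(meth_nodes, STAGES))

  structure(list(network = network, abilities = ab, basal = basal,
                 roots = roots, protein_order = protein_order,
                 mirna_order = mirna_order,
                 methyl_shape1 = sh1, methyl_shape2 = sh2,
                 noise_sd = cfg$noise_sd, config = cfg),
            class = "ground_truth_gen")
}

#' @export
print.ground_truth_gen <- function(x, ...) {
  cat("ground-truth GEN:", nrow(x$network$nodes), "nodes,",
      nrow(x$network$edges), "true edges,", length(x$roots),
      "exogenous roots\n")
  invisible(x)
}

.ab_lookup <- function(gt, target) {
  gt$abilities[gt$abilities$target == target, , drop = FALSE]
}

#' Simulate one stage's dataset from a planted ground truth
#'
#' Draws `n_samples` independent samples: methylation beta values from the
#' stage's per-gene Beta distributions, exogenous roots lognormal(0, 0.4),
#' then each modeled node in dependency order from its closed-form model
#' solution, so each generated value satisfies its model equation with
#' residual exactly the drawn noise.  Samples whose denominators fall
#' below the stability margin are redrawn (bounded by `max_retries`).
#'
#' @param gt a `ground_truth_gen`.
#' @param stage stage label.
#' @param n_samples number of samples (default from the config).
#' @param seed seed for this stage's draws.
#' @return a `stage_dataset`.
#' @export
simulate_stage <- function(gt, stage, n_samples = gt$config$n_samples,
                           seed = gt$config$seed) {
  stopifnot(inherits(gt, "ground_truth_gen"))
  stage <- match.arg(stage, STAGES)
  set.seed(seed)
  nodes <- gt$network$nodes
  syms <- nodes$symbol
  kind <- stats::setNames(nodes$kind, syms)
  genes <- syms[kind == "gene"]
  lncs <- syms[kind == "lncrna"]
  meths <- rownames(gt$methyl_shape1)
  sds <- gt$noise_sd
  margin <- gt$config$stability_margin
  basal <- gt$basal[, stage]

  expr <- matrix(NA_real_, length(syms), n_samples,
                 dimnames = list(syms, paste0(stage, "_S", seq_len(n_samples))))
  methyl <- matrix(NA_real_, length(meths), n_samples,
                   dimnames = list(meths, colnames(expr)))

  draw_sample <- function() {
    v <- stats::setNames(numeric(length(syms)), syms)
    m <- stats::rbeta(length(meths), gt$methyl_shape1[meths, stage],
                      gt$methyl_shape2[meths, stage])
    names(m) <- meths
    Mg <- methylation_effect(m)
    for (r in gt$roots) v[r] <- stats::rlnorm(1L, 0, 0.4)
    ## proteins in simulation order
    for (p in gt$protein_order) {
      if (p %in% gt$roots) next
      a <- .ab_lookup(gt, p)
      den <- 1 - sum(a$ability * v[a$regulator])
      if (abs(den) < margin) return(NULL)
      v[p] <- (basal[p] + stats::rnorm(1L, 0, sds[["protein"]])) / den
    }
    ## miRNAs in simulation order
    for (p in gt$mirna_order) {
      if (p %in% gt$roots) next
      a <- .ab_lookup(gt, p)
      tf_a <- a[a$edge_class == "tf_mirna", , drop = FALSE]
      mm_a <- a[a$edge_class == "mirna_mirna", , drop = FALSE]
      Mp <- Mg[[p]]
      den <- 1 - sum(mm_a$ability * v[mm_a$regulator]) * Mp  # ability = -psi
      if (abs(den) < margin) return(NULL)
      num <- (sum(tf_a$ability * v[tf_a$regulator]) + basal[p]) * Mp +
        stats::rnorm(1L, 0, sds[["mirna"]])
      v[p] <- num / den
    }
    ## lncRNAs
    for (q in lncs) {
      if (q %in% gt$roots) next
      a <- .ab_lookup(gt, q)
      tf_a <- a[a$edge_class == "tf_lncrna", , drop = FALSE]
      mi_a <- a[a$edge_class == "mirna_lncrna", , drop = FALSE]
      Mq <- Mg[[q]]
      den <- 1 - sum(mi_a$ability * v[mi_a$regulator]) * Mq  # ability = -zeta
      if (abs(den) < margin) return(NULL)
      num <- (sum(tf_a$ability * v[tf_a$regulator]) + basal[q]) * Mq +
        stats::rnorm(1L, 0, sds[["lncrna"]])
      v[q] <- num / den
    }
    ## genes
    for (g in genes) {
      a <- .ab_lookup(gt, g)
      tf_a <- a[a$edge_class == "tf_gene", , drop = FALSE]
      ln_a <- a[a$edge_class == "lncrna_gene", , drop = FALSE]
      mi_a <- a[a$edge_class == "mirna_gene", , drop = FALSE]
      Mi <- Mg[[g]]
      den <- 1 - sum(mi_a$ability * v[mi_a$regulator]) * Mi  # ability = -delta
      if (abs(den) < margin) return(NULL)
      num <- (sum(tf_a$ability * v[tf_a$regulator]) +
                sum(ln_a$ability * v[ln_a$regulator]) + basal[g]) * Mi +
        stats::rnorm(1L, 0, sds[["gene"]])
      v[g] <- num / den
    }
    list(v = v, m = m)
  }

  for (n in seq_len(n_samples)) {
    s <- NULL
    for (try in seq_len(gt$config$max_retries)) {
      s <- draw_sample()
      if (!is.null(s)) break
    }
    if (is.null(s))
      stop("simulation error: stability margin violated after ",
           gt$config$max_retries, " retries (sample ", n, ")")
    expr[, n] <- s$v[syms]
    methyl[, n] <- s$m[meths]
  }
  stage_dataset(stage, expr, methyl)
}

#' Simulate all four stages
#'
#' Per-stage seeds are derived deterministically from the config seed.
#'
#' @param gt a `ground_truth_gen`.
#' @param n_samples samples per stage.
#' @return named list of `stage_dataset` (normal, early, middle, advanced).
#' @export
simulate_study <- function(gt, n_samples = gt$config$n_samples) {
  out <- lapply(seq_along(STAGES), function(i)
    simulate_stage(gt, STAGES[i], n_samples,
                   seed = (gt$config$seed * 13L + i) %% 2147483647L))
  names(out) <- STAGES
  out
}

#' Add decoy edges to the true network
#'
#' Decoys are random non-edges of the same edge classes as the true edges
#' (allocated proportionally, largest remainder), never duplicating a true
#' edge, with `|decoys| = round(f * |true| / (1 - f))` so that decoys make
#' up fraction `f` of the candidate network.  Decoy membership is recorded
#' in the `"decoys"` attribute for scoring.
#'
#' @param gt a `ground_truth_gen`.
#' @param decoy_fraction fraction in [0, 1).
#' @param seed integer seed.
#' @return a `candidate_network` with attribute `decoys` (data.frame of the
#'   decoy edges).
#' @export
make_candidate_with_decoys <- function(gt, decoy_fraction = gt$config$decoy_fraction,
                                       seed = gt$config$seed) {
  stopifnot(decoy_fraction >= 0, decoy_fraction < 1)
  set.seed(seed)
  true_e <- gt$network$edges
  n_true <- nrow(true_e)
  n_decoy <- round(decoy_fraction * n_true / (1 - decoy_fraction))
  if (n_decoy == 0L) {
    out <- gt$network
    attr(out, "decoys") <- true_e[0L, ]
    return(out)
  }
  nodes <- gt$network$nodes
  kind <- stats::setNames(nodes$kind, nodes$symbol)
  cls_tab <- table(true_e$edge_class)
  quota <- floor(n_decoy * cls_tab / n_true)
  rem <- n_decoy - sum(quota)
  if (rem > 0) {
    frac <- n_decoy * cls_tab / n_true - quota
    add <- names(sort(frac, decreasing = TRUE))[seq_len(rem)]
    quota[add] <- quota[add] + 1L
  }
  true_keys <- .edge_key(true_e)
  decoys <- true_e[0L, c("source", "target", "edge_class")]
  for (cls in names(quota)) {
    if (quota[[cls]] == 0L) next
    rule <- .edge_kind_rules[[cls]]
    src <- nodes$symbol[kind[nodes$symbol] %in% rule$source]
    tgt <- nodes$symbol[kind[nodes$symbol] %in% rule$target]
    univ <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE)
    univ <- univ[univ$source != univ$target, , drop = FALSE]
    if (cls == "ppi") {
      flip <- univ$source > univ$target
      tmp <- univ$source[flip]
      univ$source[flip] <- univ$target[flip]
      univ$target[flip] <- tmp
      univ <- unique(univ)
    }
    univ$edge_class <- cls
    univ <- univ[!(.edge_key(univ) %in% true_keys), , drop = FALSE]
    if (nrow(univ) < quota[[cls]])
      stop("not enough non-edges available for class ", cls)
    decoys <- rbind(decoys, univ[sample.int(nrow(univ), quota[[cls]]), ])
  }
  out <- candidate_network(nodes, rbind(true_e[, c("source", "target", "edge_class")],
                                        decoys))
  rownames(decoys) <- NULL
  attr(out, "decoys") <- decoys
  out
}

#' Residuals of simulated data under the generative model equations
#'
#' Plugs a stage dataset back into every modeled node's equation and
#' returns the residuals (which equal the drawn noise; exactly 0 for a
#' zero-noise simulation).  Exogenous root rows are inputs and excluded.
#'
#' @param gt a `ground_truth_gen`.
#' @param data a `stage_dataset` simulated from `gt`.
#' @return matrix (modeled nodes x samples) of residuals.
#' @export
model_residuals <- function(gt, data) {
  nodes <- gt$network$nodes
  kind <- stats::setNames(nodes$kind, nodes$symbol)
  basal <- gt$basal[, data$stage]
  expr <- data$expr
  modeled <- setdiff(nodes$symbol, gt$roots)
  out <- matrix(NA_real_, length(modeled), ncol(expr),
                dimnames = list(modeled, colnames(expr)))
  for (s in modeled) {
    a <- .ab_lookup(gt, s)
    v <- expr[s, ]
    if (kind[s] %in% c("protein", "tf")) {
      pred <- as.vector(a$ability %*% expr[a$regulator, , drop = FALSE]) * v + basal[s]
      out[s, ] <- v - pred
    } else {
      Mvec <- if (s %in% rownames(data$methyl))
        methylation_effect(data$methyl[s, ]) else rep(1, ncol(expr))
      bil <- if (nrow(a)) startsWith(a$edge_class, "mirna") else logical(0)
      linpart <- if (any(!bil))
        as.vector(a$ability[!bil] %*% expr[a$regulator[!bil], , drop = FALSE]) else 0
      bilpart <- if (any(bil))
        as.vector(a$ability[bil] %*% expr[a$regulator[bil], , drop = FALSE]) * v else 0
      pred <- (linpart + bilpart + basal[s]) * Mvec
      out[s, ] <- v - pred
    }
  }
  out
}
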