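## Principal network projection (PNP): SVD of the identified ability
## matrix; nodes are scored by the norm of their row/column projections
## onto the top singular structure ("significant network linking energy").

#' Assemble the ability matrix of an identified network
#'
#' Square matrix over all network nodes (sorted symbols) with
#' `H[target, regulator]` = the final refit ability of the regulator on the
#' target, 0 where no edge survived.  Basal levels are excluded.  A
#' surviving undirected PPI edge is symmetrized: its estimate is placed at
#' both `(j, g)` and `(g, j)`; when both endpoints' equations include the
#' edge, the two estimates are averaged.
#'
#' @param idn an `identified_network`.
#' @return numeric matrix with dimnames (targets x regulators).
#' @export
assemble_ability_matrix <- function(idn) {
  stopifnot(inherits(idn, "identified_network"))
  syms <- sort(idn$pruned$nodes$symbol)
  H <- matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
  est <- idn$estimates
  e <- idn$pruned$edges
  for (k in seq_len(nrow(e))) {
    s <- e$source[k]; t <- e$target[k]
    if (e$edge_class[k] == "ppi") {
      a_st <- if (!is.null(est[[t]])) unname(est[[t]]$abilities[s]) else NA_real_
      a_ts <- if (!is.null(est[[s]])) unname(est[[s]]$abilities[t]) else NA_real_
      vals <- c(a_st, a_ts)
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      H[t, s] <- H[s, t] <- mean(vals)
    } else {
      a <- if (!is.null(est[[t]])) unname(est[[t]]$abilities[s]) else NA_real_
      if (!is.na(a)) H[t, s] <- a
    }
  }
  H
}

#' Projection values of the principal network structure
#'
#' SVD `H = U S V'`; the rank `r` is the smallest number of singular
#' components whose energy \eqn{\sum_{c \le r} s_c^2 / \sum_c s_c^2}
#' reaches `energy_threshold`.  Each node gets a target-side projection
#' value \eqn{D_L(k) = \sqrt{\sum_{c \le r} (s_c U_{kc})^2}} (its row
#' projected onto the top right-singular directions), a regulator-side
#' value \eqn{D_R(t) = \sqrt{\sum_{c \le r} (s_c V_{tc})^2}}, and a
#' combined score \eqn{\sqrt{D_L^2 + D_R^2}}.  With `energy_threshold = 1`
#' the squared projection values sum to the squared Frobenius norm of `H`
#' on each side.
#'
#' @param H ability matrix from [assemble_ability_matrix()].
#' @param energy_threshold fraction of linking energy to retain, in (0, 1].
#' @return object of class `projection_scores`: data.frame `node`, `D_L`,
#'   `D_R`, `combined`, with attributes `rank` and `energy_fraction`.
#' @export
project_network <- function(H, energy_threshold = 0.85) {
  stopifnot(is.matrix(H), energy_threshold > 0, energy_threshold <= 1)
  fn2 <- sum(H^2)
  if (fn2 == 0) stop("degenerate ability matrix: all entries are zero")
  sv <- svd(H)
  energy <- cumsum(sv$d^2) / sum(sv$d^2)
  r <- which(energy >= energy_threshold - 1e-12)[1L]
  idx <- seq_len(r)
  DL <- sqrt(rowSums((sv$u[, idx, drop = FALSE] %*%
                        diag(sv$d[idx], r, r))^2))
  DR <- sqrt(rowSums((sv$v[, idx, drop = FALSE] %*%
                        diag(sv$d[idx], r, r))^2))
  out <- data.frame(node = rownames(H), D_L = DL, D_R = DR,
                    combined = sqrt(DL^2 + DR^2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "rank") <- r
  attr(out, "energy_fraction") <- energy[r]
  class(out) <- c("projection_scores", "data.frame")
  out
}

#' Extract the core network of one stage
#'
#' Ranks non-TF proteins and TFs separately by their combined projection
#' value (descending, ties broken by symbol) and keeps the top `K_protein`
#' and `K_tf`; miRNAs and lncRNAs with at least one surviving edge to a
#' selected protein/TF (or the gene sharing its symbol) are attached;
#' core edges are the surviving edges among core nodes.
#'
#' @param idn an `identified_network`.
#' @param scores a `projection_scores` for the same network.
#' @param K_protein,K_tf selection sizes (genome-scale defaults 3000/300;
#'   synthetic runs use scaled-down values).
#' @return object of class `core_network`: list with `stage`, `nodes`
#'   (data.frame `symbol`, `kind`, `reason`, `combined`), `edges`,
#'   `scores`.
#' @export
extract_core <- function(idn, scores, K_protein = 3000L, K_tf = 300L) {
  stopifnot(inherits(idn, "identified_network"),
            K_protein >= 0, K_tf >= 0)
  nd <- idn$pruned$nodes
  sc <- stats::setNames(scores$combined, scores$node)
  pick_top <- function(kinds, K) {
    cand <- nd$symbol[nd$kind %in% kinds]
    cand <- cand[order(-sc[cand], cand)]
    utils::head(cand, K)
  }
  top_p <- pick_top("protein", K_protein)
  top_t <- pick_top("tf", K_tf)
  core <- c(top_p, top_t)
  reason <- c(rep("top_protein", length(top_p)), rep("top_tf", length(top_t)))

  ## attach miRNAs/lncRNAs with a surviving edge to a core protein/TF or to
  ## the gene encoded by one (same-symbol identity)
  e <- idn$pruned$edges
  anchors <- core    # gene symbols identical to protein symbols by mapping
  for (kd in c("mirna", "lncrna")) {
    ncs <- nd$symbol[nd$kind == kd]
    att <- ncs[vapply(ncs, function(s)
      any((e$source == s & e$target %in% anchors) |
            (e$target == s & e$source %in% anchors)), logical(1L))]
    att <- sort(att)
    core <- c(core, att)
    reason <- c(reason, rep(paste0("attached_", kd), length(att)))
  }
  keep <- e$source %in% core & e$target %in% core
  nodes <- data.frame(symbol = core,
                      kind = nd$kind[match(core, nd$symbol)],
                      reason = reason,
                      combined = unname(sc[core]),
                      stringsAsFactors = FALSE)
  structure(list(stage = idn$stage, nodes = nodes,
                 edges = e[keep, , drop = FALSE], scores = scores),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat("core GEN (", x$stage, "): ", nrow(x$nodes), " core nodes, ",
      nrow(x$edges), " core edges\n", sep = "")
  invisible(x)
}
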