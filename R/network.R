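#' @keywords internal
"_PACKAGE"

## Node kinds and edge classes of a genetic and epigenetic network (GEN).
## A "tf" is a protein that acts as a transcription factor; a gene and the
## protein it encodes share one symbol (identity mapping).

NODE_KINDS <- c("protein", "tf", "gene", "mirna", "lncrna")

EDGE_CLASSES <- c("ppi", "tf_gene", "tf_mirna", "tf_lncrna",
                  "mirna_gene", "mirna_mirna", "mirna_lncrna", "lncrna_gene")

## allowed (source, target) kinds per edge class; "proteinish" = protein or tf
.edge_kind_rules <- list(
  ppi          = list(source = c("protein", "tf"), target = c("protein", "tf")),
  tf_gene      = list(source = "tf",     target = "gene"),
  tf_mirna     = list(source = "tf",     target = "mirna"),
  tf_lncrna    = list(source = "tf",     target = "lncrna"),
  mirna_gene   = list(source = "mirna",  target = "gene"),
  mirna_mirna  = list(source = "mirna",  target = "mirna"),
  mirna_lncrna = list(source = "mirna",  target = "lncrna"),
  lncrna_gene  = list(source = "lncrna", target = "gene")
)

.sign_for_class <- function(edge_class) {
  ifelse(grepl("^mirna_", edge_class), "nonpositive", "free")
}

.edge_key <- function(edges) {
  paste(edges$source, edges$target, edges$edge_class, sep = "\r")
}

#' Construct a candidate GEN
#'
#' A candidate network is the union of database-derived possible
#' interactions and regulations: undirected protein-protein interaction
#' (PPI) pairs plus directed TF/miRNA/lncRNA regulations.  It typically
#' contains false positives that system identification later prunes.
#'
#' Edges are canonicalized: PPI pairs are stored with `source <= target`
#' lexicographically, duplicates are merged, and every miRNA-sourced edge
#' carries a `nonpositive` sign constraint (miRNA regulation is repressive,
#' so its regression coefficient is constrained to be <= 0).
#'
#' @param nodes data.frame with columns `symbol`, `kind`
#'   (kind in `protein`, `tf`, `gene`, `mirna`, `lncrna`).
#' @param edges data.frame with columns `source`, `target`, `edge_class`.
#' @return An object of class `candidate_network`: a list with canonical
#'   `nodes` and `edges` data.frames (edges gain a `sign_constraint` column).
#' @export
candidate_network <- function(nodes, edges) {
  nodes <- data.frame(symbol = as.character(nodes$symbol),
                      kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  if (anyNA(nodes$symbol) || any(!nzchar(nodes$symbol)))
    stop("node symbols must be nonempty")
  bad <- setdiff(nodes$kind, NODE_KINDS)
  if (length(bad))
    stop("unknown node kind(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(nodes$symbol)) {
    conf <- unique(nodes)
    if (anyDuplicated(conf$symbol))
      stop("conflicting kinds for symbol(s): ",
           paste(unique(conf$symbol[duplicated(conf$symbol)]), collapse = ", "))
    nodes <- conf
  }
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      edge_class = as.character(edges$edge_class),
                      stringsAsFactors = FALSE)
  bad <- setdiff(edges$edge_class, EDGE_CLASSES)
  if (length(bad))
    stop("unknown edge class(es): ", paste(bad, collapse = ", "))
  ## canonicalize undirected PPI pairs
  is_ppi <- edges$edge_class == "ppi"
  flip <- is_ppi & edges$source > edges$target
  if (any(flip)) {
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
  }
  if (any(is_ppi & edges$source == edges$target))
    stop("self PPI edges are not allowed")
  edges <- edges[!duplicated(.edge_key(edges)), , drop = FALSE]

  kind <- stats::setNames(nodes$kind, nodes$symbol)
  miss <- setdiff(unique(c(edges$source, edges$target)), nodes$symbol)
  if (length(miss))
    stop("edge endpoint(s) missing from node table: ",
         paste(miss, collapse = ", "))
  for (cls in unique(edges$edge_class)) {
    rule <- .edge_kind_rules[[cls]]
    sel <- edges$edge_class == cls
    oks <- kind[edges$source[sel]] %in% rule$source
    okt <- kind[edges$target[sel]] %in% rule$target
    if (!all(oks & okt)) {
      i <- which(sel)[which(!(oks & okt))[1L]]
      stop(sprintf("edge %s -> %s is inconsistent with class '%s' (kinds %s, %s)",
                   edges$source[i], edges$target[i], cls,
                   kind[edges$source[i]], kind[edges$target[i]]))
    }
  }
  edges$sign_constraint <- .sign_for_class(edges$edge_class)
  edges <- edges[order(edges$edge_class, edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges), class = "candidate_network")
}

#' @export
print.candidate_network <- function(x, ...) {
  cat("candidate GEN:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  kinds:", paste(names(table(x$nodes$kind)),
                        table(x$nodes$kind), collapse = ", "), "\n")
  cat("  classes:", paste(names(table(x$edges$edge_class)),
                          table(x$edges$edge_class), collapse = ", "), "\n")
  invisible(x)
}

#' Merge candidate networks
#'
#' Union of nodes and edges of several single-class (or mixed) candidate
#' networks, deduplicated.  A symbol listed as `protein` in one part and
#' `tf` in another is resolved to `tf` (TFs are proteins flagged by a TF
#' list); any other kind conflict is an error.
#'
#' @param parts list of `candidate_network` objects.
#' @return a `candidate_network`.
#' @export
merge_networks <- function(parts) {
  stopifnot(length(parts) >= 1L)
  nodes <- do.call(rbind, lapply(parts, function(p) p$nodes))
  ## tf supersedes protein for the same symbol
  tf_syms <- unique(nodes$symbol[nodes$kind == "tf"])
  nodes$kind[nodes$symbol %in% tf_syms & nodes$kind == "protein"] <- "tf"
  nodes <- unique(nodes)
  if (anyDuplicated(nodes$symbol))
    stop("conflicting kinds for symbol(s): ",
         paste(unique(nodes$symbol[duplicated(nodes$symbol)]), collapse = ", "))
  edges <- do.call(rbind, lapply(parts, function(p)
    p$edges[, c("source", "target", "edge_class")]))
  candidate_network(nodes, edges)
}

#' Regulators of one target node in a candidate network
#'
#' Directed edges pointing at `target`, plus (for proteins) both ends of any
#' undirected PPI edge touching it.
#'
#' @param net a `candidate_network`.
#' @param target node symbol.
#' @return data.frame with columns `regulator`, `edge_class`,
#'   `sign_constraint`, sorted by regulator symbol.
#' @export
regulators_of <- function(net, target) {
  e <- net$edges
  direct <- e[e$edge_class != "ppi" & e$target == target, , drop = FALSE]
  reg <- data.frame(regulator = direct$source,
                    edge_class = direct$edge_class,
                    sign_constraint = direct$sign_constraint,
                    stringsAsFactors = FALSE)
  ppi <- e[e$edge_class == "ppi" &
             (e$source == target | e$target == target), , drop = FALSE]
  if (nrow(ppi)) {
    partner <- ifelse(ppi$source == target, ppi$target, ppi$source)
    reg <- rbind(reg, data.frame(regulator = partner, edge_class = "ppi",
                                 sign_constraint = "free",
                                 stringsAsFactors = FALSE))
  }
  reg <- unique(reg)
  reg <- reg[order(reg$regulator), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}
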