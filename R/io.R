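## Readers/writers for the tab-separated dialect used throughout:
## UTF-8, tab-separated, '#'-prefixed comment lines ignored.

.read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a single-class edge list
#'
#' Reads a tab-separated file with header `source<TAB>target` (an optional
#' third weight column is ignored) into a canonical `candidate_network`.
#' Node kinds are inferred from the edge class; a node-kind table may be
#' supplied to cross-check them.
#'
#' @param path file path.
#' @param edge_class one of `ppi`, `tf_gene`, `tf_mirna`, `tf_lncrna`,
#'   `mirna_gene`, `mirna_mirna`, `mirna_lncrna`, `lncrna_gene`.
#' @param node_kinds optional data.frame (`symbol`, `kind`) used to validate
#'   that endpoints have the kinds the edge class requires.
#' @return a `candidate_network` with this one edge class.
#' @export
read_edge_list <- function(path, edge_class, node_kinds = NULL) {
  edge_class <- match.arg(edge_class, EDGE_CLASSES)
  tl <- .read_tsv_lines(path)
  if (!length(tl$lines)) stop("empty edge list: ", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L || header[1L] != "source" || header[2L] != "target")
    stop("edge list must have header 'source<TAB>target': ", path)
  fields <- fields[-1L]
  lineno <- tl$lineno[-1L]
  nfld <- lengths(fields)
  if (any(nfld < 2L))
    stop(sprintf("malformed edge line %d in %s (need at least 2 tab-separated fields)",
                 lineno[which(nfld < 2L)[1L]], path))
  src <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  if (any(!nzchar(src) | !nzchar(tgt)))
    stop(sprintf("malformed edge line %d in %s (empty symbol)",
                 lineno[which(!nzchar(src) | !nzchar(tgt))[1L]], path))
  rule <- .edge_kind_rules[[edge_class]]
  if (!is.null(node_kinds)) {
    kind <- stats::setNames(as.character(node_kinds$kind),
                            as.character(node_kinds$symbol))
    bad_s <- !is.na(kind[src]) & !(kind[src] %in% rule$source)
    bad_t <- !is.na(kind[tgt]) & !(kind[tgt] %in% rule$target)
    if (any(bad_s | bad_t)) {
      i <- which(bad_s | bad_t)[1L]
      stop(sprintf("line %d in %s: edge %s -> %s violates class '%s' under the supplied node-kind table",
                   lineno[i], path, src[i], tgt[i], edge_class))
    }
    infer <- kind
  } else infer <- character(0)
  sym <- unique(c(src, tgt))
  ## infer: a node seen as source gets the source kind, otherwise the target
  ## kind; for ppi both sides are proteins
  kinds <- ifelse(sym %in% src, rule$source[1L], rule$target[1L])
  if (length(infer)) {
    known <- infer[sym]
    kinds[!is.na(known)] <- known[!is.na(known)]
  }
  candidate_network(nodes = data.frame(symbol = sym, kind = kinds),
                    edges = data.frame(source = src, target = tgt,
                                       edge_class = edge_class))
}

#' Read a node-kind table
#'
#' TSV with header `symbol<TAB>kind`.
#'
#' @param path file path.
#' @return data.frame with columns `symbol`, `kind`.
#' @export
read_node_kinds <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("symbol", "kind") %in% names(df)))
    stop("node-kind table must have columns 'symbol' and 'kind': ", path)
  bad <- setdiff(df$kind, NODE_KINDS)
  if (length(bad)) stop("unknown node kind(s): ", paste(bad, collapse = ", "))
  df[, c("symbol", "kind")]
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated row ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))
    nonnum <- is.na(m2) & !(df[, -1L, drop = FALSE] %in% c("NA", ""))
    if (any(nonnum)) stop("non-numeric entries in matrix ", path)
    m <- m2
  }
  rownames(m) <- ids
  m
}

#' Assemble a stage dataset
#'
#' Binds an expression matrix (all node kinds, rows = nodes, columns =
#' samples) and a methylation beta-value matrix (rows = genes) for the
#' samples of one disease stage.  Sample columns must match; methylation
#' entries must lie in [0, 1] (NA allowed and later treated as unmethylated,
#' i.e. no attenuation).
#'
#' @param stage_label one of `normal`, `early`, `middle`, `advanced`.
#' @param expr numeric matrix, rows = node symbols, columns = sample ids.
#' @param methyl numeric matrix, rows = gene symbols, columns = sample ids;
#'   may have zero rows.
#' @return object of class `stage_dataset`.
#' @export
stage_dataset <- function(stage_label, expr, methyl = NULL) {
  stage_label <- match.arg(stage_label, STAGES)
  stopifnot(is.matrix(expr), is.numeric(expr), ncol(expr) >= 1L)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs row (node) and column (sample) names")
  if (is.null(methyl))
    methyl <- matrix(numeric(0), nrow = 0, ncol = ncol(expr),
                     dimnames = list(NULL, colnames(expr)))
  if (!identical(colnames(expr), colnames(methyl)))
    stop("expression and methylation sample ids do not align")
  if (nrow(methyl)) {
    v <- methyl[!is.na(methyl)]
    if (any(v < 0 | v > 1))
      stop("methylation beta values must lie in [0, 1]")
    if (!all(rownames(methyl) %in% rownames(expr)))
      stop("methylation rows must be a subset of expression rows")
  }
  structure(list(stage = stage_label, expr = expr, methyl = methyl),
            class = "stage_dataset")
}

#' @export
print.stage_dataset <- function(x, ...) {
  cat("stage_dataset:", x$stage, "-", nrow(x$expr), "nodes x",
      ncol(x$expr), "samples;", nrow(x$methyl), "methylation rows\n")
  invisible(x)
}

#' Read a stage dataset from TSV matrices
#'
#' @param expr_path TSV matrix, first column node ids, header = sample ids.
#' @param methyl_path TSV matrix of methylation beta values, or NULL.
#' @param stage_label stage name.
#' @return a `stage_dataset`.
#' @export
read_stage_dataset <- function(expr_path, methyl_path, stage_label) {
  expr <- .read_matrix_tsv(expr_path)
  methyl <- if (is.null(methyl_path)) NULL else .read_matrix_tsv(methyl_path)
  stage_dataset(stage_label, expr, methyl)
}

#' Write an expression or methylation matrix as TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the id column in the header.
#' @export
write_matrix_tsv <- function(m, path, id_col = "symbol") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge table (and optional node table)
#'
#' Edges go to `path` as TSV `source, target, edge_class[, ability]`; if
#' `node_table` is given (e.g. basal levels and residual variances) it is
#' written alongside.  Numeric columns are serialized at 12 significant
#' digits so a write/read round trip preserves abilities to ~1e-9.
#'
#' @param edges data.frame of edges (any numeric columns kept).
#' @param path output TSV path.
#' @param node_table optional data.frame written to `node_path`.
#' @param node_path path for the companion node table.
#' @export
write_network_table <- function(edges, path, node_table = NULL,
                                node_path = NULL) {
  .write_df(edges, path)
  if (!is.null(node_table)) {
    if (is.null(node_path))
      node_path <- sub("(\\.tsv)?$", ".nodes.tsv", path)
    .write_df(node_table, node_path)
  }
  invisible(path)
}

.write_df <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a network edge table written by [write_network_table()]
#' @param path TSV path.
#' @return data.frame of edges.
#' @export
read_network_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    encoding = "UTF-8")
}

STAGES <- c("normal", "early", "middle", "advanced")
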