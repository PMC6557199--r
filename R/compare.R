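## Stage-to-stage comparison: edge turnover, basal-level shift flags
## (DNA methylation on genes, post-translational modification on
## proteins), one-way-ANOVA differential expression, and the epigenetic
## enzyme eligibility rule.

#' Classify edges between two consecutive stages' core networks
#'
#' @param core_former,core_later `core_network` objects (or anything with
#'   an `edges` data.frame).
#' @return data.frame `source`, `target`, `edge_class`, `status` with
#'   status in `former_only`, `later_only`, `common` (an exact partition
#'   of the edge union).
#' @export
diff_edges <- function(core_former, core_later) {
  ef <- core_former$edges[, c("source", "target", "edge_class")]
  el <- core_later$edges[, c("source", "target", "edge_class")]
  kf <- .edge_key(ef); kl <- .edge_key(el)
  all_e <- rbind(ef, el)
  all_e <- all_e[!duplicated(.edge_key(all_e)), , drop = FALSE]
  k <- .edge_key(all_e)
  all_e$status <- ifelse(k %in% kf & k %in% kl, "common",
                         ifelse(k %in% kf, "former_only", "later_only"))
  rownames(all_e) <- NULL
  all_e
}

#' Flag basal-level shifts between two stages
#'
#' A gene whose estimated basal level changes by more than `theta_gene`
#' between consecutive stages is flagged as affected by DNA methylation;
#' a protein whose basal level changes by more than `theta_protein` is
#' flagged as affected by post-translational (epigenetic) modification.
#' Comparisons are strict (`|delta| > theta`).  When a threshold is `NULL`
#' it defaults to the `quantile`-level of the `|delta|` distribution over
#' the nodes of that kind for this stage pair (adaptive, scale-free).
#'
#' When the stage datasets and the candidate network are supplied, each
#' node's equation is refit in both stages on the \emph{union} of the two
#' stages' surviving regulator sets, so the two basal estimates come from
#' the same model structure and their difference is not confounded by
#' support changes.  Without data, the basal levels of the final per-stage
#' fits are compared directly.
#'
#' @param idn_former,idn_later `identified_network` objects.
#' @param theta_gene,theta_protein absolute thresholds, or `NULL` for the
#'   quantile default.
#' @param quantile quantile level for the adaptive threshold.
#' @param cand the candidate network (optional, for common-support refits).
#' @param data_former,data_later the two stages' `stage_dataset`s
#'   (optional, for common-support refits).
#' @return list with `methyl_flags`, `ptm_flags` (character vectors),
#'   `deltas` (data.frame `symbol`, `kind`, `delta`), `theta_gene`,
#'   `theta_protein`.
#' @export
flag_basal_shifts <- function(idn_former, idn_later,
                              theta_gene = NULL, theta_protein = NULL,
                              quantile = 0.9,
                              cand = NULL, data_former = NULL,
                              data_later = NULL) {
  if (!is.null(cand) && !is.null(data_former) && !is.null(data_later)) {
    bf <- .common_support_basal(idn_former, idn_later, cand, data_former)
    bl <- .common_support_basal(idn_former, idn_later, cand, data_later)
  } else {
    bf <- basal_table(idn_former)
    bl <- basal_table(idn_later)
  }
  shared <- merge(bf[, c("symbol", "kind", "basal")],
                  bl[, c("symbol", "basal")],
                  by = "symbol", suffixes = c("_former", "_later"))
  shared$delta <- shared$basal_later - shared$basal_former
  is_gene <- shared$kind == "gene"
  is_prot <- shared$kind %in% c("protein", "tf")
  if (is.null(theta_gene))
    theta_gene <- stats::quantile(abs(shared$delta[is_gene]), quantile,
                                  names = FALSE)
  if (is.null(theta_protein))
    theta_protein <- stats::quantile(abs(shared$delta[is_prot]), quantile,
                                     names = FALSE)
  list(methyl_flags = shared$symbol[is_gene & abs(shared$delta) > theta_gene],
       ptm_flags = shared$symbol[is_prot & abs(shared$delta) > theta_protein],
       deltas = shared[, c("symbol", "kind", "delta")],
       theta_gene = theta_gene, theta_protein = theta_protein)
}

## refit every shared node on the union of both stages' surviving
## regulators and return its basal level in `data`
.common_support_basal <- function(idn_former, idn_later, cand, data) {
  shared <- intersect(names(idn_former$estimates), names(idn_later$estimates))
  kinds <- stats::setNames(cand$nodes$kind, cand$nodes$symbol)
  rows <- lapply(shared, function(s) {
    S <- union(idn_former$estimates[[s]]$included,
               idn_later$estimates[[s]]$included)
    sys <- build_system(s, cand, data)
    idx <- c(match(S, sys$column_meta$regulator), ncol(sys$design))
    fit <- fit_constrained_lsq(sys$design[, idx, drop = FALSE], sys$response,
                               sys$column_meta$sign_constraint[idx] == "nonpositive")
    data.frame(symbol = s, kind = unname(kinds[s]),
               basal = unname(fit$coefficients[length(idx)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## closed-form two-group one-way ANOVA (F on 1 and n1+n2-2 df; F = t^2)
.anova_two_group <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((x1 - m1)^2) + sum((x2 - m2)^2)
  df2 <- n1 + n2 - 2L
  if (ssw == 0) {
    p <- if (ssb == 0) 1 else 0
  } else {
    p <- stats::pf((ssb / 1) / (ssw / df2), 1, df2, lower.tail = FALSE)
  }
  c(p = p, mean_former = m1, mean_later = m2)
}

#' Differential expression between two stages by one-way ANOVA
#'
#' Per shared node, a two-group one-way ANOVA (equivalent to the pooled
#' two-sample t-test, F = t^2) on the former- vs later-stage expression;
#' direction is `higher_in_later` / `lower_in_later` when p < `alpha`,
#' else `ns`.  Raw p-values are reported by default; set `adjust = "BH"`
#' for Benjamini-Hochberg correction.
#'
#' @param data_former,data_later `stage_dataset` objects with a shared node
#'   universe (each group needs N >= 2).
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `symbol`, `p_value`, `mean_former`, `mean_later`,
#'   `direction`.
#' @export
anova_annotate <- function(data_former, data_later, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(ncol(data_former$expr) >= 2L, ncol(data_later$expr) >= 2L)
  shared <- intersect(rownames(data_former$expr), rownames(data_later$expr))
  res <- t(vapply(shared, function(s)
    .anova_two_group(data_former$expr[s, ], data_later$expr[s, ]),
    numeric(3L)))
  p <- res[, "p"]
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  direction <- ifelse(p >= alpha, "ns",
                      ifelse(res[, "mean_later"] > res[, "mean_former"],
                             "higher_in_later", "lower_in_later"))
  data.frame(symbol = shared, p_value = unname(p),
             mean_former = unname(res[, "mean_former"]),
             mean_later = unname(res[, "mean_later"]),
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Epigenetic-enzyme eligibility across the four stages
#'
#' An epigenetic enzyme (ubiquitinase, deubiquitinase, acetylase,
#' deacetylase) is not considered responsible for a modification at a
#' stage where its mean expression is the lowest of the four stages; ties
#' at the minimum make all tied stages ineligible.
#'
#' @param expr_by_stage named list of 4 expression matrices (one per
#'   stage, in `normal`, `early`, `middle`, `advanced` order).
#' @param enzyme_table data.frame `symbol`, `modification_class`
#'   (`ubiquitination`, `deubiquitination`, `acetylation`,
#'   `deacetylation`).
#' @return data.frame `symbol`, `modification_class`, one logical column
#'   per stage (`eligible_<stage>`); enzymes without expression are
#'   skipped with a warning.
#' @export
enzyme_eligibility <- function(expr_by_stage, enzyme_table) {
  stopifnot(length(expr_by_stage) == 4L)
  if (is.null(names(expr_by_stage))) names(expr_by_stage) <- STAGES
  mats <- lapply(expr_by_stage, function(x)
    if (inherits(x, "stage_dataset")) x$expr else x)
  rows <- lapply(seq_len(nrow(enzyme_table)), function(i) {
    s <- enzyme_table$symbol[i]
    if (!all(vapply(mats, function(m) s %in% rownames(m), logical(1L)))) {
      warning("enzyme ", s, " missing from expression; skipped")
      return(NULL)
    }
    means <- vapply(mats, function(m) mean(m[s, ]), numeric(1L))
    elig <- means > min(means)        # ties at the minimum: ineligible
    out <- data.frame(symbol = s,
                      modification_class = enzyme_table$modification_class[i],
                      stringsAsFactors = FALSE)
    out[paste0("eligible_", STAGES)] <- as.list(unname(elig))
    out
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
}

#' Full comparison of two consecutive stages
#'
#' Bundles [diff_edges()], [flag_basal_shifts()] and [anova_annotate()]
#' into one stage-delta object.
#'
#' @param core_former,core_later `core_network` objects.
#' @param idn_former,idn_later `identified_network` objects.
#' @param data_former,data_later `stage_dataset` objects.
#' @param alpha ANOVA significance level.
#' @param quantile adaptive basal-shift threshold level.
#' @return object of class `stage_delta`.
#' @export
compare_stages <- function(core_former, core_later, idn_former, idn_later,
                           data_former, data_later,
                           alpha = 0.05, quantile = 0.9, cand = NULL) {
  structure(list(pair = c(core_former$stage, core_later$stage),
                 edge_status = diff_edges(core_former, core_later),
                 basal = flag_basal_shifts(idn_former, idn_later,
                                           quantile = quantile, cand = cand,
                                           data_former = data_former,
                                           data_later = data_later),
                 de_table = anova_annotate(data_former, data_later, alpha)),
            class = "stage_delta")
}

#' @export
print.stage_delta <- function(x, ...) {
  st <- table(x$edge_status$status)
  cat("stage delta ", x$pair[1L], " -> ", x$pair[2L], ": ",
      paste(names(st), st, collapse = ", "), "\n", sep = "")
  cat("  methylation flags:", length(x$basal$methyl_flags),
      "| PTM flags:", length(x$basal$ptm_flags),
      "| DE nodes:", sum(x$de_table$direction != "ns"), "\n")
  invisible(x)
}
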