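## Signature-reversal drug scoring against a drug-gene correlation matrix
## (CMap-style: C[g, d] = correlation between gene g's expression and the
## concentration of compound d; positive = the compound up-regulates g).

#' Specify a restoration signature
#'
#' @param up_targets genes to activate (lower in disease than normal).
#' @param down_targets genes to repress (higher in disease than normal).
#' @param housekeeping genes whose expression must not be perturbed.
#' @param weight_hk nonnegative weight of the housekeeping penalty.
#' @return list of class `signature_spec`.
#' @export
signature_spec <- function(up_targets, down_targets,
                           housekeeping = character(0), weight_hk = 1) {
  up_targets <- unique(as.character(up_targets))
  down_targets <- unique(as.character(down_targets))
  housekeeping <- unique(as.character(housekeeping))
  if (length(intersect(up_targets, down_targets)) ||
      length(intersect(up_targets, housekeeping)) ||
      length(intersect(down_targets, housekeeping)))
    stop("up/down/housekeeping gene sets must be pairwise disjoint")
  stopifnot(weight_hk >= 0)
  structure(list(up_targets = up_targets, down_targets = down_targets,
                 housekeeping = housekeeping, weight_hk = weight_hk),
            class = "signature_spec")
}

#' Rank compounds by signature reversal
#'
#' Scores each compound d as
#' \deqn{score(d) = mean_{g \in up} C_{gd} - mean_{g \in down} C_{gd}
#'   - w_{hk} \cdot mean_{g \in hk} |C_{gd}|,}
#' i.e. it should up-regulate the activation targets, down-regulate the
#' repression targets and leave housekeeping genes untouched.  The score
#' is linear in every correlation entry and bounded in
#' `[-2 - weight_hk, 2]`.
#'
#' @param C numeric gene x drug matrix of correlations in [-1, 1], with
#'   dimnames.
#' @param spec a [signature_spec()]; genes absent from `C` are dropped
#'   with a warning.
#' @return data.frame of class `drug_ranking`: `drug`, `score`,
#'   `up_score`, `down_score`, `hk_penalty`, sorted by score descending
#'   (ties by drug id).
#' @export
score_drugs <- function(C, spec) {
  stopifnot(is.matrix(C), !is.null(rownames(C)), !is.null(colnames(C)))
  if (any(abs(C) > 1 + 1e-9)) stop("correlations must lie in [-1, 1]")
  use <- function(genes, what) {
    miss <- setdiff(genes, rownames(C))
    if (length(miss))
      warning("dropping ", length(miss), " ", what,
              " gene(s) absent from the correlation matrix")
    intersect(genes, rownames(C))
  }
  up <- use(spec$up_targets, "up")
  dn <- use(spec$down_targets, "down")
  hk <- use(spec$housekeeping, "housekeeping")
  if (!length(up) && !length(dn))
    stop("signature has no up or down targets present in the matrix")
  colmean <- function(genes, f = identity)
    if (length(genes)) colMeans(f(C[genes, , drop = FALSE])) else
      stats::setNames(numeric(ncol(C)), colnames(C))
  up_s <- colmean(up)
  dn_s <- colmean(dn)
  hk_p <- colmean(hk, abs)
  score <- up_s - dn_s - spec$weight_hk * hk_p
  out <- data.frame(drug = colnames(C), score = unname(score),
                    up_score = unname(up_s), down_score = unname(dn_s),
                    hk_penalty = unname(hk_p),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drug_ranking", "data.frame")
  out
}

#' Greedy selection of a multi-compound combination
#'
#' Iteratively adds the highest-scoring compound that covers at least one
#' currently-uncovered target (a target is covered when the compound moves
#' it in the correct direction with `|C| >= effect_cutoff`), until
#' `k_drugs` compounds are chosen or all targets are covered.
#'
#' @param ranking a `drug_ranking` from [score_drugs()].
#' @param C the correlation matrix used for the ranking.
#' @param spec the [signature_spec()].
#' @param k_drugs maximum number of compounds (the study design uses 3).
#' @param effect_cutoff minimum correlation magnitude to count as covering
#'   a target.
#' @return character vector of selected drug ids (in selection order).
#' @export
select_combination <- function(ranking, C, spec, k_drugs = 3L,
                               effect_cutoff = 0.3) {
  stopifnot(k_drugs >= 1L)
  up <- intersect(spec$up_targets, rownames(C))
  dn <- intersect(spec$down_targets, rownames(C))
  uncovered <- c(paste0("up:", up), paste0("down:", dn))
  covers <- function(drug) {
    cu <- up[C[up, drug] >= effect_cutoff]
    cd <- dn[C[dn, drug] <= -effect_cutoff]
    c(paste0("up:", cu), paste0("down:", cd))
  }
  chosen <- character(0)
  for (d in ranking$drug) {
    if (length(chosen) >= k_drugs || !length(uncovered)) break
    new_cov <- intersect(covers(d), uncovered)
    if (length(new_cov)) {
      chosen <- c(chosen, d)
      uncovered <- setdiff(uncovered, new_cov)
    }
  }
  chosen
}

#' Read a gene x drug correlation matrix from TSV
#' @param path TSV path (first column gene ids, header drug ids).
#' @return numeric matrix.
#' @export
read_correlations <- function(path) {
  m <- .read_matrix_tsv(path)
  if (any(abs(m) > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]: ", path)
  m
}

#' Simulate a drug-gene correlation matrix with a planted restorer
#'
#' Demonstration input for the pipeline's drug-scoring step: random
#' correlations for `n_drugs - 1` compounds plus one planted
#' perfect-restorer compound (+1 on the up targets, -1 on the down
#' targets, 0 elsewhere).
#'
#' @param genes gene symbols (matrix rows).
#' @param spec a [signature_spec()].
#' @param n_drugs number of compounds.
#' @param seed integer seed.
#' @return numeric gene x drug matrix.
#' @export
simulate_correlations <- function(genes, spec, n_drugs = 30L, seed = 1L) {
  set.seed(seed)
  C <- matrix(stats::runif(length(genes) * (n_drugs - 1L), -1, 1),
              length(genes), n_drugs - 1L,
              dimnames = list(genes, sprintf("drug%02d", seq_len(n_drugs - 1L))))
  restorer <- stats::setNames(numeric(length(genes)), genes)
  restorer[intersect(spec$up_targets, genes)] <- 1
  restorer[intersect(spec$down_targets, genes)] <- -1
  cbind(C, restorer = restorer)
}
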