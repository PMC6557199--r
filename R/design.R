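#' DNA-methylation attenuation of binding affinity
#'
#' The methylation regulation of a target is
#' \deqn{M(m) = \frac{1}{1 + (m / 0.5)^2},}
#' where `m` is the methylation beta value in [0, 1].  The higher the
#' methylation level, the weaker the binding affinity of TFs, miRNAs,
#' lncRNAs and RNA polymerase on the target: `M` decreases strictly from 1
#' (unmethylated) to 0.2 (fully methylated), so even a fully methylated
#' gene retains a residual regulation value of 0.2.
#'
#' @param m numeric vector of methylation beta values in [0, 1]; `NA` is
#'   treated as "no methylation evidence" and mapped to `M = 1`.
#' @return numeric vector of attenuation factors in [0.2, 1].
#' @examples
#' methylation_effect(c(0, 0.5, 1))  # 1.0 0.5 0.2
#' @export
methylation_effect <- function(m) {
  mm <- m[!is.na(m)]
  if (length(mm) && (any(mm < 0) || any(mm > 1)))
    stop("methylation values must lie in [0, 1]")
  out <- 1 / (1 + (m / 0.5)^2)
  out[is.na(m)] <- 1
  out
}

#' Build the per-node regression system
#'
#' Translates a target node's interactive/regulatory model into one
#' linear-in-parameters regression:
#' \itemize{
#'   \item protein target j (PPI model):
#'     \eqn{y_j[n] = \sum_g \alpha_{jg} y_g[n] y_j[n] + b_j + v_j[n]};
#'     regressor columns are `y_g * y_j`, the basal column is all ones, no
#'     methylation factor.
#'   \item gene target i:
#'     \eqn{x_i = \sum_j \beta_{ij} y_j M_i + \sum_q \tau_{iq} l_q M_i
#'       - \sum_p \delta_{ip} x_i r_p M_i + k_i M_i + \varepsilon_i};
#'     TF and lncRNA columns are `regulator * M`, miRNA columns are the
#'     bilinear product `x_i * r_p * M` with coefficient constrained
#'     nonpositive (so the estimate is \eqn{-\delta \le 0}), the basal
#'     column is `M`.
#'   \item miRNA target p: TF columns `y_j * M_p`, miRNA columns
#'     `r_p * r_z * M_p` (nonpositive), basal `M_p`.
#'   \item lncRNA target q: TF columns `y_j * M_q`, miRNA columns
#'     `l_q * r_p * M_q` (nonpositive), basal `M_q`.
#' }
#' `M` is [methylation_effect()] of the target's methylation row; targets
#' without a methylation row (typically miRNAs/lncRNAs not covered by the
#' array) use `M = 1`.  Columns are ordered by regulator symbol with the
#' basal column last.
#'
#' @param target node symbol.
#' @param cand a `candidate_network` (provides regulators and node kinds).
#' @param data a `stage_dataset`.
#' @return object of class `regression_system`: list with `target`,
#'   `model_kind`, `response` (length-N vector), `design` (N x (p+1)
#'   matrix), `column_meta` (data.frame `regulator`, `edge_class`,
#'   `sign_constraint`; the basal row has regulator `"BASAL"`).
#' @export
build_system <- function(target, cand, data) {
  stopifnot(inherits(cand, "candidate_network"),
            inherits(data, "stage_dataset"))
  expr <- data$expr
  if (!target %in% rownames(expr))
    stop("target '", target, "' has no expression row")
  kind <- cand$nodes$kind[match(target, cand$nodes$symbol)]
  if (is.na(kind)) stop("target '", target, "' is not in the network")
  model_kind <- switch(kind, protein = "protein", tf = "protein",
                       gene = "gene", mirna = "mirna", lncrna = "lncrna")
  N <- ncol(expr)
  if (N == 0L) stop("no samples in expression matrix")
  reg <- regulators_of(cand, target)
  miss <- setdiff(reg$regulator, rownames(expr))
  if (length(miss))
    stop("regulator(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))

  y_t <- expr[target, ]
  if (model_kind == "protein") {
    Mvec <- rep(1, N)
    basal_col <- rep(1, N)
  } else {
    mrow <- if (target %in% rownames(data$methyl)) data$methyl[target, ] else rep(NA_real_, N)
    mrow[is.na(mrow)] <- 0            # absent evidence: no attenuation
    Mvec <- methylation_effect(mrow)
    basal_col <- Mvec
  }

  cols <- lapply(seq_len(nrow(reg)), function(k) {
    r <- expr[reg$regulator[k], ]
    switch(reg$edge_class[k],
           ppi          = r * y_t,
           tf_gene      = ,
           tf_mirna     = ,
           tf_lncrna    = ,
           lncrna_gene  = r * Mvec,
           mirna_gene   = ,
           mirna_mirna  = ,
           mirna_lncrna = y_t * r * Mvec,
           stop("unhandled edge class ", reg$edge_class[k]))
  })
  design <- do.call(cbind, c(cols, list(basal_col)))
  colnames(design) <- c(reg$regulator, "BASAL")
  meta <- rbind(reg,
                data.frame(regulator = "BASAL", edge_class = "basal",
                           sign_constraint = "free", stringsAsFactors = FALSE))
  rownames(meta) <- NULL

  ## bilinear columns contain the target's own expression as a factor
  ## (y_g * y_j for PPIs; x * r * M for miRNA repression); keep the factor
  ## that multiplies the target so order detection can check that the
  ## implied implicit-equation denominator 1 - sum(theta * factor) stays
  ## away from 0 (model stability)
  bilinear <- c(reg$edge_class == "ppi" |
                  startsWith(reg$edge_class, "mirna"), FALSE)
  factors <- NULL
  if (any(bilinear)) {
    fcols <- lapply(which(bilinear), function(k) {
      r <- expr[reg$regulator[k], ]
      if (reg$edge_class[k] == "ppi") r else r * Mvec
    })
    factors <- do.call(cbind, fcols)
    colnames(factors) <- reg$regulator[bilinear[seq_len(nrow(reg))]]
  }
  structure(list(target = target, model_kind = model_kind,
                 response = y_t, design = design, column_meta = meta,
                 bilinear = bilinear, factors = factors),
            class = "regression_system")
}
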