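## Sign-constrained least squares.
##
## The estimation problem is min ||y - X theta||^2 subject to theta_c <= 0
## for every column c flagged `nonpositive` (miRNA repression).  The solver
## is an active-set method in the Lawson-Hanson family: constrained columns
## start at their bound (0); the most violated KKT multiplier is freed one
## at a time, with backtracking steps that return variables to the bound
## when an inner solution leaves the feasible region.  Free columns are
## permanently in the passive set.  The problem is convex, so the method
## terminates at the global minimizer.

.ls_solve <- function(X, y, ridge = FALSE) {
  p <- ncol(X)
  if (p == 0L) return(numeric(0))
  qrX <- qr(X)
  if (!ridge && qrX$rank == p) {
    co <- qr.coef(qrX, y)
    co[is.na(co)] <- 0
    return(co)
  }
  ## ridge fallback for rank deficiency: penalty 1e-8 * trace(X'X)/p
  lam <- 1e-8 * sum(X * X) / p
  if (lam <= 0) lam <- 1e-12
  Xa <- rbind(X, diag(sqrt(lam), p))
  ya <- c(y, numeric(p))
  co <- qr.coef(qr(Xa), ya)
  co[is.na(co)] <- 0
  attr(co, "ridge") <- TRUE
  co
}

#' Sign-constrained least-squares fit of a regression system
#'
#' Minimizes \eqn{\|y - X\theta\|^2} subject to \eqn{\theta_c \le 0} for
#' every `nonpositive` column (the miRNA repression constraint).  When the
#' design is rank deficient (or N is too small), a small ridge penalty
#' (`1e-8 * trace(X'X)/p`) is added and the fit is flagged.
#'
#' @param sys a `regression_system` from [build_system()], or a design
#'   matrix (then `response` and `constrained` must be given).
#' @param response response vector (if `sys` is a matrix).
#' @param constrained logical vector marking nonpositive columns (if `sys`
#'   is a matrix).
#' @return list with `coefficients` (named), `SSE`, `ridge` (logical flag).
#' @export
fit_constrained_lsq <- function(sys, response = NULL, constrained = NULL) {
  if (inherits(sys, "regression_system")) {
    X <- sys$design
    y <- sys$response
    constrained <- sys$column_meta$sign_constraint == "nonpositive"
  } else {
    X <- as.matrix(sys)
    y <- response
  }
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in design or response")
  n <- length(y)
  p <- ncol(X)
  if (is.null(constrained)) constrained <- rep(FALSE, p)
  stopifnot(nrow(X) == n, length(constrained) == p)

  ridge_used <- FALSE
  if (p == 0L)
    return(list(coefficients = numeric(0), SSE = sum(y^2), ridge = FALSE))

  ## negate constrained columns: constraint becomes phi >= 0
  B <- X
  if (any(constrained)) B[, constrained] <- -B[, constrained]

  solve_passive <- function(Pset) {
    phi <- numeric(p)
    if (any(Pset)) {
      co <- .ls_solve(B[, Pset, drop = FALSE], y)
      if (isTRUE(attr(co, "ridge"))) ridge_used <<- TRUE
      phi[Pset] <- co
    }
    phi
  }

  P <- !constrained             # free columns always passive
  phi <- solve_passive(P)
  ## clamp any infeasible start (cannot happen: constrained cols not in P)
  tol <- 1e-10 * max(1, sum(abs(crossprod(B, y))))
  Z <- constrained
  iter <- 0L
  max_iter <- 30L * p + 100L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- as.vector(crossprod(B, y - B %*% phi))
    cand <- which(Z & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE; Z[j] <- FALSE
    repeat {
      z <- solve_passive(P)
      viol <- which(P & constrained & z <= 0)
      if (!length(viol)) { phi <- z; break }
      alpha <- min(phi[viol] / (phi[viol] - z[viol]))
      phi <- phi + alpha * (z - phi)
      drop <- which(P & constrained & phi <= tol * max(1, max(abs(phi))))
      phi[drop] <- 0
      P[drop] <- FALSE; Z[drop] <- TRUE
      if (!any(P)) break
    }
  }
  theta <- phi
  theta[constrained] <- -phi[constrained]
  names(theta) <- colnames(X)
  resid <- y - X %*% theta
  list(coefficients = theta, SSE = sum(resid^2), ridge = ridge_used)
}

## Independent brute-force solution of the same convex problem by
## enumerating active subsets of the constrained columns (used by tests as
## an oracle; exact because the optimum's active set is among the subsets).
.constrained_lsq_enum <- function(X, y, constrained) {
  p <- ncol(X)
  C <- which(constrained)
  best <- NULL
  subsets <- if (length(C)) 0:(2^length(C) - 1L) else 0L
  for (s in subsets) {
    active <- C[bitwAnd(s, 2^(seq_along(C) - 1L)) > 0]
    keep <- setdiff(seq_len(p), active)
    theta <- numeric(p)
    if (length(keep)) {
      co <- .ls_solve(X[, keep, drop = FALSE], y)
      theta[keep] <- co
    }
    if (any(theta[C] > 1e-9)) next
    sse <- sum((y - X %*% theta)^2)
    if (is.null(best) || sse < best$SSE)
      best <- list(coefficients = theta, SSE = sse)
  }
  best
}
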