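## Linear programming for flux balance analysis.
##
## Two independent routes are provided on purpose:
##  * lp_solve_bounded(): a dense two-phase primal simplex with Bland's
##    rule, the production path behind fba();
##  * fba_brute_force(): enumeration of basic solutions (fix n-rank(S)
##    reactions at a bound, solve the rest from S v = 0), the oracle the
##    test-suite compares the simplex against.
## Networks at desk scale are tiny (tens of reactions), so dense tableaus
## are the right tool; infinite bounds are clamped to +-BIG_BOUND.

BIG_BOUND <- 1e6

#' Solve max c'v subject to A v = b, lb <= v <= ub
#'
#' Two-phase dense simplex with Bland's anti-cycling rule. Intended for
#' small (toy / synthetic) flux polytopes; infinite bounds are clamped
#' at `1e6`.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n).
#' @param maximize maximize (default) or minimize.
#' @return `list(status, x, objective)`; status one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`.
#' @export
lp_solve_bounded <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL, objective = NA_real_))
  lb2 <- pmax(lb, -BIG_BOUND); ub2 <- pmin(ub, BIG_BOUND)
  cvec <- if (maximize) obj else -obj
  # shift x = v - lb >= 0, add upper-bound slacks: x + s = u
  u <- ub2 - lb2
  b1 <- b - drop(A %*% lb2)
  Astd <- rbind(cbind(A, matrix(0, m, n)),
                cbind(diag(n), diag(n)))
  bstd <- c(b1, u)
  cstd <- c(cvec, rep(0, n))
  res <- simplex_two_phase(Astd, bstd, cstd)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objective = NA_real_))
  v <- res$x[seq_len(n)] + lb2
  objective <- sum(obj * v)
  list(status = "optimal", x = v, objective = objective)
}

## max c'x s.t. Ax = b, x >= 0
simplex_two_phase <- function(A, b, cvec, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg]
  # phase 1: artificials with identity basis
  T1 <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(-1, m))
  out <- simplex_iterate(T1, basis, c1, tol)
  if (out$status == "unbounded") return(list(status = "infeasible"))
  T1 <- out$tab; basis <- out$basis
  phase1_obj <- sum(c1[basis] * T1[, ncol(T1)])
  if (phase1_obj < -1e-7) return(list(status = "infeasible"))
  # drive remaining artificials out of the basis
  art <- which(basis > n)
  drop_rows <- integer(0)
  for (i in art) {
    piv <- which(abs(T1[i, seq_len(n)]) > tol)
    if (length(piv)) {
      T1 <- simplex_pivot(T1, i, piv[1])
      basis[i] <- piv[1]
    } else {
      drop_rows <- c(drop_rows, i)  # redundant constraint
    }
  }
  if (length(drop_rows)) {
    T1 <- T1[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2 on the original columns
  T2 <- T1[, c(seq_len(n), ncol(T1)), drop = FALSE]
  out <- simplex_iterate(T2, basis, cvec, tol)
  if (out$status == "unbounded") return(list(status = "unbounded"))
  tab <- out$tab; basis <- out$basis
  x <- numeric(n)
  x[basis] <- tab[, ncol(tab)]
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

simplex_iterate <- function(tab, basis, cvec, tol = 1e-9, max_iter = 100000L) {
  m <- nrow(tab); ncols <- ncol(tab); n <- ncols - 1L
  for (iter in seq_len(max_iter)) {
    # reduced costs z_j = c_j - c_B' B^{-1} a_j  (tab already reduced)
    cb <- cvec[basis]
    red <- cvec[seq_len(n)] - drop(crossprod(tab[, seq_len(n), drop = FALSE], cb))
    red[basis] <- 0
    enter <- which(red > tol)
    if (!length(enter)) return(list(status = "optimal", tab = tab, basis = basis))
    j <- min(enter)  # Bland
    col <- tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", tab = tab, basis = basis))
    ratio <- tab[pos, ncols] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]  # Bland tie-break
    tab <- simplex_pivot(tab, i, j)
    basis[i] <- j
  }
  stop("simplex: iteration limit reached")
}

simplex_pivot <- function(tab, i, j) {
  tab[i, ] <- tab[i, ] / tab[i, j]
  other <- setdiff(seq_len(nrow(tab)), i)
  tab[other, ] <- tab[other, , drop = FALSE] -
    outer(tab[other, j], tab[i, ])
  tab
}

#' Brute-force FBA oracle by basic-solution enumeration
#'
#' Independent check on the simplex route: every vertex of
#' \{S v = 0, lb <= v <= ub\} fixes at least n - rank(S) reactions at a
#' bound; the remaining fluxes follow from the mass-balance equations.
#' All such candidates are enumerated and the best feasible objective
#' returned. Exponential in n - rank(S); use on toy networks only.
#'
#' @param S stoichiometric matrix (metabolites x reactions).
#' @param lb,ub finite bound vectors.
#' @param w objective coefficients.
#' @param tol feasibility tolerance.
#' @return `list(objective, x, status)`.
#' @export
fba_brute_force <- function(S, lb, ub, w, tol = 1e-7) {
  S <- as.matrix(S); n <- ncol(S)
  lb <- pmax(lb, -BIG_BOUND); ub <- pmin(ub, BIG_BOUND)
  r <- if (nrow(S)) qr(S)$rank else 0L
  best <- -Inf; bestx <- NULL
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (nrow(S) && max(abs(S %*% v)) > tol) return()
    o <- sum(w * v)
    if (o > best) { best <<- o; bestx <<- v }
  }
  if (r == 0L) {
    v <- ifelse(w > 0, ub, lb)
    consider(v)
  } else {
    combos_B <- utils::combn(n, r)
    nfix <- n - r
    grid <- if (nfix == 0L) matrix(FALSE, 1, 0) else
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nfix)))
    for (k in seq_len(ncol(combos_B))) {
      B <- combos_B[, k]
      SB <- S[, B, drop = FALSE]
      qrB <- qr(SB)
      if (qrB$rank < r) next
      N <- setdiff(seq_len(n), B)
      for (g in seq_len(nrow(grid))) {
        vN <- ifelse(grid[g, ], ub[N], lb[N])
        rhs <- if (length(N)) -drop(S[, N, drop = FALSE] %*% vN) else numeric(nrow(S))
        vB <- tryCatch(qr.coef(qrB, rhs), error = function(e) NULL)
        if (is.null(vB) || anyNA(vB)) next
        v <- numeric(n); v[B] <- vB; v[N] <- vN
        consider(v)
      }
    }
  }
  if (is.null(bestx)) return(list(objective = NA_real_, x = NULL, status = "infeasible"))
  list(objective = best, x = bestx, status = "optimal")
}
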