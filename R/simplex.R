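# Dense two-phase primal simplex with Bland's rule.
#
# Solves   max  c'x   s.t.  A x = b,  x >= 0.
#
# The flux balance problems this package builds are small (tens of variables:
# directional flux splits plus bound and crowding slacks), dense, and highly
# degenerate, so a tableau method with Bland's anti-cycling rule is both fast
# enough and -- crucially for the reproducibility contracts of the ensemble
# experiments -- fully deterministic: identical inputs give identical optimal
# vertices, not merely identical objective values.

# One pivot on tableau `tab` (rows = constraints, last column = rhs).
.spxPivot <- function(tab, row, col) {
  piv <- tab[row, col]
  tab[row, ] <- tab[row, ] / piv
  other <- setdiff(seq_len(nrow(tab)), row)
  # rank-1 update; keep pivot column numerically exact
  tab[other, ] <- tab[other, ] - outer(tab[other, col], tab[row, ])
  tab[other, col] <- 0
  tab
}

# Run simplex iterations on a canonical tableau for objective `cost`
# (maximization) over columns `cols`. Returns updated tableau/basis.
.spxIterate <- function(tab, basis, cost, cols, tol, maxIter) {
  m <- nrow(tab)
  rhsCol <- ncol(tab)
  for (iter in seq_len(maxIter)) {
    red <- cost[cols] - drop(cost[basis] %*% tab[, cols, drop = FALSE])
    enterable <- cols[red > tol]
    enterable <- setdiff(enterable, basis)
    if (!length(enterable)) {
      return(list(tab = tab, basis = basis, status = "optimal"))
    }
    j <- min(enterable) # Bland: smallest eligible index enters
    colj <- tab[, j]
    rows <- which(colj > tol)
    if (!length(rows)) {
      return(list(tab = tab, basis = basis, status = "unbounded"))
    }
    ratio <- tab[rows, rhsCol] / colj[rows]
    best <- rows[ratio <= min(ratio) + tol]
    i <- best[which.min(basis[best])] # Bland: smallest basic variable leaves
    tab <- .spxPivot(tab, i, j)
    basis[i] <- j
  }
  list(tab = tab, basis = basis, status = "maxiter")
}

#' @noRd
.simplex <- function(obj, A, b, tol = 1e-9, maxIter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m)
  # row equilibration: scale every constraint to max |coefficient| 1 so that
  # crowding rows (coefficients possibly ~1e-6) pivot reliably
  scale <- apply(abs(A), 1, max)
  scale[scale < tol] <- 1
  A <- A / scale
  b <- b / scale
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  # phase 1: maximize -(sum of artificials)
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- .spxIterate(tab, basis, cost1, seq_len(n + m), tol, maxIter)
  if (ph1$status == "maxiter") return(list(status = "maxiter"))
  tab <- ph1$tab; basis <- ph1$basis
  resid <- -drop(cost1[basis] %*% tab[, ncol(tab)])
  if (resid > tol * max(1, sum(abs(b)))) {
    return(list(status = "infeasible"))
  }
  # drive leftover artificials out of the basis (degenerate rows)
  keep <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] > n) {
      cand <- which(abs(tab[r, seq_len(n)]) > tol)
      cand <- setdiff(cand, basis)
      if (length(cand)) {
        tab <- .spxPivot(tab, r, min(cand))
        basis[r] <- min(cand)
      } else {
        keep[r] <- FALSE # redundant constraint row
      }
    }
  }
  tab <- tab[keep, , drop = FALSE]
  basis <- basis[keep]
  tab <- tab[, c(seq_len(n), n + m + 1L), drop = FALSE]
  # phase 2
  ph2 <- .spxIterate(tab, basis, c(obj, 0), seq_len(n), tol, maxIter)
  if (ph2$status == "maxiter") return(list(status = "maxiter"))
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  tab <- ph2$tab; basis <- ph2$basis
  x <- numeric(n)
  x[basis] <- tab[, ncol(tab)]
  x[x < 0 & x > -tol] <- 0
  list(status = "optimal", x = x, value = sum(obj * x))
}
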