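# Dense two-phase primal simplex for the small LPs this package solves
# (flux balance systems of toy-to-moderate size). Variables carry finite box
# bounds which are encoded as explicit rows, phase 1 uses artificial
# variables on the equality rows, and pivoting follows Bland's rule
# throughout, so the method terminates on the (heavily degenerate) S v = 0
# systems FBA produces.

# max/min cvec'x  s.t.  A x = b, 0 <= x <= u   (b may be any sign; u finite)
lp_simplex <- function(cvec, A, b, u, maximize = TRUE, eps = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(u) == n, all(is.finite(u)), all(u >= 0))
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  # drop all-zero rows (redundant if b == 0, infeasible otherwise)
  zero_row <- apply(abs(A) > eps, 1, sum) == 0
  if (any(zero_row & b > eps))
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  if (any(zero_row)) { A <- A[!zero_row, , drop = FALSE]; b <- b[!zero_row] }
  m <- nrow(A)

  bounded <- which(u < Inf & u > 0)  # u == 0 variables are structurally zero
  fixed0 <- which(u == 0)
  if (length(fixed0)) { A[, fixed0] <- 0; cvec_f <- cvec; cvec_f[fixed0] <- 0 }
  nb <- length(bounded)
  # columns: x (n) | bound slacks (nb) | artificials (m)
  ncols <- n + nb + m
  Tm <- matrix(0, m + nb, ncols + 1L)
  Tm[seq_len(m), seq_len(n)] <- A
  Tm[seq_len(m), n + nb + seq_len(m)] <- diag(m)
  Tm[seq_len(m), ncols + 1L] <- b
  if (nb) {
    Tm[cbind(m + seq_len(nb), bounded)] <- 1
    Tm[cbind(m + seq_len(nb), n + seq_len(nb))] <- 1
    Tm[m + seq_len(nb), ncols + 1L] <- u[bounded]
  }
  basis <- c(n + nb + seq_len(m), n + seq_len(nb))

  # phase 1: drive the artificials to zero
  cost1 <- c(rep(0, n + nb), rep(1, m))
  res <- simplex_iterate(Tm, basis, cost1, eps)
  Tm <- res$T; basis <- res$basis
  art_cols <- n + nb + seq_len(m)
  xall <- numeric(ncols)
  xall[basis] <- Tm[, ncols + 1L]
  if (sum(xall[art_cols]) > 1e-7)
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  # pivot basic artificials (at zero) out, or drop their redundant rows
  drop_rows <- integer(0)
  for (r in seq_along(basis)) {
    if (basis[r] %in% art_cols) {
      piv <- which(abs(Tm[r, seq_len(n + nb)]) > eps &
                     !(seq_len(n + nb) %in% basis))
      if (length(piv)) {
        Tm <- simplex_pivot(Tm, r, piv[1])
        basis[r] <- piv[1]
      } else {
        drop_rows <- c(drop_rows, r)
      }
    }
  }
  if (length(drop_rows)) {
    Tm <- Tm[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2 on the real objective (artificial columns neutralised)
  cost2 <- c(if (length(fixed0)) cvec_f else cvec, rep(0, nb), rep(0, m))
  if (maximize) cost2 <- -cost2
  Tm[, art_cols] <- 0
  res <- simplex_iterate(Tm, basis, cost2, eps)
  Tm <- res$T; basis <- res$basis
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, x = NULL))
  x <- numeric(ncols)
  x[basis] <- Tm[, ncol(Tm)]
  xv <- x[seq_len(n)]
  list(status = "optimal", value = sum(cvec * xv), x = xv)
}

simplex_pivot <- function(Tm, r, c) {
  Tm[r, ] <- Tm[r, ] / Tm[r, c]
  other <- setdiff(seq_len(nrow(Tm)), r)
  Tm[other, ] <- Tm[other, ] - outer(Tm[other, c], Tm[r, ])
  Tm
}

# minimise cost'x over the tableau; Bland's rule (smallest-index entering
# and leaving) guarantees termination under degeneracy
simplex_iterate <- function(Tm, basis, cost, eps, max_iter = 20000L) {
  nc <- ncol(Tm) - 1L
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    red <- cost - as.vector(cb %*% Tm[, seq_len(nc), drop = FALSE])
    red[basis] <- 0
    enter_candidates <- which(red < -eps)
    if (!length(enter_candidates))
      return(list(T = Tm, basis = basis, status = "optimal"))
    enter <- enter_candidates[1L]           # Bland: smallest index
    col <- Tm[, enter]
    pos <- which(col > eps)
    if (!length(pos))
      return(list(T = Tm, basis = basis, status = "unbounded"))
    ratios <- Tm[pos, nc + 1L] / col[pos]
    best <- min(ratios)
    tie <- pos[ratios <= best + eps]
    leave <- tie[which.min(basis[tie])]     # Bland: smallest basic index
    Tm <- simplex_pivot(Tm, leave, enter)
    basis[leave] <- enter
  }
  list(T = Tm, basis = basis, status = "unsolved")
}
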