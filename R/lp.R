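# Internal linear-programming layer.
#
# All flux and elementary-mode-coefficient problems in this package are LPs
# over nonnegative variables:
#
#   max / min  c'x   s.t.  A_eq x = b_eq,  A_le x <= b_le,  A_ge x >= b_ge,
#                          x >= 0
#
# solved by a dense two-phase primal simplex written here. The problems are
# small (tens of variables and rows) but are solved many thousands of times
# inside branch-and-bound and Monte-Carlo loops, and correctness of every
# optimizer in the package rests on this layer, so it detects infeasibility
# and unboundedness explicitly and uses Bland's rule as an anti-cycling
# fallback after a stall.

.LP_TOL <- 1e-9

# One simplex run on the tableau
#   rows 1..m : [ b | A ]  (b >= 0 maintained)
#   row  m+1  : [ -z | reduced costs ]
# minimizing, basis = column index per row. `allowed` marks columns that may
# enter (used to lock out artificials in phase 2).
simplex_core <- function(tab, basis, allowed, max_iter) {
  m <- nrow(tab) - 1L
  bland_after <- max_iter %/% 2L
  for (it in seq_len(max_iter)) {
    red <- tab[m + 1L, -1L]
    cand <- which(red < -.LP_TOL & allowed)
    if (!length(cand)) return(list(tab = tab, basis = basis, status = "optimal"))
    enter <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])]
    col <- tab[seq_len(m), enter + 1L]
    pos <- which(col > .LP_TOL)
    if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
    ratios <- tab[pos, 1L] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + .LP_TOL]
    leave <- if (length(ties) > 1L) ties[which.min(basis[ties])] else ties
    # pivot
    pr <- tab[leave, ] / tab[leave, enter + 1L]
    tab <- tab - tab[, enter + 1L] %o% pr
    tab[leave, ] <- pr
    basis[leave] <- enter
    tab[seq_len(m), 1L][abs(tab[seq_len(m), 1L]) < .LP_TOL] <- 0
  }
  list(tab = tab, basis = basis, status = "iteration-limit")
}

# min/max obj'x s.t. A_eq x = b_eq, A_le x <= b_le, A_ge x >= b_ge, x >= 0
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     A_ge = NULL, b_ge = NULL, maximize = TRUE) {
  n <- length(obj)
  as_mat <- function(A) if (is.null(A)) matrix(0, 0, n) else
    matrix(as.numeric(A), ncol = n)
  A_eq <- as_mat(A_eq); A_le <- as_mat(A_le); A_ge <- as_mat(A_ge)
  b_eq <- as.numeric(b_eq %||% numeric(0))
  b_le <- as.numeric(b_le %||% numeric(0))
  b_ge <- as.numeric(b_ge %||% numeric(0))

  # a >= row with nonpositive rhs is implied by x >= 0 unless its
  # coefficients are negative; normalize all rows to b >= 0 instead
  A <- rbind(A_le, A_ge, A_eq)
  b <- c(b_le, b_ge, b_eq)
  m <- nrow(A)
  type <- rep(c("le", "ge", "eq"), c(nrow(A_le), nrow(A_ge), nrow(A_eq)))
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  type[flip] <- c(le = "ge", ge = "le", eq = "eq")[type[flip]]

  # slack (+1) for le, surplus (-1) for ge; artificials where the slack
  # cannot seed the basis (ge and eq rows)
  n_slack <- sum(type == "le") + sum(type == "ge")
  slack_of <- integer(m); art_of <- integer(m)
  Aext <- cbind(A, matrix(0, m, n_slack))
  sc <- n
  for (i in seq_len(m)) {
    if (type[i] == "le") { sc <- sc + 1L; Aext[i, sc] <- 1; slack_of[i] <- sc }
    if (type[i] == "ge") { sc <- sc + 1L; Aext[i, sc] <- -1; slack_of[i] <- sc }
  }
  need_art <- type != "le"
  n_art <- sum(need_art)
  Aext <- cbind(Aext, matrix(0, m, n_art))
  ac <- n + n_slack
  basis <- integer(m)
  for (i in seq_len(m)) {
    if (need_art[i]) { ac <- ac + 1L; Aext[i, ac] <- 1; art_of[i] <- ac; basis[i] <- ac }
    else basis[i] <- slack_of[i]
  }
  ntot <- n + n_slack + n_art
  max_iter <- 200L + 40L * (m + ntot)

  cost <- if (maximize) -obj else obj

  if (n_art > 0) {
    # phase 1: minimize the artificial sum
    tab <- rbind(cbind(b, Aext), 0)
    art_cols <- which(art_of > 0)
    tab[m + 1L, ] <- -colSums(tab[art_cols, , drop = FALSE])
    # each artificial is basic in exactly one row: its own reduced cost is 0
    tab[m + 1L, 1L + ((n + n_slack + 1L):ntot)] <- 0
    allowed <- rep(TRUE, ntot)
    ph1 <- simplex_core(tab, basis, allowed, max_iter)
    if (ph1$status == "iteration-limit")
      return(list(status = "iteration-limit", objective = NA_real_,
                  x = rep(NA_real_, n)))
    if (-ph1$tab[m + 1L, 1L] > 1e-7)
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
    tab <- ph1$tab; basis <- ph1$basis
    # pivot residual zero-level artificials out of the basis where possible
    for (i in which(basis > n + n_slack)) {
      row <- tab[i, -1L]
      piv <- which(abs(row) > .LP_TOL & seq_len(ntot) <= n + n_slack)
      if (length(piv)) {
        enter <- piv[1L]
        pr <- tab[i, ] / tab[i, enter + 1L]
        tab <- tab - tab[, enter + 1L] %o% pr
        tab[i, ] <- pr
        basis[i] <- enter
      }
    }
    # rebuild the cost row for phase 2
    tab[m + 1L, ] <- c(0, cost, rep(0, n_slack + n_art))
    for (i in seq_len(m)) {
      cb <- tab[m + 1L, basis[i] + 1L]
      if (cb != 0) tab[m + 1L, ] <- tab[m + 1L, ] - cb * tab[i, ]
    }
    allowed <- c(rep(TRUE, n + n_slack), rep(FALSE, n_art))
  } else {
    tab <- rbind(cbind(b, Aext), c(0, cost, rep(0, n_slack)))
    for (i in seq_len(m)) {
      cb <- tab[m + 1L, basis[i] + 1L]
      if (cb != 0) tab[m + 1L, ] <- tab[m + 1L, ] - cb * tab[i, ]
    }
    allowed <- rep(TRUE, ntot)
  }

  ph2 <- simplex_core(tab, basis, allowed, max_iter)
  if (ph2$status != "optimal")
    return(list(status = ph2$status, objective = NA_real_,
                x = rep(NA_real_, n)))
  x <- numeric(ntot)
  x[ph2$basis] <- ph2$tab[seq_len(m), 1L]
  x <- x[seq_len(n)]
  x[abs(x) < .LP_TOL] <- 0
  list(status = "optimal", objective = sum(obj * x), x = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Maximize or minimize a linear functional of a flux vector over
# {S v = 0, lower <= v <= upper} plus optional extra rows. Infinite upper
# bounds simply contribute no row; true unboundedness is reported as such.
fba_lp <- function(S, obj, upper, lower = NULL, maximize = TRUE,
                   A_le = NULL, b_le = NULL, A_ge = NULL, b_ge = NULL) {
  n <- ncol(S)
  if (is.null(lower)) lower <- rep(0, n)
  ub_rows <- which(is.finite(upper))
  A1 <- if (length(ub_rows)) diag(n)[ub_rows, , drop = FALSE] else NULL
  b1 <- if (length(ub_rows)) upper[ub_rows] else NULL
  lb_rows <- which(lower > 0)
  A2 <- if (length(lb_rows)) diag(n)[lb_rows, , drop = FALSE] else NULL
  b2 <- if (length(lb_rows)) lower[lb_rows] else NULL
  if (!is.null(A_le)) { A1 <- rbind(A1, A_le); b1 <- c(b1, b_le) }
  if (!is.null(A_ge)) { A2 <- rbind(A2, A_ge); b2 <- c(b2, b_ge) }
  lp_solve(obj, A_eq = S, b_eq = rep(0, nrow(S)), A_le = A1, b_le = b1,
           A_ge = A2, b_ge = b2, maximize = maximize)
}
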