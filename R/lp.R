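# Dense two-phase simplex for the small linear programs behind flux
# variability analysis.  Problems here have tens of variables, so a plain
# tableau with Bland's anti-cycling rule is both adequate and exactly
# reproducible; no external solver is required.

# Solve: optimize c'v  s.t.  S v = 0,  lb <= v <= ub.
# maximize = TRUE maximizes, else minimizes.  Returns list(status, objective,
# solution).  status: "optimal" | "infeasible" | "unbounded".
solve_flux_lp <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible"))
  # substitute x = v - lb  =>  0 <= x <= ub - lb,  S x = -S lb
  rng <- ub - lb
  beq <- as.numeric(-S %*% lb)
  # bounded variables: add slack rows x_i + s_i = rng_i for finite ranges
  finite_ub <- which(is.finite(rng))
  m_eq <- nrow(S)
  m_ub <- length(finite_ub)
  m <- m_eq + m_ub
  ncols <- n + m_ub          # structural + upper-bound slacks
  A <- matrix(0, m, ncols)
  A[seq_len(m_eq), seq_len(n)] <- S
  b <- c(beq, rng[finite_ub])
  if (m_ub > 0) {
    for (j in seq_len(m_ub)) {
      A[m_eq + j, finite_ub[j]] <- 1
      A[m_eq + j, n + j] <- 1
    }
  }
  # flip equality rows so b >= 0 (slack rows already have b >= 0)
  neg <- which(b < 0)
  if (length(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  cvec <- c(if (maximize) -obj else obj, rep(0, m_ub))  # minimize internally

  # Phase 1: artificials only for the equality rows; the upper-bound slack
  # variables serve as the starting basis of their own rows.
  Aext <- cbind(A, rbind(diag(m_eq), matrix(0, m_ub, m_eq)))
  cost1 <- c(rep(0, ncols), rep(1, m_eq))
  basis <- c(ncols + seq_len(m_eq),
             if (m_ub > 0) n + seq_len(m_ub))
  res1 <- simplex_core(Aext, b, cost1, basis, tol)
  if (res1$status != "optimal" || res1$objective > 1e-7)
    return(list(status = "infeasible"))
  tab <- res1$tab; basis <- res1$basis
  # drive any artificial still basic (at zero) out of the basis
  for (i in seq_len(m)) {
    if (basis[i] > ncols) {
      piv <- which(abs(tab[i, seq_len(ncols)]) > tol)[1]
      if (!is.na(piv)) {
        tab <- pivot_tableau(tab, i, piv)
        basis[i] <- piv
      }
    }
  }
  keep <- c(seq_len(ncols), ncol(tab))  # drop artificial columns
  redundant <- basis > ncols            # rows whose artificial stayed basic
  tab <- tab[!redundant, keep, drop = FALSE]
  basis <- basis[!redundant]
  res2 <- simplex_core(tab[, -ncol(tab), drop = FALSE],
                       tab[, ncol(tab)], cvec, basis, tol, phase1 = FALSE)
  if (res2$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(ncols)
  x[res2$basis] <- res2$tab[, ncol(res2$tab)]
  v <- x[seq_len(n)] + lb
  objective <- sum(obj * v)
  list(status = "optimal", objective = objective, solution = v)
}

# Tableau simplex minimizing cost'x over A x = b (b >= 0), x >= 0, starting
# from a given feasible basis.  Bland's rule; returns final tableau + basis.
simplex_core <- function(A, b, cost, basis, tol = 1e-9, phase1 = TRUE) {
  m <- nrow(A); ncols <- ncol(A)
  tab <- cbind(A, b)
  # canonicalize rows for the starting basis
  for (i in seq_len(m)) {
    piv <- tab[i, basis[i]]
    if (abs(piv - 1) > tol || any(abs(tab[-i, basis[i]]) > tol)) {
      tab <- pivot_tableau(tab, i, basis[i])
    }
  }
  it_max <- 200L * (m + ncols)
  for (it in seq_len(it_max)) {
    # reduced costs
    cb <- cost[basis]
    z <- as.numeric(cb %*% tab[, seq_len(ncols), drop = FALSE])
    red <- cost[seq_len(ncols)] - z
    enter_cands <- which(red < -tol)
    if (!length(enter_cands)) {
      objective <- sum(cb * tab[, ncols + 1])
      return(list(status = "optimal", tab = tab, basis = basis,
                  objective = objective))
    }
    enter <- min(enter_cands)  # Bland
    col <- tab[, enter]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- tab[pos, ncols + 1] / col[pos]
    best <- min(ratios)
    leave_cands <- pos[ratios <= best + tol]
    leave <- leave_cands[which.min(basis[leave_cands])]  # Bland on ties
    tab <- pivot_tableau(tab, leave, enter)
    basis[leave] <- enter
  }
  stop2("simplex iteration limit reached")
}

pivot_tableau <- function(tab, row, col) {
  tab[row, ] <- tab[row, ] / tab[row, col]
  others <- setdiff(seq_len(nrow(tab)), row)
  if (length(others)) {
    tab[others, ] <- tab[others, , drop = FALSE] -
      outer(tab[others, col], tab[row, ])
  }
  tab
}
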