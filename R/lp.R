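# Dense two-phase simplex. Problem sizes here are small (toy networks,
# paired-condition models with a few hundred columns), so a dense tableau
# with Bland's-rule fallback is both fast enough and numerically
# transparent.

#' Solve a linear program
#'
#' Minimizes or maximizes `obj %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and `lb <= x <= ub`, by two-phase dense simplex.
#' Lower bounds must be finite; upper bounds may be `Inf`.
#'
#' @param obj numeric objective coefficients.
#' @param A_eq,b_eq equality constraints (matrix may be `NULL`).
#' @param A_le,b_le inequality (<=) constraints (matrix may be `NULL`).
#' @param lb,ub variable bounds, recycled to `length(obj)`.
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivot tolerance.
#' @param opt_tol optimality / feasibility tolerance on reduced costs.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (solution in original variable space) and `objective`.
#' @keywords internal
#' @noRd
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb = 0, ub = Inf, maximize = FALSE,
                     tol = 1e-9, opt_tol = 1e-7) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb))) stop("solve_lp requires finite lower bounds")
  if (any(ub < lb)) stop("solve_lp: upper bound below lower bound")

  if (!is.null(A_eq)) {
    A_eq <- matrix(as.numeric(A_eq), ncol = n)
    b_eq <- as.numeric(b_eq) - as.vector(A_eq %*% lb)
  }
  if (!is.null(A_le)) {
    A_le <- matrix(as.numeric(A_le), ncol = n)
    b_le <- as.numeric(b_le) - as.vector(A_le %*% lb)
  }
  ubs <- ub - lb                      # shifted upper bounds, x >= 0
  fin <- which(is.finite(ubs))

  m_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  m_le <- if (is.null(A_le)) 0L else nrow(A_le)
  m_ub <- length(fin)
  m <- m_eq + m_le + m_ub
  n_slack <- m_le + m_ub
  nc <- n + n_slack                   # structural + slack columns
  ncol_tot <- nc + m                  # + artificial columns

  A <- matrix(0, m, ncol_tot)
  b <- numeric(m)
  r <- 0L
  if (m_eq) {
    A[seq_len(m_eq), seq_len(n)] <- A_eq
    b[seq_len(m_eq)] <- b_eq
    r <- m_eq
  }
  if (m_le) {
    idx <- r + seq_len(m_le)
    A[idx, seq_len(n)] <- A_le
    A[cbind(idx, n + seq_len(m_le))] <- 1
    b[idx] <- b_le
    r <- r + m_le
  }
  if (m_ub) {
    idx <- r + seq_len(m_ub)
    A[cbind(idx, fin)] <- 1
    A[cbind(idx, n + m_le + seq_len(m_ub))] <- 1
    b[idx] <- ubs[fin]
  }
  neg <- which(b < 0)
  if (length(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  A[cbind(seq_len(m), nc + seq_len(m))] <- 1   # artificial identity
  basis <- nc + seq_len(m)

  Tab <- cbind(A, b)
  rhs_col <- ncol_tot + 1L

  cost_min <- if (maximize) -obj else obj

  objective_row <- function(cost) {
    # cost over all columns; returns c(reduced costs, -z) for current basis
    cfull <- c(cost, numeric(ncol_tot - length(cost)))
    cb <- cfull[basis]
    red <- cfull - as.vector(crossprod(cb, Tab[, seq_len(ncol_tot), drop = FALSE]))
    z <- sum(cb * Tab[, rhs_col])
    c(red, -z)
  }

  run_simplex <- function(cost, allowed) {
    # minimizes; returns list(status, orow)
    orow <- objective_row(cost)
    it <- 0L
    max_it <- 2000L + 200L * (m + nc)
    stall <- 0L
    bland <- FALSE
    repeat {
      it <- it + 1L
      if (it > max_it) stop("simplex iteration limit exceeded")
      if (it %% 300L == 0L) orow <- objective_row(cost)  # kill numeric drift
      red <- orow[seq_len(ncol_tot)]
      cand <- which(allowed & red < -opt_tol)
      if (!length(cand)) return(list(status = "optimal", orow = orow))
      j <- if (bland) cand[1L] else cand[which.min(red[cand])]
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded", orow = orow))
      ratios <- Tab[pos, rhs_col] / col[pos]
      rmin <- min(ratios)
      tiers <- pos[ratios <= rmin + tol]
      p <- tiers[which.min(basis[tiers])]      # Bland-compatible tie-break
      if (rmin < tol) stall <- stall + 1L else stall <- 0L
      if (stall > 3L * (m + 10L)) bland <- TRUE
      piv <- Tab[p, j]
      Tab[p, ] <<- Tab[p, ] / piv
      fac <- Tab[, j]
      fac[p] <- 0
      nz <- which(abs(fac) > 0)
      if (length(nz)) Tab[nz, ] <<- Tab[nz, ] - outer(fac[nz], Tab[p, ])
      orow <- orow - orow[j] * Tab[p, ]
      basis[p] <<- j
    }
  }

  # Phase 1: minimize sum of artificials
  allowed1 <- c(rep(TRUE, nc), rep(TRUE, m))
  c1 <- c(numeric(nc), rep(1, m))
  res1 <- run_simplex(c1, allowed1)
  phase1_obj <- res1$orow[rhs_col] * -1
  if (phase1_obj > 1e-6) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # Drive artificials out of the basis where possible
  for (i in seq_len(m)) {
    if (basis[i] > nc) {
      row <- Tab[i, seq_len(nc)]
      j <- which(abs(row) > 1e-7)
      if (length(j)) {
        j <- j[1L]
        piv <- Tab[i, j]
        Tab[i, ] <- Tab[i, ] / piv
        fac <- Tab[, j]
        fac[i] <- 0
        nz <- which(abs(fac) > 0)
        if (length(nz)) Tab[nz, ] <- Tab[nz, ] - outer(fac[nz], Tab[i, ])
        basis[i] <- j
      }
    }
  }

  # Phase 2
  allowed2 <- c(rep(TRUE, nc), rep(FALSE, m))
  res2 <- run_simplex(cost_min, allowed2)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  x_std <- numeric(ncol_tot)
  x_std[basis] <- Tab[, rhs_col]
  x <- x_std[seq_len(n)] + lb
  list(status = "optimal", x = x, objective = sum(obj * x))
}
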