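#' Dense two-phase simplex for bounded linear programs
#'
#' Solves `max/min c'x` subject to `Aeq x = beq`, `Age x >= bge` and
#' `lb <= x <= ub`. This is the linear-programming backend behind every flux
#' balance computation in the package. It is a textbook two-phase tableau
#' simplex with a Dantzig pivot rule that falls back to Bland's rule to
#' guarantee termination on the highly degenerate programs that metabolic
#' steady-state constraints produce. Problem sizes targeted here (core-carbon
#' networks, a few hundred variables) are well within dense-tableau territory.
#'
#' Lower bounds must be finite (flux bounds in constraint-based models are);
#' upper bounds may be `Inf`.
#'
#' @param obj numeric objective coefficients, length n.
#' @param Aeq,beq equality constraints (matrix m1 x n, vector m1), or NULL.
#' @param Age,bge inequality constraints `Age x >= bge`, or NULL.
#' @param lb,ub variable bounds, length n; `lb` finite, `ub` may be `Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (length-n solution, NULL unless optimal) and `objval`.
#' @keywords internal
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Age = NULL, bge = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) {
    stop("lp_solve requires finite lower bounds")
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }

  # shift x = y + lb so y >= 0
  if (!is.null(Aeq)) {
    Aeq <- as.matrix(Aeq)
    beq <- as.numeric(beq) - as.numeric(Aeq %*% lb)
  }
  if (!is.null(Age)) {
    Age <- as.matrix(Age)
    bge <- as.numeric(bge) - as.numeric(Age %*% lb)
  }
  u <- ub - lb                       # y upper bounds, may be Inf
  cc <- if (maximize) -obj else obj  # minimize form
  shift_const <- sum(obj * lb)

  m_eq <- if (is.null(Aeq)) 0L else nrow(Aeq)
  m_ge <- if (is.null(Age)) 0L else nrow(Age)
  ub_idx <- which(is.finite(u))
  m_ub <- length(ub_idx)
  m <- m_eq + m_ge + m_ub

  # columns: y (n) | ub slacks (m_ub) | ge surplus/slack (m_ge) | artificials
  n_cols <- n + m_ub + m_ge
  Tmat <- matrix(0, m, n_cols)
  rhs <- numeric(m)
  basis <- integer(m)
  art_rows <- integer(0)

  row <- 0L
  for (k in seq_along(ub_idx)) {
    row <- row + 1L
    j <- ub_idx[k]
    Tmat[row, j] <- 1
    Tmat[row, n + k] <- 1
    rhs[row] <- u[j]
    basis[row] <- n + k
  }
  if (m_eq > 0) {
    for (i in seq_len(m_eq)) {
      row <- row + 1L
      a <- Aeq[i, ]
      b <- beq[i]
      if (b < 0) { a <- -a; b <- -b }
      Tmat[row, seq_len(n)] <- a
      rhs[row] <- b
      art_rows <- c(art_rows, row)
    }
  }
  if (m_ge > 0) {
    for (i in seq_len(m_ge)) {
      row <- row + 1L
      a <- Age[i, ]
      b <- bge[i]
      if (b >= 0) {
        # a.y - t = b, artificial needed
        Tmat[row, seq_len(n)] <- a
        Tmat[row, n + m_ub + i] <- -1
        rhs[row] <- b
        art_rows <- c(art_rows, row)
      } else {
        # flip: -a.y + t = -b >= 0, slack t basic
        Tmat[row, seq_len(n)] <- -a
        Tmat[row, n + m_ub + i] <- 1
        rhs[row] <- -b
        basis[row] <- n + m_ub + i
      }
    }
  }

  n_art <- length(art_rows)
  if (n_art > 0) {
    Amat <- matrix(0, m, n_art)
    for (k in seq_len(n_art)) {
      Amat[art_rows[k], k] <- 1
      basis[art_rows[k]] <- n_cols + k
    }
    Tmat <- cbind(Tmat, Amat)
  }
  total_cols <- ncol(Tmat)
  art_cols <- if (n_art > 0) (n_cols + 1L):total_cols else integer(0)

  run_simplex <- function(Tmat, rhs, basis, cost, banned) {
    m <- nrow(Tmat)
    # reduced costs for current basis
    cB <- cost[basis]
    red <- cost - as.numeric(cB %*% Tmat)
    objv <- sum(cB * rhs)
    max_iter <- 200L * (m + ncol(Tmat))
    bland_after <- 10L * (m + ncol(Tmat))
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      cand <- which(red < -tol)
      cand <- setdiff(cand, banned)
      if (length(cand) == 0) {
        return(list(Tmat = Tmat, rhs = rhs, basis = basis, red = red,
                    objv = objv, status = "optimal"))
      }
      jin <- if (it > bland_after) min(cand) else cand[which.min(red[cand])]
      col <- Tmat[, jin]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(status = "unbounded"))
      }
      ratios <- rhs[pos] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol]
      # tie-break on smallest basis index (anti-cycling aid)
      ip <- ties[which.min(basis[ties])]
      piv <- Tmat[ip, jin]
      Tmat[ip, ] <- Tmat[ip, ] / piv
      rhs[ip] <- rhs[ip] / piv
      colv <- Tmat[, jin]
      colv[ip] <- 0
      Tmat <- Tmat - outer(colv, Tmat[ip, ])
      rhs <- rhs - colv * rhs[ip]
      rhs[rhs < 0 & rhs > -1e-9] <- 0
      red <- red - red[jin] * Tmat[ip, ]
      basis[ip] <- jin
      objv <- sum(cost[basis] * rhs)
    }
  }

  # phase 1
  if (n_art > 0) {
    cost1 <- numeric(total_cols)
    cost1[art_cols] <- 1
    ph1 <- run_simplex(Tmat, rhs, basis, cost1, banned = integer(0))
    if (identical(ph1$status, "unbounded")) {
      stop("internal error: phase-1 program unbounded")
    }
    scale <- max(1, max(abs(rhs)))
    if (ph1$objv > 1e-7 * scale) {
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    }
    Tmat <- ph1$Tmat; rhs <- ph1$rhs; basis <- ph1$basis
    # pivot basic artificials (at zero) out where possible
    for (i in which(basis %in% art_cols)) {
      rowv <- Tmat[i, seq_len(n_cols)]
      jnz <- which(abs(rowv) > tol * 10)
      if (length(jnz) > 0) {
        jin <- jnz[1]
        piv <- Tmat[i, jin]
        Tmat[i, ] <- Tmat[i, ] / piv
        rhs[i] <- rhs[i] / piv
        colv <- Tmat[, jin]
        colv[i] <- 0
        Tmat <- Tmat - outer(colv, Tmat[i, ])
        rhs <- rhs - colv * rhs[i]
        rhs[rhs < 0 & rhs > -1e-9] <- 0
        basis[i] <- jin
      }
    }
  }

  # phase 2
  cost2 <- numeric(total_cols)
  cost2[seq_len(n)] <- cc
  ph2 <- run_simplex(Tmat, rhs, basis, cost2, banned = art_cols)
  if (identical(ph2$status, "unbounded")) {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  y <- numeric(total_cols)
  y[ph2$basis] <- ph2$rhs
  x <- y[seq_len(n)] + lb
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}
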