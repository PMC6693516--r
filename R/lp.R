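# Internal linear-programming layer.
#
# All flux optimization in the package reduces to small dense LPs
# (steady-state equalities, bound boxes, a few big-M rows), solved by a
# two-phase dense tableau simplex (Dantzig pricing with a Bland's-rule
# fallback for anti-cycling), plus a depth-first branch-and-bound for the
# binary variables of the flux-activity (iMAT) and transformation (MTA)
# MILPs. Problem sizes are those of curated toy networks (tens of
# variables), for which a dense tableau is entirely adequate; the solver
# is deterministic, which keeps every downstream flux state reproducible.

# Core: minimize c'x subject to A x = b, x >= 0 (standard form; b is made
# non-negative by row flips before phase 1). Returns status, x, value.
#' @keywords internal
#' @noRd
simplex_standard <- function(c_obj, A, b, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # no constraints beyond x >= 0: minimum is at 0 unless a negative cost
    # makes the problem unbounded
    if (any(c_obj < -tol)) return(list(status = "unbounded", x = NULL, value = NA_real_))
    return(list(status = "optimal", x = rep(0, n), value = 0))
  }
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  if (is.null(max_iter)) max_iter <- 200L * (m + n + 10L)
  bland_after <- 10L * (m + n + 10L)

  # Tableau over columns [structural | artificial | rhs]; basis starts on
  # the artificials.
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  run_phase <- function(Tb, basis, cost, n_total, max_iter) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit", Tb = Tb, basis = basis))
      cb <- cost[basis]
      red <- cost[seq_len(n_total)] - as.numeric(cb %*% Tb[, seq_len(n_total), drop = FALSE])
      red[basis] <- 0
      cand <- which(red < -tol)
      if (!length(cand)) return(list(status = "optimal", Tb = Tb, basis = basis))
      j <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])]
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
      ratios <- Tb[pos, n_total + 1L] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol]
      # Bland tie-break: leave the basic variable with the smallest index.
      i <- ties[which.min(basis[ties])]
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      other <- setdiff(seq_len(nrow(Tb)), i)
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
      Tb[, j] <- 0
      Tb[i, j] <- 1
      basis[i] <- j
    }
  }

  # Phase 1: drive artificials to zero.
  cost1 <- c(rep(0, n), rep(1, m), 0)
  ph1 <- run_phase(Tb, basis, cost1, n + m, max_iter)
  if (ph1$status != "optimal") {
    return(list(status = ph1$status, x = NULL, value = NA_real_))
  }
  Tb <- ph1$Tb
  basis <- ph1$basis
  obj1 <- sum(cost1[basis] * Tb[, n + m + 1L])
  if (obj1 > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # Pivot any residual zero-level artificials out of the basis; rows where
  # that is impossible are redundant and dropped.
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] > n) {
      cols <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(cols)) {
        j <- cols[1L]
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv
        other <- setdiff(seq_len(nrow(Tb)), i)
        Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
        Tb[, j] <- 0
        Tb[i, j] <- 1
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  if (!nrow(Tb)) {
    x <- rep(0, n)
    return(list(status = "optimal", x = x, value = sum(c_obj * x)))
  }
  # Phase 2 on structural columns only.
  keep <- c(seq_len(n), n + m + 1L)
  Tb2 <- Tb[, keep, drop = FALSE]
  cost2 <- c(c_obj, 0)
  ph2 <- run_phase(Tb2, basis, cost2, n, max_iter)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  }
  x <- rep(0, n)
  x[ph2$basis] <- ph2$Tb[, n + 1L]
  x[x < 0] <- 0
  list(status = "optimal", x = x, value = sum(c_obj * x))
}

#' @keywords internal
#' @noRd
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = FALSE, n_iter = NULL, eps = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve() requires finite variable bounds", call. = FALSE)
  }
  if (any(lb > ub + 1e-9)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  if (!is.null(A_eq)) A_eq <- matrix(A_eq, ncol = n)
  if (!is.null(A_ub)) A_ub <- matrix(A_ub, ncol = n)

  # Substitute out variables fixed by their bounds; they only shift the
  # right-hand sides.
  fixed <- which(ub - lb <= 1e-12)
  free <- setdiff(seq_len(n), fixed)
  xf <- (lb[fixed] + ub[fixed]) / 2
  if (length(fixed)) {
    if (!is.null(A_eq)) {
      b_eq <- as.numeric(b_eq) - as.numeric(A_eq[, fixed, drop = FALSE] %*% xf)
      A_eq <- A_eq[, free, drop = FALSE]
    }
    if (!is.null(A_ub)) {
      b_ub <- as.numeric(b_ub) - as.numeric(A_ub[, fixed, drop = FALSE] %*% xf)
      A_ub <- A_ub[, free, drop = FALSE]
    }
  }
  # Drop rows that no longer involve any variable.
  if (!is.null(A_eq)) {
    zero <- rowSums(abs(A_eq)) <= 1e-12
    if (any(zero)) {
      if (any(abs(as.numeric(b_eq)[zero]) > 1e-7)) {
        return(list(status = "infeasible", x = NULL, value = NA_real_))
      }
      A_eq <- A_eq[!zero, , drop = FALSE]
      b_eq <- as.numeric(b_eq)[!zero]
    }
    if (!nrow(A_eq)) A_eq <- NULL
  }
  if (!is.null(A_ub)) {
    zero <- rowSums(abs(A_ub)) <= 1e-12
    if (any(zero)) {
      if (any(as.numeric(b_ub)[zero] < -1e-7)) {
        return(list(status = "infeasible", x = NULL, value = NA_real_))
      }
      A_ub <- A_ub[!zero, , drop = FALSE]
      b_ub <- as.numeric(b_ub)[!zero]
    }
    if (!nrow(A_ub)) A_ub <- NULL
  }
  restore <- function(xfree) {
    x <- numeric(n)
    x[fixed] <- xf
    x[free] <- xfree
    x
  }
  if (!length(free)) {
    # Everything is fixed; verify the remaining (variable-free) system.
    x <- restore(numeric(0))
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }

  # Standard form: y = x - lb >= 0; upper bounds and inequality rows get
  # slack variables.
  m_free <- length(free)
  objf <- if (maximize) -obj[free] else obj[free]
  lbf <- lb[free]
  rngf <- ub[free] - lbf
  n_ub_rows <- if (!is.null(A_ub)) nrow(A_ub) else 0L
  n_slack <- m_free + n_ub_rows          # one slack per bound, one per row
  n_tot <- m_free + n_slack
  rows <- list()
  rhs <- numeric(0)
  # y_i + s_i = rng_i
  bound_block <- cbind(diag(m_free), diag(m_free),
                       matrix(0, m_free, n_ub_rows))
  rows[[1L]] <- bound_block
  rhs <- c(rhs, rngf)
  if (!is.null(A_ub)) {
    ub_block <- cbind(A_ub, matrix(0, n_ub_rows, m_free), diag(n_ub_rows))
    rows[[length(rows) + 1L]] <- ub_block
    rhs <- c(rhs, as.numeric(b_ub) - as.numeric(A_ub %*% lbf))
  }
  if (!is.null(A_eq)) {
    eq_block <- cbind(A_eq, matrix(0, nrow(A_eq), n_slack))
    rows[[length(rows) + 1L]] <- eq_block
    rhs <- c(rhs, as.numeric(b_eq) - as.numeric(A_eq %*% lbf))
  }
  A_std <- do.call(rbind, rows)
  c_std <- c(objf, rep(0, n_slack))
  res <- simplex_standard(c_std, A_std, rhs, tol = eps, max_iter = n_iter)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, value = NA_real_))
  }
  xfree <- pmin(pmax(res$x[seq_len(m_free)] + lbf, lbf), ub[free])
  x <- restore(xfree)
  list(status = "optimal", x = x, value = sum(obj * x))
}

# Branch-and-bound over binary variables on top of the LP relaxation.
# `binary_idx` indexes variables restricted to {0,1}; when
# `integer_objective` is TRUE the objective is known to take integer values
# at integral points, which sharpens the pruning bound.
#' @keywords internal
#' @noRd
milp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                       lb, ub, binary_idx = integer(0), maximize = FALSE,
                       integer_objective = FALSE, int_tol = 1e-6,
                       node_limit = 100000L) {
  sense <- if (maximize) 1 else -1
  best <- list(value = -Inf, x = NULL)   # in maximize-equivalent sense
  nodes <- 0L
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) {
      stop("milp_solve(): node limit exceeded", call. = FALSE)
    }
    rel <- lp_solve(obj, A_eq, b_eq, A_ub, b_ub, node$lb, node$ub,
                    maximize = maximize)
    if (rel$status != "optimal") next
    bound <- sense * rel$value
    if (integer_objective) bound <- floor(bound + 1e-7)
    if (bound <= best$value + 1e-9) next
    frac <- abs(rel$x[binary_idx] - round(rel$x[binary_idx]))
    if (!length(binary_idx) || max(frac) <= int_tol) {
      x <- rel$x
      x[binary_idx] <- round(x[binary_idx])
      val <- sense * sum(obj * x)
      if (val > best$value + 1e-9) best <- list(value = val, x = x)
      next
    }
    j <- binary_idx[which.max(frac)]
    xj <- rel$x[j]
    # Dive toward the nearer integer first (pushed last = popped first).
    lo <- node
    lo$ub[j] <- 0
    hi <- node
    hi$lb[j] <- 1
    if (xj >= 0.5) {
      stack <- c(stack, list(lo, hi))
    } else {
      stack <- c(stack, list(hi, lo))
    }
  }
  if (is.null(best$x)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = best$x, value = sense * best$value,
       nodes = nodes)
}

# Feasibility of {A_eq x = b_eq, A_ub x <= b_ub, lb <= x <= ub}; returns a
# feasible point or NULL.
#' @keywords internal
#' @noRd
lp_feasible_point <- function(A_eq = NULL, b_eq = NULL, A_ub = NULL,
                              b_ub = NULL, lb, ub) {
  res <- lp_solve(rep(0, length(lb)), A_eq, b_eq, A_ub, b_ub, lb, ub)
  if (res$status == "optimal") res$x else NULL
}
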