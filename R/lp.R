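# Internal linear-programming layer.
#
# All flux balance problems in this package reduce to
#     max/min  obj' v
#     s.t.     Aeq  v  = beq
#              Aineq v <= bineq
#              lb <= v <= ub
# Inequalities get slack variables, infinite bounds are replaced by a large
# finite cap (so the polytope is always bounded and a true unbounded ray
# shows up as a variable pressed against its cap), and the resulting
# equality-form problem is solved by a two-phase bounded-variable primal
# simplex with Bland's anti-cycling rule. Bland's rule costs speed but
# guarantees termination on the highly degenerate bases that metabolic
# networks produce; the problems here are small, so robustness wins.

# Bounded-variable simplex on  max c'x  s.t.  A x = b,  l <= x <= u (finite).
# Phase 1 introduces one artificial per row (driven to zero), phase 2
# optimizes c with the artificials pinned at zero.
simplex_bounded <- function(A, b, c_obj, l, u, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    x <- ifelse(c_obj > 0, u, l)
    return(list(status = "optimal", x = x, value = sum(c_obj * x)))
  }
  # nonbasic start: each structural variable at the bound nearer zero
  x <- ifelse(abs(l) <= abs(u), l, u)
  resid <- b - drop(A %*% x)
  Aa <- cbind(A, diag(ifelse(resid >= 0, 1, -1), m))
  la <- c(l, rep(0, m)); ua <- c(u, abs(resid))
  xa <- c(x, abs(resid))
  basis <- n + seq_len(m)
  at_upper <- xa >= (la + ua) / 2 & (ua - la) > 0  # start status of nonbasics
  at_upper[basis] <- FALSE
  at_upper[seq_len(n)] <- abs(l) > abs(u)

  run_phase <- function(cc, basis, xa, at_upper, fixed_art) {
    la_ <- la; ua_ <- ua
    if (fixed_art) ua_[n + seq_len(m)] <- 0
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "iteration_limit", basis = basis, xa = xa,
                    at_upper = at_upper))
      B <- Aa[, basis, drop = FALSE]
      lu <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(lu))
        return(list(status = "singular_basis", basis = basis, xa = xa,
                    at_upper = at_upper))
      nonbasic <- setdiff(seq_len(n + m), basis)
      y <- drop(crossprod(lu, cc[basis]))       # y = B^-T c_B
      d <- cc[nonbasic] - drop(y %*% Aa[, nonbasic, drop = FALSE])
      fixed <- (ua_[nonbasic] - la_[nonbasic]) <= tol
      improving <- (!fixed) &
        ((!at_upper[nonbasic] & d > tol) | (at_upper[nonbasic] & d < -tol))
      if (!any(improving))
        return(list(status = "optimal", basis = basis, xa = xa,
                    at_upper = at_upper))
      e <- nonbasic[improving][which.min(nonbasic[improving])]  # Bland
      dir <- if (at_upper[e]) -1 else 1                          # x_e moves by dir*t
      w <- drop(lu %*% Aa[, e])                                  # x_B moves by -dir*w*t
      tmax <- ua_[e] - la_[e]; leaving <- 0L; leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        bi <- basis[i]
        delta <- -dir * w[i]
        if (delta < -tol) {
          t_i <- (la_[bi] - xa[bi]) / delta
        } else if (delta > tol) {
          t_i <- (ua_[bi] - xa[bi]) / delta
        } else next
        t_i <- max(t_i, 0)
        # Bland tie-break: strictly smaller ratio, or equal ratio with a
        # smaller variable index
        if (t_i < tmax - tol ||
            (t_i < tmax + tol && leaving > 0L && bi < basis[leaving])) {
          tmax <- t_i; leaving <- i; leave_to_upper <- delta > tol
        }
      }
      if (!is.finite(tmax))
        return(list(status = "unbounded", basis = basis, xa = xa,
                    at_upper = at_upper))
      # apply the step
      xa[e] <- xa[e] + dir * tmax
      xa[basis] <- xa[basis] - dir * w * tmax
      if (leaving == 0L) {
        at_upper[e] <- !at_upper[e]          # bound-to-bound flip
      } else {
        lv <- basis[leaving]
        xa[lv] <- if (leave_to_upper) ua_[lv] else la_[lv]  # snap exactly
        at_upper[lv] <- leave_to_upper
        basis[leaving] <- e
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, xa, at_upper, fixed_art = FALSE)
  if (p1$status != "optimal")
    return(list(status = paste0("phase1_", p1$status), x = NULL, value = NA_real_))
  if (sum(p1$xa[n + seq_len(m)]) > 1e-6)
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  # phase 2: artificials pinned at zero
  c2 <- c(c_obj, rep(0, m))
  xa <- p1$xa; xa[n + seq_len(m)] <- pmin(xa[n + seq_len(m)], 0)
  p2 <- run_phase(c2, p1$basis, xa, p1$at_upper, fixed_art = TRUE)
  if (p2$status != "optimal")
    return(list(status = paste0("phase2_", p2$status), x = NULL, value = NA_real_))
  x <- p2$xa[seq_len(n)]
  list(status = "optimal", x = x, value = sum(c_obj * x))
}

#' @noRd
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                     lb, ub, maximize = TRUE, big = 1e9, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", solution = NULL, value = NA_real_,
                reason = "inconsistent bounds"))
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, n); beq <- numeric(0) }
  if (is.null(Aineq)) { Aineq <- matrix(0, 0, n); bineq <- numeric(0) }
  Aeq <- as.matrix(Aeq); Aineq <- as.matrix(Aineq)

  lb_eff <- ifelse(is.finite(lb), lb, -big)
  ub_eff <- ifelse(is.finite(ub), ub, big)
  capped <- !is.finite(ub) | !is.finite(lb)

  ns <- nrow(Aineq)   # one slack per inequality
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), ns)),
             cbind(Aineq, diag(1, ns)))
  bvec <- c(beq, bineq)
  l_all <- c(lb_eff, rep(0, ns))
  u_all <- c(ub_eff, rep(big, ns))
  c_all <- c(if (maximize) obj else -obj, rep(0, ns))

  res <- simplex_bounded(A, bvec, c_all, l_all, u_all, tol = tol)
  if (res$status == "infeasible")
    return(list(status = "infeasible", solution = NULL, value = NA_real_))
  if (res$status != "optimal")
    return(list(status = "solver_error", solution = NULL, value = NA_real_,
                reason = res$status))
  v <- res$x[seq_len(n)]
  value <- sum(obj * v)
  at_cap <- capped & (abs(v) >= 0.5 * big)
  if (any(at_cap))
    return(list(status = "unbounded", solution = v, value = value,
                unbounded_index = which(at_cap)))
  list(status = "optimal", solution = v, value = value)
}
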