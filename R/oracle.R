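# Brute-force LP cross-check.
#
# For a bounded LP max c'v s.t. S v = 0, lb <= v <= ub, every vertex of the
# feasible polytope fixes at least n - rank(S) variables at one of their
# bounds; the remaining square system is solved directly. Enumerating all
# such fixings and keeping the feasible ones visits every vertex, so the
# maximum over them is the LP optimum. Exponential, intended only for tiny
# networks (<= ~12 reactions); kept deliberately independent of the simplex
# path used by solve_fba().

#' Vertex-enumeration LP oracle
#'
#' @param S stoichiometry matrix (metabolites x reactions).
#' @param obj objective vector.
#' @param lb,ub bound vectors (finite).
#' @param tol feasibility tolerance on bounds and balances.
#' @return list with `value` (max objective over vertices, `-Inf` when no
#'   feasible vertex exists) and `vertex` (an attaining flux vector).
#' @export
lp_vertex_optimum <- function(S, obj, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), length(obj) == n)
  r <- if (nrow(S) == 0L) 0L else qr(S)$rank
  nfix <- n - r
  best <- -Inf; best_v <- NULL
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (nrow(S) > 0L && max(abs(S %*% v)) > tol * max(1, max(abs(v)))) return()
    val <- sum(obj * v)
    if (val > best) { best <<- val; best_v <<- v }
  }
  if (nfix == 0L) {
    # unique solution of S v = 0 given full column rank: v = 0
    consider(rep(0, n))
  } else {
    sets <- utils::combn(n, nfix)
    for (ci in seq_len(ncol(sets))) {
      fix <- sets[, ci]
      free <- setdiff(seq_len(n), fix)
      Sb <- S[, free, drop = FALSE]
      qrSb <- qr(Sb)
      if (qrSb$rank < length(free)) next
      # each fixed variable at its lower or upper bound
      for (mask in 0:(2^nfix - 1)) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(nfix) - 1L)))
        vf <- ifelse(at_ub, ub[fix], lb[fix])
        rhs <- -S[, fix, drop = FALSE] %*% vf
        sol <- tryCatch(qr.coef(qrSb, rhs), error = function(e) NULL)
        if (is.null(sol) || anyNA(sol)) next
        # solution must actually satisfy the (possibly overdetermined) system
        v <- numeric(n); v[fix] <- vf; v[free] <- sol
        consider(v)
      }
    }
  }
  list(value = best, vertex = best_v)
}

#' Vertex oracle applied to a metabolic model
#'
#' Convenience wrapper running [lp_vertex_optimum()] on a model's
#' stoichiometric matrix, bounds, and objective.
#'
#' @param model a `metabolic_model` (finite bounds, small).
#' @param objective named objective weights; defaults to the model objective.
#' @return as [lp_vertex_optimum()].
#' @export
fba_vertex_optimum <- function(model, objective = model$objective) {
  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  obj <- numeric(ncol(S))
  obj[match(names(objective), colnames(S))] <- objective
  lp_vertex_optimum(S, obj, model$reactions$lower_bound,
                    model$reactions$upper_bound)
}

#' Reactions reachable from open exchange inputs
#'
#' Graph-reachability screen: starting from metabolites that can enter the
#' system (exchange reactions whose lower bound is negative), repeatedly
#' marks reactions whose substrates are all producible and adds their
#' products. Reactions never marked cannot carry forward flux; for networks
#' of irreversible reactions this is an independent oracle for the zero-flux
#' screen.
#'
#' @param model a `metabolic_model`.
#' @return character vector of unreachable (structurally blocked) reaction ids.
#' @export
blocked_reactions <- function(model) {
  rxn <- model$reactions
  producible <- character(0)
  for (i in which(rxn$kind == "exchange")) {
    s <- model$stoichiometry[[rxn$id[i]]]
    if (rxn$lower_bound[i] < 0) producible <- c(producible, names(s))
  }
  active <- rep(FALSE, nrow(rxn))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(rxn))) {
      if (active[i] || rxn$kind[i] == "exchange") next
      if (rxn$upper_bound[i] <= 0) next
      s <- model$stoichiometry[[rxn$id[i]]]
      subs <- names(s)[s < 0]
      if (all(subs %in% producible)) {
        active[i] <- TRUE
        producible <- unique(c(producible, names(s)[s > 0]))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rxn$id[!active & rxn$kind != "exchange"]
}
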