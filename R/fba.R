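#' Flux balance analysis
#'
#' Maximizes `objective' v` subject to steady-state mass balance `S v = 0`
#' and the model's flux bounds (optionally overridden per reaction). For the
#' usual biomass objective the optimum is the specific growth rate mu (1/h).
#' The LP optimum is unique even when the optimal flux vector is not; use
#' [parsimonious_flux()] to resolve degenerate optima reproducibly.
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector of reaction weights; defaults to the
#'   model objective.
#' @param bound_overrides named list: reaction id -> `c(lower, upper)`,
#'   replacing that reaction's bounds for this solve only.
#' @param tol_feas LP pivoting tolerance.
#' @return a `flux_state`: list with `fluxes` (named vector, mmol/gDW/h;
#'   biomass in 1/h), `objective_value`, and `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`; for unbounded problems the offending
#'   reaction is named in `unbounded_reaction`).
#' @export
solve_fba <- function(model, objective = model$objective,
                      bound_overrides = NULL, tol_feas = 1e-10) {
  validate_model(model)
  rxn_ids <- model$reactions$id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(bound_overrides)) {
    unknown <- setdiff(names(bound_overrides), rxn_ids)
    if (length(unknown))
      stop("bound_overrides name reactions absent from the model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (rid in names(bound_overrides)) {
      b <- bound_overrides[[rid]]
      if (length(b) != 2L || b[1] > b[2])
        stop("invalid bound override for '", rid, "'", call. = FALSE)
      j <- match(rid, rxn_ids)
      lb[j] <- b[1]; ub[j] <- b[2]
    }
  }
  if (length(objective) == 0L)
    stop("no objective defined", call. = FALSE)
  if (!all(names(objective) %in% rxn_ids))
    stop("objective names reactions absent from the model", call. = FALSE)
  obj <- numeric(length(rxn_ids))
  obj[match(names(objective), rxn_ids)] <- objective

  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  res <- lp_solve(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                  maximize = TRUE, tol = tol_feas)
  fs <- list(fluxes = NULL, objective_value = NA_real_, status = res$status,
             resolution_method = "fba")
  if (res$status == "optimal") {
    fs$fluxes <- stats::setNames(res$solution, rxn_ids)
    fs$objective_value <- res$value
  } else if (res$status == "unbounded") {
    fs$unbounded_reaction <- rxn_ids[res$unbounded_index]
  } else if (res$status == "solver_error") {
    stop("LP solver failure: ", res$reason, call. = FALSE)
  }
  class(fs) <- "flux_state"
  fs
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("flux_state [%s]: objective %s (%s)\n", x$status,
              format(x$objective_value), x$resolution_method))
  invisible(x)
}

#' Mass-balance residual of a flux state
#'
#' @param model a `metabolic_model`.
#' @param flux_state a `flux_state` (or named flux vector).
#' @return `max_i |(S v)_i|`.
#' @export
mass_balance_residual <- function(model, flux_state) {
  v <- if (inherits(flux_state, "flux_state")) flux_state$fluxes else flux_state
  S <- stoichiometric_matrix(model)
  if (nrow(S) == 0L || length(v) == 0L) return(0)
  max(abs(as.numeric(S %*% v[colnames(S)])))
}

#' Parsimonious resolution of degenerate optima
#'
#' Among flux vectors attaining the previously computed optimum (within
#' `tol_opt`), returns the one minimizing total absolute flux `sum(|v|)`.
#' This removes futile cycles and picks a reproducible representative of the
#' optimal face, which matters when flux profiles are compared to expression
#' profiles downstream.
#'
#' @param model a `metabolic_model`.
#' @param objective named objective weights (as in [solve_fba()]).
#' @param optimum the LP optimum returned by a prior [solve_fba()].
#' @param bound_overrides as in [solve_fba()].
#' @param tol_opt slack allowed on the objective floor. The optimum is first
#'   re-witnessed inside the 1-norm problem itself, so the floor is feasible
#'   by construction and the slack can stay tiny; a tight slack matters when
#'   some objective weights are small (a loose floor would let the
#'   low-weighted fluxes drift by `tol_opt / weight`).
#' @return a `flux_state` with `resolution_method = "parsimonious"` and
#'   `objective_value` equal to `objective' v` of the returned vector.
#' @export
parsimonious_flux <- function(model, objective = model$objective, optimum,
                              bound_overrides = NULL, tol_opt = 1e-12) {
  validate_model(model)
  rxn_ids <- model$reactions$id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(bound_overrides)) {
    for (rid in names(bound_overrides)) {
      j <- match(rid, rxn_ids)
      lb[j] <- bound_overrides[[rid]][1]; ub[j] <- bound_overrides[[rid]][2]
    }
  }
  obj <- numeric(length(rxn_ids))
  obj[match(names(objective), rxn_ids)] <- objective
  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  n <- length(rxn_ids)

  # v = p - q with p, q >= 0; |v| = p + q at the optimum of the 1-norm
  big <- 1e9
  ub_p <- pmax(ifelse(is.finite(ub), ub, big), 0)
  ub_q <- pmax(ifelse(is.finite(lb), -lb, big), 0)
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  # bounds not representable by the split caps (strictly positive lb / negative ub)
  Ain <- matrix(0, 0, 2L * n); bin <- numeric(0)
  for (j in which(lb > 0)) {
    row <- numeric(2L * n); row[j] <- -1; row[n + j] <- 1
    Ain <- rbind(Ain, row); bin <- c(bin, -lb[j])
  }
  for (j in which(ub < 0)) {
    row <- numeric(2L * n); row[j] <- 1; row[n + j] <- -1
    Ain <- rbind(Ain, row); bin <- c(bin, ub[j])
  }

  # re-witness the optimum within this problem's own constraint set and
  # arithmetic, so the objective floor below is attainable by construction
  wit <- lp_solve(c(obj, -obj), Aeq = Aeq, beq = beq,
                  Aineq = if (nrow(Ain)) Ain else NULL,
                  bineq = if (nrow(Ain)) bin else NULL,
                  lb = rep(0, 2L * n), ub = c(ub_p, ub_q), maximize = TRUE)
  if (wit$status != "optimal")
    stop("parsimonious resolution: objective re-maximization failed (status: ",
         wit$status, ")", call. = FALSE)
  if (optimum - tol_opt > wit$value + 1e-7)
    stop("parsimonious resolution infeasible at the fixed optimum ",
         "(attainable ", format(wit$value, digits = 12), " < floor ",
         format(optimum - tol_opt, digits = 12), "); consider relaxing tol_opt",
         call. = FALSE)
  floor_val <- min(optimum, wit$value) - tol_opt
  # objective floor: obj'(p - q) >= floor  <=>  -obj'(p-q) <= -floor
  Ain <- rbind(Ain, c(-obj, obj)); bin <- c(bin, -floor_val)

  res <- lp_solve(rep(1, 2L * n), Aeq = Aeq, beq = beq,
                  Aineq = Ain, bineq = bin,
                  lb = rep(0, 2L * n), ub = c(ub_p, ub_q), maximize = FALSE)
  if (res$status != "optimal")
    stop("parsimonious resolution infeasible at the fixed optimum; ",
         "consider relaxing tol_opt (status: ", res$status, ")", call. = FALSE)
  v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
  fs <- list(fluxes = stats::setNames(v, rxn_ids),
             objective_value = sum(obj * v),
             status = "optimal",
             total_abs_flux = sum(abs(v)),
             resolution_method = "parsimonious")
  class(fs) <- "flux_state"
  fs
}

#' Molecular weight from a chemical formula
#'
#' @param formula e.g. `"C32H26O14"`.
#' @return weight in g/mol.
#' @export
formula_weight <- function(formula) {
  masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974,
              S = 32.06, Fe = 55.845, Mg = 24.305, Ca = 40.078, Na = 22.99,
              K = 39.098, Cl = 35.45)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    cnt <- gsub("[^0-9]", "", tk)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!el %in% names(masses))
      stop("unknown element '", el, "' in formula '", formula, "'", call. = FALSE)
    total <- total + masses[[el]] * cnt
  }
  total
}

# micrograms per gDW per hour -> mmol per gDW per hour
ug_to_mmol <- function(rate_ug, mw) rate_ug / (1000 * mw)

#' Chemostat validation panel
#'
#' Applies a set of steady-state chemostat conditions (glucose and oxygen
#' uptake, carbon dioxide and actinorhodin production) to the model's
#' exchange reactions and maximizes biomass, one solve per condition. At
#' steady state the chemostat dilution rate D equals the specific growth
#' rate, so the predicted optimum is directly comparable to the observed D.
#'
#' Uptakes are applied as capacity bounds (lower bound `-rate`); measured
#' productions are by default pinned as equalities (`lower = upper = rate`),
#' since they are observations rather than capacities; set
#' `production_equality = FALSE` to treat them as caps instead.
#'
#' @param model a `metabolic_model`.
#' @param conditions data.frame with columns `glucose_uptake`, `o2_uptake`
#'   (mmol/gDW/h), `co2_production` (mmol/gDW/h), `actinorhodin_production`
#'   (ug/gDW/h) and optionally `observed_dilution_rate` (1/h).
#' @param exchange_map named character vector mapping
#'   `glucose`/`o2`/`co2`/`actinorhodin` to exchange reaction ids.
#' @param actinorhodin_mw molecular weight (g/mol) used to convert ug to
#'   mmol; default derived from the model's actinorhodin species formula
#'   when available, else the actinorhodin formula C32H26O14.
#' @param production_equality pin measured productions as equalities.
#' @param parsimonious also compute the parsimonious flux vector per solve.
#' @return data.frame: the input conditions plus `predicted_mu` and `status`,
#'   in input order, with the flux states in attribute `"flux_states"`.
#' @export
chemostat_panel <- function(model, conditions, exchange_map,
                            actinorhodin_mw = NULL,
                            production_equality = TRUE,
                            parsimonious = FALSE) {
  validate_model(model)
  needed <- c("glucose", "o2", "co2", "actinorhodin")
  missing_map <- setdiff(needed, names(exchange_map))
  if (length(missing_map))
    stop("exchange_map lacks entries for: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(unname(exchange_map[needed]), model$reactions$id)
  if (length(absent))
    stop("model lacks exchange reactions for constrained metabolites: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (is.null(actinorhodin_mw)) {
    ex <- exchange_map[["actinorhodin"]]
    met <- names(model$stoichiometry[[ex]])
    f <- model$metabolites$formula[match(met, model$metabolites$id)]
    actinorhodin_mw <- if (length(f) == 1L && !is.na(f) && nzchar(f))
      formula_weight(f) else formula_weight("C32H26O14")
  }

  conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 0L) {
    conditions$predicted_mu <- numeric(0)
    conditions$status <- character(0)
    return(conditions)
  }
  rates <- c("glucose_uptake", "o2_uptake", "co2_production",
             "actinorhodin_production")
  for (cc in rates) {
    if (!cc %in% names(conditions))
      stop("conditions table lacks column '", cc, "'", call. = FALSE)
    if (any(conditions[[cc]] < 0))
      stop("negative rate in column '", cc, "' (rates are magnitudes; ",
           "signs are applied internally)", call. = FALSE)
  }

  mu <- numeric(nrow(conditions)); status <- character(nrow(conditions))
  states <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    act_mmol <- ug_to_mmol(conditions$actinorhodin_production[i], actinorhodin_mw)
    ov <- list()
    ov[[exchange_map[["glucose"]]]] <- c(-conditions$glucose_uptake[i], 0)
    ov[[exchange_map[["o2"]]]] <- c(-conditions$o2_uptake[i], 0)
    co2 <- conditions$co2_production[i]
    ov[[exchange_map[["co2"]]]] <- if (production_equality) c(co2, co2) else c(0, co2)
    ov[[exchange_map[["actinorhodin"]]]] <-
      if (production_equality) c(act_mmol, act_mmol) else c(0, act_mmol)
    fs <- solve_fba(model, bound_overrides = ov)
    if (parsimonious && fs$status == "optimal")
      fs <- parsimonious_flux(model, optimum = fs$objective_value,
                              bound_overrides = ov)
    mu[i] <- fs$objective_value
    status[i] <- fs$status
    states[[i]] <- fs
  }
  out <- conditions
  out$predicted_mu <- mu
  out$status <- status
  attr(out, "flux_states") <- states
  out
}

#' Read a chemostat condition table
#'
#' Tab-separated, one row per condition; the column headers of the published
#' layout (`Glucose (mmol/g.h)`, `O2 (mmol/g.h)`, `CO2 (mmol/g.h)`,
#' `Actinorhodin (ug/g.h)`, `Observed dilution rate D(/h)`) or the canonical
#' names used by [chemostat_panel()] are both accepted.
#'
#' @param path a TSV file.
#' @return data.frame in [chemostat_panel()]'s canonical column naming.
#' @export
read_chemostat_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  canon <- c("glucose" = "glucose_uptake", "o2" = "o2_uptake",
             "co2" = "co2_production", "actinorhodin" = "actinorhodin_production",
             "dilution" = "observed_dilution_rate", "observed" = "observed_dilution_rate")
  nm <- names(df)
  low <- tolower(nm)
  for (key in names(canon)) {
    hit <- which(startsWith(low, key) | grepl(key, low))
    if (length(hit)) nm[hit[1]] <- canon[[key]]
  }
  names(df) <- nm
  df
}
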