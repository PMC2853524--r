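#' Time-varying constraint schedule
#'
#' Holds the dynamic input function of a fermentation: per-time exchange
#' bounds for measured nutrient uptakes, per-time antibiotic production
#' rates, and the switch time at which the culture transitions from
#' growth-directed to antibiotic-directed metabolism (phosphate depletion,
#' by default at 34 h).
#'
#' @param times strictly increasing sampling times (h).
#' @param exchange_bounds named list: exchange reaction id -> length(times) x 2
#'   matrix of (lower, upper) bounds (mmol/gDW/h).
#' @param antibiotic_rates named list: antibiotic exchange reaction id ->
#'   per-time production rate (ug/gDW/h); must be 0 before `switch_time`.
#' @param switch_time hours.
#' @return a `constraint_schedule`.
#' @export
constraint_schedule <- function(times, exchange_bounds = list(),
                                antibiotic_rates = list(), switch_time = 34) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  for (rid in names(exchange_bounds)) {
    b <- exchange_bounds[[rid]]
    if (!is.matrix(b) || nrow(b) != length(times) || ncol(b) != 2L)
      stop("exchange_bounds[['", rid, "']] must be a length(times) x 2 matrix",
           call. = FALSE)
    if (any(b[, 1] > b[, 2]))
      stop("lower > upper bound in schedule for '", rid, "'", call. = FALSE)
  }
  for (rid in names(antibiotic_rates)) {
    r <- antibiotic_rates[[rid]]
    if (length(r) != length(times))
      stop("antibiotic_rates[['", rid, "']] must align with times", call. = FALSE)
    if (any(r[times < switch_time] > 0))
      stop("antibiotic rates must be zero before the switch time", call. = FALSE)
  }
  structure(list(times = times, exchange_bounds = exchange_bounds,
                 antibiotic_rates = antibiotic_rates,
                 switch_time = switch_time),
            class = "constraint_schedule")
}

#' Build a constraint schedule from a measurement table
#'
#' Turns time-stamped nutrient uptake and antibiotic production measurements
#' into a [constraint_schedule()]. Uptake columns become exchange lower
#' bounds `-rate` (upper bound 0, i.e. uptake only); a measured rate of 0 is
#' a hard zero bound, encoding depletion. Production columns (ug/gDW/h)
#' become antibiotic rate tracks. Rates at unmeasured times are filled by
#' linear interpolation when the schedule is queried; no extrapolation
#' beyond the measured window.
#'
#' @param measurements data.frame with a `time_h` column plus one column per
#'   measured rate (all magnitudes, nonnegative).
#' @param uptake_map named character vector: measurement column -> exchange
#'   reaction id, for nutrient uptakes.
#' @param production_map named character vector: measurement column ->
#'   antibiotic exchange reaction id.
#' @param switch_time hours (default 34).
#' @return a `constraint_schedule` on the measured time grid.
#' @export
build_schedule <- function(measurements, uptake_map,
                           production_map = character(0), switch_time = 34) {
  measurements <- as.data.frame(measurements)
  if (!"time_h" %in% names(measurements))
    stop("measurements must have a 'time_h' column", call. = FALSE)
  if (anyDuplicated(measurements$time_h))
    stop("duplicate time stamps in measurements: ",
         paste(unique(measurements$time_h[duplicated(measurements$time_h)]),
               collapse = ", "), call. = FALSE)
  o <- order(measurements$time_h)
  measurements <- measurements[o, , drop = FALSE]
  times <- measurements$time_h
  for (cc in c(names(uptake_map), names(production_map))) {
    if (!cc %in% names(measurements))
      stop("measurements lack column '", cc, "'", call. = FALSE)
    bad <- which(measurements[[cc]] < 0)
    if (length(bad))
      stop("negative measured rate at column '", cc, "', row ", bad[1],
           " (time ", times[bad[1]], " h)", call. = FALSE)
  }
  eb <- list()
  for (cc in names(uptake_map))
    eb[[uptake_map[[cc]]]] <- cbind(lower = -measurements[[cc]], upper = 0)
  ar <- list()
  for (cc in names(production_map))
    ar[[production_map[[cc]]]] <- measurements[[cc]]
  constraint_schedule(times, eb, ar, switch_time = switch_time)
}

# linear interpolation of schedule tracks; strict range check
schedule_index <- function(schedule, t) {
  if (t < min(schedule$times) - 1e-9 || t > max(schedule$times) + 1e-9)
    stop("time ", t, " h outside the schedule range [",
         min(schedule$times), ", ", max(schedule$times), "]", call. = FALSE)
}

#' Exchange bounds of a schedule at a time point
#'
#' @param schedule a `constraint_schedule`.
#' @param t hours, within the schedule range.
#' @return named list: reaction id -> `c(lower, upper)`, linearly
#'   interpolated between measured times.
#' @export
schedule_bounds_at <- function(schedule, t) {
  schedule_index(schedule, t)
  out <- list()
  for (rid in names(schedule$exchange_bounds)) {
    b <- schedule$exchange_bounds[[rid]]
    out[[rid]] <- c(stats::approx(schedule$times, b[, 1], xout = t)$y,
                    stats::approx(schedule$times, b[, 2], xout = t)$y)
  }
  out
}

#' Antibiotic production rates at a time point
#'
#' @inheritParams schedule_bounds_at
#' @return named numeric vector of rates (ug/gDW/h), 0 before the switch.
#' @export
antibiotic_rates_at <- function(schedule, t) {
  schedule_index(schedule, t)
  vapply(schedule$antibiotic_rates, function(r)
    stats::approx(schedule$times, r, xout = t)$y, numeric(1))
}

#' Dynamic objective at a time point
#'
#' Before the switch time the objective is pure biomass. From the switch
#' time on, the biomass composition is shifted toward antibiotics: each
#' antibiotic exchange receives a weight proportional to its measured
#' production rate at `t`, converted from ug/gDW/h to mmol/gDW/h via the
#' species' molecular weight and scaled by `weight_scale` (the
#' proportionality constant linking observed production to objective
#' weight; dimensionless, default 1).
#'
#' @param model a `metabolic_model`.
#' @param schedule a `constraint_schedule`.
#' @param t hours within the schedule range.
#' @param biomass_id biomass reaction id; default: the model objective.
#' @param weight_scale scaling applied to the molar antibiotic rates.
#' @param antibiotic_mw named vector of molecular weights (g/mol) per
#'   antibiotic exchange id; defaults derived from species formulas.
#' @return named numeric objective weights (an objective spec usable by
#'   [solve_fba()]).
#' @export
objective_at <- function(model, schedule, t, biomass_id = NULL,
                         weight_scale = 1, antibiotic_mw = NULL) {
  schedule_index(schedule, t)
  if (is.null(biomass_id)) {
    if (!length(model$objective)) stop("model has no objective", call. = FALSE)
    biomass_id <- names(model$objective)[1]
  }
  w <- stats::setNames(1, biomass_id)
  if (t < schedule$switch_time) return(w)
  rates <- antibiotic_rates_at(schedule, t)
  for (rid in names(rates)) {
    if (rates[[rid]] <= 0) next
    mw <- if (!is.null(antibiotic_mw) && rid %in% names(antibiotic_mw)) {
      antibiotic_mw[[rid]]
    } else {
      met <- names(model$stoichiometry[[rid]])
      f <- model$metabolites$formula[match(met, model$metabolites$id)]
      if (length(f) == 1L && !is.na(f) && nzchar(f)) formula_weight(f)
      else formula_weight("C32H26O14")
    }
    w[rid] <- ug_to_mmol(rates[[rid]], mw) * weight_scale
  }
  w
}

#' Time-resolved flux balance analysis
#'
#' Treats each time point as an independent steady state: applies the
#' schedule's interpolated exchange bounds, builds the dynamic objective
#' ([objective_at()]; or, in `"forced"` mode, keeps the pure biomass
#' objective and pins the antibiotic exchange fluxes to the measured molar
#' rates), solves the FBA problem, and (by default) resolves degenerate
#' optima parsimoniously. Infeasible time points are recorded in the status
#' vector, never silently dropped.
#'
#' @param model a `metabolic_model`.
#' @param schedule a `constraint_schedule` whose exchange ids are all in the
#'   model.
#' @param times solve times; defaults to the schedule's grid.
#' @param objective_mode `"weighted"` (antibiotics enter the objective) or
#'   `"forced"` (antibiotic secretion pinned, biomass maximized).
#' @param parsimonious resolve each optimum with [parsimonious_flux()].
#' @param weight_scale,antibiotic_mw passed to [objective_at()].
#' @return a `flux_time_series`: list with `times`, `flux_matrix`
#'   (reactions x times; NA columns where infeasible), `growth_curve`
#'   (biomass flux, 1/h), `objective_values`, `status`, and
#'   `resolution_method`.
#' @export
run_dynamic_fba <- function(model, schedule, times = schedule$times,
                            objective_mode = c("weighted", "forced"),
                            parsimonious = TRUE, weight_scale = 1,
                            antibiotic_mw = NULL) {
  objective_mode <- match.arg(objective_mode)
  validate_model(model)
  sched_rxns <- c(names(schedule$exchange_bounds), names(schedule$antibiotic_rates))
  absent <- setdiff(sched_rxns, model$reactions$id)
  if (length(absent))
    stop("model lacks scheduled exchange reactions: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!length(model$objective))
    stop("model has no biomass objective", call. = FALSE)
  biomass_id <- names(model$objective)[1]

  rxn_ids <- model$reactions$id
  fm <- matrix(NA_real_, nrow = length(rxn_ids), ncol = length(times),
               dimnames = list(rxn_ids, paste0("t", times)))
  status <- character(length(times))
  objv <- rep(NA_real_, length(times))

  for (k in seq_along(times)) {
    t <- times[k]
    ov <- schedule_bounds_at(schedule, t)
    if (objective_mode == "forced") {
      obj <- stats::setNames(1, biomass_id)
      rates <- antibiotic_rates_at(schedule, t)
      for (rid in names(rates)) {
        mw <- if (!is.null(antibiotic_mw) && rid %in% names(antibiotic_mw))
          antibiotic_mw[[rid]] else formula_weight("C32H26O14")
        mmol <- ug_to_mmol(rates[[rid]], mw)
        ov[[rid]] <- c(mmol, mmol)
      }
    } else {
      obj <- objective_at(model, schedule, t, biomass_id = biomass_id,
                          weight_scale = weight_scale,
                          antibiotic_mw = antibiotic_mw)
    }
    fs <- solve_fba(model, objective = obj, bound_overrides = ov)
    if (fs$status == "optimal" && parsimonious)
      fs <- parsimonious_flux(model, objective = obj,
                              optimum = fs$objective_value,
                              bound_overrides = ov)
    status[k] <- fs$status
    if (fs$status == "optimal") {
      fm[, k] <- fs$fluxes[rxn_ids]
      objv[k] <- fs$objective_value
    }
  }
  structure(list(times = times, flux_matrix = fm,
                 growth_curve = stats::setNames(fm[biomass_id, ], paste0("t", times)),
                 objective_values = objv, status = status,
                 resolution_method = if (parsimonious) "parsimonious" else "fba"),
            class = "flux_time_series")
}

#' @export
print.flux_time_series <- function(x, ...) {
  cat(sprintf("flux_time_series: %d reactions x %d times (%s), mu range [%s, %s]\n",
              nrow(x$flux_matrix), length(x$times), x$resolution_method,
              format(min(x$growth_curve, na.rm = TRUE), digits = 4),
              format(max(x$growth_curve, na.rm = TRUE), digits = 4)))
  invisible(x)
}
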