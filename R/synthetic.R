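# Synthetic fixtures.
#
# The generator emulates the structure of a phosphate-limited Streptomyces
# fermentation study: a toy metabolic network with a glucose (carbon) stream,
# a phosphate stream, an antibiotic secretion branch, a maintenance drain and
# a structurally blocked pathway; a depletion-style constraint schedule
# (phosphate exhausted at the switch time, antibiotic production ramping up
# afterwards); and expression profiles that are noisy affine transforms of
# the predicted flux profiles with injected anticorrelated, constant-flux,
# unexpressed and zero-flux genes. Optima and flux distributions of the toy
# network have closed forms, recorded alongside, so every pipeline stage can
# be checked against ground truth.

#' Specification for the synthetic study
#'
#' @param n_chain_length number of reactions in the carbon backbone (>= 1).
#' @param n_branches number of parallel carbon branches feeding biomass;
#'   branch j is a sub-chain of j reactions, so parsimonious resolution
#'   fills short branches first and the flux split is deterministic.
#' @param n_genes total genes distributed over the gene-bearing reactions.
#' @param times sampling grid in hours; default hourly 20-44 h then
#'   two-hourly 46-60 h, the usual fermentation sampling design.
#' @param noise_sd Gaussian noise sd on log2 expression (profiles are
#'   variance-standardized before the affine map).
#' @param fractions named vector with entries `correlated`, `anticorrelated`,
#'   `constant_flux`, `unexpressed`, each in \[0,1\], summing to at most 1.
#'   Anticorrelated / unexpressed counts are drawn from the dynamic-flux
#'   genes; `constant_flux` genes sit on the maintenance reaction; the
#'   remaining dynamic genes are faithful (correlated).
#' @param seed integer; fixed seed gives byte-identical outputs.
#' @param depletion_times named vector, nutrient -> hour at which its uptake
#'   reaches zero (linear ramp from the initial rate). Recognised nutrients:
#'   `phosphate`, `glucose`.
#' @param switch_time hours; antibiotic production is 0 before this.
#' @param glucose_rate0,glucose_rate_end glucose uptake (mmol/gDW/h) at the
#'   grid start/end (ignored when glucose is in `depletion_times`).
#' @param phosphate_rate0 initial phosphate uptake (mmol/gDW/h).
#' @param o2_rate fixed oxygen uptake capacity (mmol/gDW/h; kept slack).
#' @param act_rate_max antibiotic production rate (ug/gDW/h) reached at the
#'   end of the grid.
#' @param maintenance fixed maintenance drain (mmol/gDW/h).
#' @param biomass_demand carbon precursor units consumed per unit biomass.
#' @param phosphate_demand phosphate units consumed per unit biomass.
#' @param branch_caps capacities of the carbon branches (mmol/gDW/h);
#'   `NULL` draws them uniformly from \[2, 6\] under the seed.
#' @param essential_shift log2 expression offset added to genes on
#'   always-active reactions, emulating the higher expression of essential
#'   genes.
#' @param n_controls negative-control probes added to the expression matrix.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chain_length = 4, n_branches = 2, n_genes = 200,
                           times = c(20:44, seq(46, 60, by = 2)),
                           noise_sd = 0.1,
                           fractions = c(correlated = 0.75, anticorrelated = 0.10,
                                         constant_flux = 0.05, unexpressed = 0.05),
                           seed = 1L,
                           depletion_times = c(phosphate = 34),
                           switch_time = 34,
                           glucose_rate0 = 10, glucose_rate_end = 4,
                           phosphate_rate0 = 5, o2_rate = 50,
                           act_rate_max = 200, maintenance = 0.1,
                           biomass_demand = 1, phosphate_demand = 1,
                           branch_caps = NULL, essential_shift = 0.6,
                           n_controls = 10) {
  sp <- mget(names(formals()))
  need <- c("correlated", "anticorrelated", "constant_flux", "unexpressed")
  if (!all(need %in% names(fractions)))
    stop("fractions must name ", paste(need, collapse = ", "), call. = FALSE)
  if (any(fractions < 0) || any(fractions > 1) || sum(fractions[need]) > 1 + 1e-12)
    stop("fractions must lie in [0,1] and sum to at most 1", call. = FALSE)
  if (n_chain_length < 1L) stop("chain length must be at least 1", call. = FALSE)
  if (n_branches < 1L) stop("need at least one branch", call. = FALSE)
  if (any(depletion_times < min(times)))
    stop("depletion before the start of the time grid", call. = FALSE)
  structure(sp, class = "synthetic_spec")
}

#' Toy metabolic model with analytically known optima
#'
#' Builds a small irreversible network: glucose is taken up and oxidized
#' along a linear backbone (consuming oxygen, releasing carbon dioxide),
#' then routed through parallel capacity-limited branches into a biomass
#' precursor; phosphate is taken up independently; biomass consumes both
#' streams in fixed proportions (its flux is the growth rate mu); an
#' antibiotic branch secretes surplus carbon; a maintenance reaction drains
#' a fixed flux; and a xylose pathway is structurally blocked (its exchange
#' is closed), providing known zero-flux reactions. Genes (isozymes via
#' `or`, one `and` complex, one multi-reaction gene) are distributed over
#' the enzymatic and transport reactions in contiguous blocks, emulating
#' operons in genome order.
#'
#' The returned record contains the closed-form optimum: with glucose uptake
#' `u_g`, oxygen `u_o`, phosphate `u_p`, maintenance `m`, branch capacities
#' `cap`, and demands `d_c`/`d_p`,
#' `mu* = max(0, min((min(u_g, u_o) - m)/d_c, sum(cap)/d_c, u_p/d_p))`,
#' and when the antibiotic carries positive objective weight the surplus
#' carbon `min(u_g, u_o) - m - d_c mu*` is secreted as antibiotic.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (a `metabolic_model`) and `record` (role ids,
#'   capacities, demands, and `mu_star`, the optimum under the spec's
#'   initial uptake rates with pure biomass objective).
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$n_chain_length; B <- spec$n_branches
  caps <- spec$branch_caps
  if (is.null(caps)) caps <- round(stats::runif(B, 2, 6), 3)
  if (length(caps) != B) stop("branch_caps must have n_branches entries", call. = FALSE)
  m <- spec$maintenance; d_c <- spec$biomass_demand; d_p <- spec$phosphate_demand

  met <- function(id, compartment, formula = NA_character_)
    data.frame(id = id, name = id, compartment = compartment, formula = formula,
               stringsAsFactors = FALSE)
  mets <- rbind(
    met("glc_e", "e"), met("glc_c", "c"),
    met("o2_e", "e"), met("o2_c", "c"),
    met("co2_e", "e"), met("co2_c", "c"),
    met("pho_e", "e"), met("pho_c", "c"), met("ppool_c", "c"),
    met("act_e", "e", "C32H26O14"), met("act_c", "c", "C32H26O14"),
    met("xyl_e", "e"), met("xyl_c", "c"), met("xyl_d_c", "c"),
    met("bmpre_c", "c"))
  chain_mets <- paste0("m", seq_len(L), "_c")
  mets <- rbind(mets, do.call(rbind, lapply(chain_mets, met, compartment = "c")))
  branch_mets <- list()
  for (j in seq_len(B)) {
    if (j > 1) {
      ids <- paste0("b", j, "x", seq_len(j - 1), "_c")
      branch_mets[[j]] <- ids
      mets <- rbind(mets, do.call(rbind, lapply(ids, met, compartment = "c")))
    } else branch_mets[[j]] <- character(0)
  }

  rx <- list(); st <- list()
  add <- function(id, stoich, lb = 0, ub = 1000, gpr = "", kind = NA_character_,
                  subsystem = NA_character_) {
    rx[[length(rx) + 1L]] <<- data.frame(
      id = id, name = id, lower_bound = lb, upper_bound = ub,
      gene_association = gpr, subsystem = subsystem, kind = kind,
      stringsAsFactors = FALSE)
    st[[id]] <<- stoich
  }
  prec <- chain_mets[L]

  add("EX_glc", c(glc_e = -1), lb = -spec$glucose_rate0, ub = 0, kind = "exchange")
  add("EX_o2", c(o2_e = -1), lb = -spec$o2_rate, ub = 0, kind = "exchange")
  add("EX_co2", c(co2_e = -1), lb = 0, ub = 1000, kind = "exchange")
  add("EX_pho", c(pho_e = -1), lb = -spec$phosphate_rate0, ub = 0, kind = "exchange")
  add("EX_act", c(act_e = -1), lb = 0, ub = 1000, kind = "exchange")
  add("EX_xyl", c(xyl_e = -1), lb = 0, ub = 0, kind = "exchange")

  add("T_glc", c(glc_e = -1, glc_c = 1), subsystem = "transport")
  add("T_o2", c(o2_e = -1, o2_c = 1), subsystem = "transport")
  add("T_co2", c(co2_c = -1, co2_e = 1), subsystem = "transport")
  add("T_pho", c(pho_e = -1, pho_c = 1), subsystem = "transport")

  add("CHN01", c(glc_c = -1, o2_c = -1, co2_c = 1,
                 stats::setNames(1, chain_mets[1])), subsystem = "backbone")
  if (L > 1) for (i in 2:L)
    add(sprintf("CHN%02d", i),
        stats::setNames(c(-1, 1), c(chain_mets[i - 1], chain_mets[i])),
        subsystem = "backbone")
  add("MAINT", stats::setNames(-1, chain_mets[1]), lb = m, ub = m,
      kind = "maintenance", subsystem = "maintenance")

  branch_rxns <- list()
  for (j in seq_len(B)) {
    ids <- character(j)
    path <- c(prec, branch_mets[[j]], "bmpre_c")
    for (s in seq_len(j)) {
      ids[s] <- sprintf("BR%d_%d", j, s)
      add(ids[s], stats::setNames(c(-1, 1), c(path[s], path[s + 1])),
          ub = if (s == 1) caps[j] else 1000, subsystem = "branch")
    }
    branch_rxns[[j]] <- ids
  }

  add("PHOA", c(pho_c = -1, ppool_c = 1), subsystem = "phosphate")
  add("ACT1", stats::setNames(c(-1, 1), c(prec, "act_c")), subsystem = "antibiotic")
  add("T_act", c(act_c = -1, act_e = 1), subsystem = "antibiotic")
  add("T_xyl", c(xyl_e = -1, xyl_c = 1), subsystem = "blocked")
  add("XYL1", c(xyl_c = -1, xyl_d_c = 1), subsystem = "blocked")
  add("XYL2", stats::setNames(c(-1, 1), c("xyl_d_c", prec)), subsystem = "blocked")
  add("BIOMASS", c(bmpre_c = -d_c, ppool_c = -d_p), kind = "biomass")

  reactions <- do.call(rbind, rx)

  # gene-bearing reactions, in genome (block) order
  dyn_rxns <- c("T_glc", "T_o2", "T_co2", "T_pho",
                sprintf("CHN%02d", seq_len(L)),
                unlist(branch_rxns), "PHOA", "ACT1", "T_act")
  blocked <- c("T_xyl", "XYL1", "XYL2")
  n_const <- round(spec$fractions[["constant_flux"]] * spec$n_genes)
  n_zero <- 2L * length(blocked)
  n_dyn <- spec$n_genes - n_const - n_zero
  if (n_dyn < length(dyn_rxns))
    stop("n_genes too small for the network (need at least ",
         length(dyn_rxns) + n_const + n_zero, ")", call. = FALSE)

  gene_id <- function(i) sprintf("g%04d", i)
  gctr <- 0L
  take <- function(n) { ids <- gene_id(gctr + seq_len(n)); gctr <<- gctr + n; ids }

  # contiguous blocks of isozymes per reaction (operon emulation)
  alloc <- rep(n_dyn %/% length(dyn_rxns), length(dyn_rxns))
  extra <- n_dyn %% length(dyn_rxns)
  if (extra) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  gpr_of <- character(nrow(reactions)); names(gpr_of) <- reactions$id
  gene_blocks <- list()
  for (i in seq_along(dyn_rxns)) {
    ids <- take(alloc[i])
    gene_blocks[[dyn_rxns[i]]] <- ids
    gpr <- if (i == 1L && length(ids) >= 2L) {
      # one complex: first two genes form an AND pair, rest are isozymes
      paste(c(sprintf("(%s and %s)", ids[1], ids[2]), ids[-(1:2)]),
            collapse = " or ")
    } else paste(ids, collapse = " or ")
    gpr_of[dyn_rxns[i]] <- gpr
  }
  for (b in blocked) {
    ids <- take(2L)
    gene_blocks[[b]] <- ids
    gpr_of[b] <- paste(ids, collapse = " or ")
  }
  const_genes <- take(n_const)
  if (n_const > 0) gpr_of["MAINT"] <- paste(const_genes, collapse = " or ")
  gene_blocks[["MAINT"]] <- const_genes
  # one multi-reaction gene: the first backbone gene also appears on the
  # blocked XYL1 (it must match to the backbone, which carries more flux)
  multi_gene <- gene_blocks[["CHN01"]][1]
  gpr_of["XYL1"] <- paste(gpr_of["XYL1"], multi_gene, sep = " or ")

  reactions$gene_association <- unname(gpr_of[reactions$id])
  model <- metabolic_model(mets, reactions, st)

  u_eff <- min(spec$glucose_rate0, spec$o2_rate)
  mu_star <- max(0, min((u_eff - m) / d_c, sum(caps) / d_c,
                        spec$phosphate_rate0 / d_p))
  record <- list(
    caps = caps, maintenance = m, d_c = d_c, d_p = d_p,
    u_glc = spec$glucose_rate0, u_o2 = spec$o2_rate, u_pho = spec$phosphate_rate0,
    mu_star = mu_star,
    biomass_id = "BIOMASS",
    chain_rxns = sprintf("CHN%02d", seq_len(L)),
    branch_rxns = branch_rxns,
    carbon_rxns = c("EX_glc", "T_glc", "EX_o2", "T_o2", "T_co2", "EX_co2",
                    sprintf("CHN%02d", seq_len(L))),
    pho_rxns = c("EX_pho", "T_pho", "PHOA"),
    act_rxns = c("ACT1", "T_act", "EX_act"),
    blocked_rxns = blocked,
    maintenance_rxn = "MAINT",
    exchange_map = c(glucose = "EX_glc", o2 = "EX_o2", co2 = "EX_co2",
                     actinorhodin = "EX_act", phosphate = "EX_pho"),
    gene_blocks = gene_blocks,
    multi_gene = multi_gene,
    zero_flux_genes = setdiff(unlist(gene_blocks[blocked]), multi_gene),
    constant_genes = const_genes,
    n_genes = spec$n_genes)
  list(model = model, record = record)
}

#' Analytic optimum of the toy network
#'
#' Closed-form counterpart of [solve_fba()] on a [make_toy_model()] network.
#'
#' @param record the `record` from [make_toy_model()].
#' @param u_glc,u_o2,u_pho uptake capacities (mmol/gDW/h).
#' @param act_weight antibiotic objective weight; any positive value routes
#'   surplus carbon to the antibiotic (must be < 1 so biomass dominates).
#' @return list with `mu`, `v_act`, and `feasible`.
#' @export
toy_optimum <- function(record, u_glc = record$u_glc, u_o2 = record$u_o2,
                        u_pho = record$u_pho, act_weight = 0) {
  m <- record$maintenance
  u_eff <- min(u_glc, u_o2)
  if (u_eff < m - 1e-12)
    return(list(mu = NA_real_, v_act = NA_real_, feasible = FALSE))
  mu <- max(0, min((u_eff - m) / record$d_c, sum(record$caps) / record$d_c,
                   u_pho / record$d_p))
  v_act <- if (act_weight > 0) max(0, u_eff - m - record$d_c * mu) else 0
  list(mu = mu, v_act = v_act, feasible = TRUE)
}

#' Analytic parsimonious flux series of the toy network
#'
#' Closed-form counterpart of [run_dynamic_fba()] (weighted mode,
#' parsimonious resolution) on a toy network under a schedule: growth takes
#' carbon first, surplus goes to the antibiotic once its rate is positive,
#' and branch flux fills the shortest branches first (the 1-norm-minimal
#' split).
#'
#' @param record the `record` from [make_toy_model()].
#' @param schedule a `constraint_schedule` over the toy exchange ids.
#' @param times evaluation times; defaults to the schedule grid.
#' @return a `flux_time_series` built analytically (no LP involved).
#' @export
toy_flux_series <- function(record, schedule, times = schedule$times) {
  m <- record$maintenance
  rids <- c(record$carbon_rxns, record$pho_rxns, record$act_rxns,
            record$blocked_rxns, record$maintenance_rxn,
            unlist(record$branch_rxns), record$biomass_id)
  rids <- unique(rids)
  fm <- matrix(0, nrow = length(rids), ncol = length(times),
               dimnames = list(rids, paste0("t", times)))
  for (k in seq_along(times)) {
    t <- times[k]
    bl <- schedule_bounds_at(schedule, t)
    u_glc <- if ("EX_glc" %in% names(bl)) -bl[["EX_glc"]][1] else record$u_glc
    u_pho <- if ("EX_pho" %in% names(bl)) -bl[["EX_pho"]][1] else record$u_pho
    u_o2 <- if ("EX_o2" %in% names(bl)) -bl[["EX_o2"]][1] else record$u_o2
    rates <- antibiotic_rates_at(schedule, t)
    beta_pos <- t >= schedule$switch_time && length(rates) && any(rates > 0)
    opt <- toy_optimum(record, u_glc, u_o2, u_pho,
                       act_weight = if (beta_pos) 0.5 else 0)
    mu <- opt$mu; v_act <- opt$v_act
    FF <- record$d_c * mu + v_act + m
    fm["EX_glc", k] <- -FF; fm["T_glc", k] <- FF
    fm["EX_o2", k] <- -FF; fm["T_o2", k] <- FF
    fm["T_co2", k] <- FF; fm["EX_co2", k] <- FF
    fm[record$chain_rxns[1], k] <- FF
    if (length(record$chain_rxns) > 1)
      fm[record$chain_rxns[-1], k] <- FF - m
    fm[record$maintenance_rxn, k] <- m
    rem <- record$d_c * mu
    for (j in seq_along(record$branch_rxns)) {
      x <- min(record$caps[j], rem); rem <- rem - x
      fm[record$branch_rxns[[j]], k] <- x
    }
    fm["EX_pho", k] <- -record$d_p * mu
    fm["T_pho", k] <- record$d_p * mu
    fm["PHOA", k] <- record$d_p * mu
    fm[c("ACT1", "T_act", "EX_act"), k] <- v_act
    fm[record$biomass_id, k] <- mu
  }
  structure(list(times = times, flux_matrix = fm,
                 growth_curve = stats::setNames(fm[record$biomass_id, ],
                                                paste0("t", times)),
                 objective_values = fm[record$biomass_id, ],
                 status = rep("optimal", length(times)),
                 resolution_method = "analytic"),
            class = "flux_time_series")
}

#' Depletion-style constraint schedule for the toy network
#'
#' Linear ramps: phosphate (and optionally glucose) uptake falls linearly to
#' zero at its depletion time and stays zero; glucose otherwise ramps from
#' `glucose_rate0` to `glucose_rate_end`; oxygen is constant; the
#' antibiotic rate is zero before the switch and rises linearly to
#' `act_rate_max` at the end of the grid.
#'
#' @param spec a [synthetic_spec()].
#' @return a `constraint_schedule` over the toy exchange ids.
#' @export
make_schedule <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tt <- spec$times
  t0 <- min(tt); t1 <- max(tt)
  ramp_to_zero <- function(r0, t_dep)
    pmax(0, r0 * (t_dep - tt) / (t_dep - t0))
  glc <- if ("glucose" %in% names(spec$depletion_times)) {
    ramp_to_zero(spec$glucose_rate0, spec$depletion_times[["glucose"]])
  } else {
    spec$glucose_rate0 + (spec$glucose_rate_end - spec$glucose_rate0) * (tt - t0) / (t1 - t0)
  }
  pho <- if ("phosphate" %in% names(spec$depletion_times)) {
    ramp_to_zero(spec$phosphate_rate0, spec$depletion_times[["phosphate"]])
  } else rep(spec$phosphate_rate0, length(tt))
  act <- ifelse(tt < spec$switch_time, 0,
                spec$act_rate_max * (tt - spec$switch_time) /
                  max(t1 - spec$switch_time, 1e-9))
  constraint_schedule(
    times = tt,
    exchange_bounds = list(
      EX_glc = cbind(lower = -glc, upper = 0),
      EX_pho = cbind(lower = -pho, upper = 0),
      EX_o2 = cbind(lower = rep(-spec$o2_rate, length(tt)), upper = 0)),
    antibiotic_rates = list(EX_act = act),
    switch_time = spec$switch_time)
}

#' Simulate expression profiles from a flux time series
#'
#' For every matched gene the expression profile is derived from the matched
#' reaction's flux profile: faithful (correlated) genes get a positive
#' affine transform of the variance-standardized flux plus Gaussian noise;
#' injected anticorrelated genes get the sign-flipped transform (emulating
#' misannotated genes whose expression rises as predicted flux falls);
#' unexpressed genes sit at a low noise floor; genes on constant-flux
#' (maintenance) reactions and on zero-flux (blocked) reactions get dynamic
#' profiles unrelated to flux (a post-switch induction sigmoid), emulating
#' the expressed-but-not-predicted signature. Genes whose matched reaction
#' is always active get `essential_shift` added to their baseline.
#'
#' @param fluxTS a `flux_time_series` (use [toy_flux_series()] for a
#'   generator-side series independent of the LP path).
#' @param matching gene -> reaction map from [match_genes()].
#' @param spec a [synthetic_spec()] (noise level, fractions, seed, controls).
#' @return list with `expr` (an `expression_matrix`, controls included) and
#'   `truth` (data.frame: gene, label, reaction, slope, intercept).
#' @export
simulate_expression <- function(fluxTS, matching, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  genes <- names(matching)
  fm <- fluxTS$flux_matrix
  tt <- fluxTS$times
  tol <- 1e-9

  prof <- fm[unname(matching[genes]), , drop = FALSE]
  rownames(prof) <- genes
  sdv <- apply(prof, 1, stats::sd)
  zero <- genes[apply(abs(prof) <= tol, 1, all)]
  constant <- setdiff(genes[sdv <= tol], zero)
  dyn <- setdiff(genes, c(zero, constant))
  essential <- genes[apply(abs(prof) > tol, 1, all)]

  n_anti <- round(spec$fractions[["anticorrelated"]] * spec$n_genes)
  n_unexp <- round(spec$fractions[["unexpressed"]] * spec$n_genes)
  if (n_anti + n_unexp > length(dyn))
    stop("too few dynamic-flux genes for the requested fractions", call. = FALSE)
  shuffled <- sample(dyn)
  anti <- shuffled[seq_len(n_anti)]
  unexp <- shuffled[n_anti + seq_len(n_unexp)]
  faithful <- setdiff(dyn, c(anti, unexp))

  label <- stats::setNames(rep("correlated", length(genes)), genes)
  label[anti] <- "anticorrelated"
  label[unexp] <- "unexpressed"
  label[constant] <- "constant_flux"
  label[zero] <- "zero_flux"

  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(tt),
                 dimnames = list(genes, paste0("t", tt)))
  slope <- stats::setNames(rep(NA_real_, length(genes)), genes)
  intercept <- stats::setNames(rep(NA_real_, length(genes)), genes)
  noise <- function() stats::rnorm(length(tt), 0, spec$noise_sd)
  sigmoid <- function() {
    base <- stats::runif(1, 5, 7); amp <- stats::runif(1, 1, 3)
    base + amp / (1 + exp(-(tt - spec$switch_time) / 2))
  }
  for (g in genes) {
    if (label[g] %in% c("correlated", "anticorrelated")) {
      z <- (prof[g, ] - mean(prof[g, ])) / sdv[g]
      a <- stats::runif(1, 0.5, 2) * if (label[g] == "anticorrelated") -1 else 1
      b <- stats::runif(1, 5, 9) + if (g %in% essential) spec$essential_shift else 0
      vals[g, ] <- a * z + b + noise()
      slope[g] <- a; intercept[g] <- b
    } else if (label[g] == "unexpressed") {
      vals[g, ] <- 4 + stats::rnorm(length(tt), 0, 0.2)
    } else {
      vals[g, ] <- sigmoid() + noise()
    }
  }
  ctrl <- character(0)
  if (spec$n_controls > 0) {
    ctrl <- sprintf("ctrl%02d", seq_len(spec$n_controls))
    cv <- matrix(4.5 + stats::rnorm(spec$n_controls * length(tt), 0, 0.3),
                 nrow = spec$n_controls, dimnames = list(ctrl, paste0("t", tt)))
    vals <- rbind(vals, cv)
  }
  truth <- data.frame(gene = genes, label = unname(label[genes]),
                      reaction = unname(matching[genes]),
                      essential = genes %in% essential,
                      slope = unname(slope[genes]),
                      intercept = unname(intercept[genes]),
                      stringsAsFactors = FALSE)
  list(expr = expression_matrix(vals, tt, control_rows = ctrl), truth = truth)
}

#' Two-group expression fixture for clustering checks
#'
#' Flat-high vs flat-low profiles with separation much larger than noise;
#' ground-truth labels returned alongside.
#'
#' @param n_per_group genes per group.
#' @param times sampling grid.
#' @param separation log2 distance between group means.
#' @param noise_sd per-sample Gaussian noise.
#' @param seed integer.
#' @return list with `expr` and `truth` (named group vector).
#' @export
make_two_group_expression <- function(n_per_group = 25, times = seq(20, 40, 2),
                                      separation = 4, noise_sd = 0.2, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  ids <- sprintf("g%03d", seq_len(n))
  grp <- rep(1:2, each = n_per_group)
  base <- ifelse(grp == 1, 6, 6 + separation)
  # opposite slow trends so the two shapes differ, not just the levels
  trend <- ifelse(grp == 1, 0.05, -0.05)
  vals <- t(vapply(seq_len(n), function(i)
    base[i] + trend[i] * (times - min(times)) + stats::rnorm(length(times), 0, noise_sd),
    numeric(length(times))))
  rownames(vals) <- ids
  list(expr = expression_matrix(vals, times),
       truth = stats::setNames(grp, ids))
}

#' Self-consistent chemostat panel for a toy model
#'
#' Generates `n` steady-state conditions with increasing substrate supply.
#' Oxygen is kept slack, carbon dioxide production is pinned to the total
#' carbon throughput implied by the condition, antibiotic production is
#' negligible, and the observed dilution rate column is filled with the
#' model's own prediction, giving a panel on which prediction and
#' observation agree by construction.
#'
#' @param model a toy `metabolic_model` from [make_toy_model()].
#' @param record its generator record.
#' @param n number of conditions.
#' @param seed integer.
#' @return data.frame in [chemostat_panel()] column convention.
#' @export
make_chemostat_table <- function(model, record, n, seed = 1L) {
  set.seed(seed)
  cols <- c("glucose_uptake", "o2_uptake", "co2_production",
            "actinorhodin_production", "observed_dilution_rate")
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  m <- record$maintenance
  hi <- min(sum(record$caps) / record$d_c, record$u_pho / record$d_p)
  mu_targets <- seq(0.2 * hi, 0.9 * hi, length.out = n)
  glc <- record$d_c * mu_targets + m
  out <- data.frame(glucose_uptake = glc,
                    o2_uptake = glc + 1,
                    co2_production = glc,
                    actinorhodin_production = rep(0, n),
                    observed_dilution_rate = NA_real_)
  panel <- chemostat_panel(model, out, exchange_map = record$exchange_map[
    c("glucose", "o2", "co2", "actinorhodin")])
  out$observed_dilution_rate <- panel$predicted_mu
  out
}
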