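test_that("FBA solves the analytic toy chain", {
  m <- tiny_chain_model(uptake = 10, demand = 2)
  fs <- solve_fba(m)
  expect_equal(fs$status, "optimal")
  expect_equal(fs$objective_value, 5.0)
  expect_equal(unname(fs$fluxes["EX_A"]), -10)
  expect_lte(mass_balance_residual(m, fs), 1e-6)
})

test_that("LP optimum matches the vertex-enumeration oracle on random networks", {
  worst <- 0
  for (seed in 1:40) {
    net <- random_lp_network(seed)
    lp <- switchFBA:::lp_solve(net$obj, Aeq = net$S, beq = rep(0, nrow(net$S)),
                               lb = net$lb, ub = net$ub, maximize = TRUE)
    vo <- lp_vertex_optimum(net$S, net$obj, net$lb, net$ub)
    expect_equal(lp$status, "optimal", info = paste("seed", seed))
    worst <- max(worst, abs(lp$value - vo$value))
    expect_lt(abs(lp$value - vo$value), 1e-8)
    # mass balance of the returned vertex
    expect_lt(max(abs(net$S %*% lp$solution)), 1e-6)
  }
  expect_lt(worst, 1e-8)
})

test_that("objective value is invariant under metabolite row permutation", {
  tm <- make_toy_model(synthetic_spec(n_genes = 40, seed = 23))
  m1 <- tm$model
  ref <- solve_fba(m1)$objective_value
  set.seed(1)
  perm <- sample(nrow(m1$metabolites))
  m2 <- metabolic_model(m1$metabolites[perm, ], m1$reactions,
                        m1$stoichiometry, objective = m1$objective)
  expect_equal(solve_fba(m2)$objective_value, ref, tolerance = 1e-9)
  # and across repeated solves
  expect_identical(solve_fba(m1)$objective_value, ref)
})

test_that("relaxing an uptake bound never decreases the optimum", {
  m <- tiny_chain_model(uptake = 4)
  mu <- vapply(c(2, 4, 6, 8), function(u)
    solve_fba(m, bound_overrides = list(EX_A = c(-u, 0)))$objective_value,
    numeric(1))
  expect_true(all(diff(mu) >= -1e-10))
})

test_that("infeasible and unbounded problems are reported faithfully", {
  m <- tiny_chain_model()
  # production pinned above what uptake allows
  fs <- solve_fba(m, bound_overrides = list(EX_A = c(-1, 0),
                                            BIOMASS = c(2, 2)))
  expect_equal(fs$status, "infeasible")
  expect_null(fs$fluxes)

  # a reversible unbounded pair pumping the objective
  mets <- data.frame(id = "A_c", name = "A", compartment = "c")
  rxns <- data.frame(id = c("FWD", "BWD"), name = c("fwd", "bwd"),
                     lower_bound = c(-Inf, -Inf), upper_bound = c(Inf, Inf),
                     gene_association = "", kind = "enzymatic",
                     stringsAsFactors = FALSE)
  st <- list(FWD = c(A_c = 1), BWD = c(A_c = -1))
  mu <- metabolic_model(mets, rxns, st, objective = c(FWD = 1))
  fs2 <- solve_fba(mu)
  expect_equal(fs2$status, "unbounded")
  expect_true("FWD" %in% fs2$unbounded_reaction)

  # invalid override
  expect_error(solve_fba(m, bound_overrides = list(EX_A = c(1, -1))),
               "invalid bound override")
  expect_error(solve_fba(m, bound_overrides = list(NOPE = c(0, 1))),
               "absent from the model")
})

test_that("parsimonious resolution reproduces unique optima and kills cycles", {
  # unique optimum: identical to the plain FBA vector
  m <- tiny_chain_model()
  fs <- solve_fba(m)
  pf <- parsimonious_flux(m, optimum = fs$objective_value)
  expect_equal(pf$fluxes, fs$fluxes, tolerance = 1e-8)
  expect_equal(pf$objective_value, fs$objective_value, tolerance = 1e-9)

  # closed internal 2-cycle carries zero flux in the parsimonious solution
  mc <- cycle_model()
  fc <- solve_fba(mc)
  pc <- parsimonious_flux(mc, optimum = fc$objective_value)
  expect_equal(unname(pc$fluxes["CYC1"]), 0, tolerance = 1e-9)
  expect_equal(unname(pc$fluxes["CYC2"]), 0, tolerance = 1e-9)
  expect_equal(pc$objective_value, fc$objective_value, tolerance = 1e-9)
})

test_that("parsimonious total flux matches the brute-force minimum over the optimal face", {
  # uptake 6, direct route capped at 4: optimum mu = 6, and the cheapest
  # routing is direct 4 + two-step 2, giving sum|v| = 6 + 6 + 4 + 2 + 2 + 2
  m <- two_route_model(uptake = 6, cap_direct = 4)
  fs <- solve_fba(m)
  expect_equal(fs$objective_value, 6)
  pf <- parsimonious_flux(m, optimum = fs$objective_value)
  # brute-force search over the optimal face: DIR in [0, 4], VIA = 6 - DIR
  grid <- seq(0, 4, by = 0.01)
  costs <- vapply(grid, function(d) 6 + 6 + d + 2 * (6 - d), numeric(1))
  expect_equal(pf$total_abs_flux, min(costs), tolerance = 1e-6)
  expect_equal(unname(pf$fluxes["DIR"]), 4, tolerance = 1e-8)
  expect_equal(unname(pf$fluxes["VIA1"]), 2, tolerance = 1e-8)
})

test_that("chemostat panel applies the exchange conventions per condition", {
  tm <- make_toy_model(synthetic_spec(n_genes = 40, seed = 29))
  panel <- make_chemostat_table(tm$model, tm$record, n = 5, seed = 1)
  res <- chemostat_panel(tm$model, panel,
                         exchange_map = tm$record$exchange_map)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$status == "optimal"))
  # self-consistent panel: observed column was filled with the prediction
  expect_equal(res$predicted_mu, panel$observed_dilution_rate, tolerance = 1e-9)
  # increasing supply -> strictly increasing growth for a substrate-limited toy
  expect_true(all(diff(res$predicted_mu) > 0))

  # single condition equals a direct solve with the same overrides
  one <- chemostat_panel(tm$model, panel[3, ], tm$record$exchange_map)
  ov <- list(EX_glc = c(-panel$glucose_uptake[3], 0),
             EX_o2 = c(-panel$o2_uptake[3], 0),
             EX_co2 = c(panel$co2_production[3], panel$co2_production[3]),
             EX_act = c(0, 0))
  expect_equal(one$predicted_mu, solve_fba(tm$model, bound_overrides = ov)$objective_value,
               tolerance = 1e-9)

  # empty condition list -> empty output
  empty <- chemostat_panel(tm$model, panel[0, ], tm$record$exchange_map)
  expect_equal(nrow(empty), 0L)

  # missing exchange -> configuration error naming the metabolite mapping
  expect_error(chemostat_panel(tm$model, panel,
                               exchange_map = c(glucose = "EX_glc", o2 = "EX_o2",
                                                co2 = "EX_co2",
                                                actinorhodin = "EX_missing")),
               "EX_missing")
  # negative rates rejected
  bad <- panel; bad$glucose_uptake[1] <- -1
  expect_error(chemostat_panel(tm$model, bad, tm$record$exchange_map),
               "negative rate")
})

test_that("published chemostat condition table parses with original headers", {
  path <- system.file("extdata", "chemostat_conditions.tsv", package = "switchFBA")
  df <- read_chemostat_table(path)
  expect_equal(nrow(df), 7L)
  expect_true(all(c("glucose_uptake", "o2_uptake", "co2_production",
                    "actinorhodin_production", "observed_dilution_rate") %in%
                    names(df)))
  expect_equal(df$glucose_uptake[1], 0.5)
  expect_equal(df$observed_dilution_rate[7], 0.128)

  # original published header names are mapped too
  alt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("Glucose (mmol/g.h)", "O2 (mmol/g.h)", "CO2 (mmol/g.h)",
                     "Actinorhodin (ug/g.h)", "Observed dilution rate D(/h)",
                     sep = "\t"),
               paste(0.5, 1.8, 1.9, 2, 0.035, sep = "\t")), alt)
  df2 <- read_chemostat_table(alt)
  expect_equal(df2$glucose_uptake, 0.5)
  expect_equal(df2$observed_dilution_rate, 0.035)
})

test_that("chemical formula weights support the microgram conversion", {
  expect_equal(formula_weight("H2O"), 18.015, tolerance = 1e-3)
  # actinorhodin C32H26O14
  expect_equal(formula_weight("C32H26O14"), 634.54, tolerance = 0.1)
  expect_error(formula_weight("Xx3"), "unknown element")
  # 634.54 ug/gDW/h is 0.001 mmol/gDW/h
  expect_equal(switchFBA:::ug_to_mmol(634.54, 634.54), 1e-3)
})
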