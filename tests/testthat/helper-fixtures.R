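# Shared fixtures, all built in code.

# minimal chain: uptake of A (<= 10), A -> B, biomass consumes 2 B.
# analytic optimum: 10 / 2 = 5.
tiny_chain_model <- function(uptake = 10, demand = 2) {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "R1", "BIOMASS"),
    name = c("A exchange", "A to B", "biomass"),
    lower_bound = c(-uptake, 0, 0),
    upper_bound = c(0, 1000, 1000),
    gene_association = c("", "g1", ""),
    stringsAsFactors = FALSE)
  st <- list(EX_A = c(A_c = -1), R1 = c(A_c = -1, B_c = 1),
             BIOMASS = c(B_c = -demand))
  metabolic_model(mets, rxns, st)
}

# two irreversible parallel routes A -> B with different costs (one direct,
# one via an intermediate), used for parsimonious-resolution checks
two_route_model <- function(uptake = 6, cap_direct = 4) {
  mets <- data.frame(id = c("A_c", "I_c", "B_c"), name = c("A", "I", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "DIR", "VIA1", "VIA2", "BIOMASS"),
    name = c("A exchange", "direct", "via step 1", "via step 2", "biomass"),
    lower_bound = c(-uptake, 0, 0, 0, 0),
    upper_bound = c(0, cap_direct, 1000, 1000, 1000),
    gene_association = "",
    stringsAsFactors = FALSE)
  st <- list(EX_A = c(A_c = -1), DIR = c(A_c = -1, B_c = 1),
             VIA1 = c(A_c = -1, I_c = 1), VIA2 = c(I_c = -1, B_c = 1),
             BIOMASS = c(B_c = -1))
  metabolic_model(mets, rxns, st)
}

# chain with a closed internal 2-cycle between B and C
cycle_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_c", "B_c", "C_c"), name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "R1", "CYC1", "CYC2", "BIOMASS"),
    name = c("A exchange", "A to B", "B to C", "C to B", "biomass"),
    lower_bound = c(-uptake, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000),
    gene_association = "",
    stringsAsFactors = FALSE)
  st <- list(EX_A = c(A_c = -1), R1 = c(A_c = -1, B_c = 1),
             CYC1 = c(B_c = -1, C_c = 1), CYC2 = c(C_c = -1, B_c = 1),
             BIOMASS = c(B_c = -1))
  metabolic_model(mets, rxns, st)
}

# random bounded LP over a random sparse stoichiometry; feasible (v = 0)
# and bounded by construction
random_lp_network <- function(seed, n_range = 6:9, m_range = 3:5) {
  set.seed(seed)
  m <- sample(m_range, 1)
  n <- sample(n_range, 1)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    k <- sample(seq_len(min(3, m)), 1)
    S[sample(m, k), j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  lb <- ifelse(stats::runif(n) < 0.3, -round(stats::runif(n, 1, 10), 1), 0)
  ub <- round(stats::runif(n, 1, 10), 1)
  obj <- numeric(n)
  nobj <- sample(1:2, 1)
  obj[sample(n, nobj)] <- round(stats::runif(nobj, 0.5, 2), 2)
  list(S = S, lb = lb, ub = ub, obj = obj)
}

# small synthetic bundle reused by several integration tests
small_bundle <- function(seed = 7, n_genes = 60, noise_sd = 0.1) {
  spec <- synthetic_spec(n_genes = n_genes, noise_sd = noise_sd, seed = seed)
  tm <- make_toy_model(spec)
  sch <- make_schedule(spec)
  ats <- toy_flux_series(tm$record, sch)
  matching <- match_genes(tm$model, ats)
  sim <- simulate_expression(ats, matching, spec)
  list(spec = spec, model = tm$model, record = tm$record, schedule = sch,
       analytic = ats, matching = matching, expr = sim$expr, truth = sim$truth)
}
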