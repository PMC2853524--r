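make_ts <- function(mat, times) {
  structure(list(times = times, flux_matrix = mat,
                 growth_curve = mat[1, ], status = rep("optimal", length(times)),
                 resolution_method = "parsimonious"),
            class = "flux_time_series")
}

test_that("expression tables round-trip through TSV with parsed times", {
  vals <- matrix(rnorm(12), nrow = 3,
                 dimnames = list(c("gA", "gB", "gC"), NULL))
  em <- expression_matrix(vals, times = c(20, 21, 22, 23))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, path)
  em2 <- read_expression(path)
  expect_equal(em2$values, em$values)
  expect_equal(em2$times, c(20, 21, 22, 23))

  # header variants encode hours
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt20\tt21", "gA\t1\t2", "gB\t3\t4"), path2)
  expect_equal(read_expression(path2)$times, c(20, 21))

  # errors: non-numeric cell, duplicate gene
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt20\tt21", "gA\t1\toops", "gB\t3\t4"), path3)
  expect_error(read_expression(path3), "non-numeric expression value")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt20\tt21", "gA\t1\t2", "gA\t3\t4"), path4)
  expect_error(read_expression(path4), "duplicate gene ids")
})

test_that("genes match their highest-flux reaction with deterministic ties", {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"), compartment = "c")
  rxns <- data.frame(
    id = c("EX_A", "RBIG", "RSMALL", "RTIE"),
    name = c("ex", "big", "small", "tie"),
    lower_bound = c(-10, 0, 0, 0), upper_bound = c(0, 10, 10, 10),
    gene_association = c("", "gm or giso1 or giso2", "gm", "gm"),
    kind = c("exchange", "enzymatic", "enzymatic", "enzymatic"),
    stringsAsFactors = FALSE)
  st <- list(EX_A = c(A_c = -1), RBIG = c(A_c = -1, B_c = 1),
             RSMALL = c(A_c = -1, B_c = 1), RTIE = c(A_c = -1, B_c = 1))
  m <- metabolic_model(mets, rxns, st, objective = c(RBIG = 1))
  fm <- rbind(EX_A = c(-2.5, -2.5), RBIG = c(2.0, 2.0),
              RSMALL = c(0.5, 0.5), RTIE = c(2.0, 2.0))
  ts <- make_ts(fm, times = c(20, 21))
  mt <- match_genes(m, ts)
  # mean |v| 2.0 beats 0.5; tie between RBIG and RTIE broken lexicographically
  expect_equal(unname(mt["gm"]), "RBIG")
  # isozymes both map to their shared reaction
  expect_equal(unname(mt[c("giso1", "giso2")]), c("RBIG", "RBIG"))
  expect_length(attr(mt, "zero_flux"), 0L)
})

test_that("correlation is affine-exact and excludes uninformative genes", {
  flux <- c(1, 2, 3, 5, 4, 6)
  fm <- rbind(R1 = flux, R2 = rep(2, 6), R3 = rep(0, 6))
  ts <- make_ts(fm, times = 20:25)
  vals <- rbind(gpos = 3 * flux + 7,
                gneg = -flux,
                gconst = 2 * rep(2, 6) + 1,
                gzero = rnorm(6),
                gflat = rep(5, 6))
  em <- expression_matrix(vals, times = 20:25)
  matching <- c(gpos = "R1", gneg = "R1", gconst = "R2", gzero = "R3",
                gflat = "R1")
  attr(matching, "zero_flux") <- "gzero"
  rep <- correlate(ts, em, matching)
  p <- rep$profiles
  expect_equal(p$r[p$gene == "gpos"], 1.0, tolerance = 1e-12)
  expect_equal(p$r[p$gene == "gneg"], -1.0, tolerance = 1e-12)
  # constant flux / zero flux / constant expression carry no r
  expect_true(all(p$excluded[p$gene %in% c("gconst", "gzero", "gflat")]))
  expect_true(all(is.na(p$r[p$excluded])))
  expect_equal(p$reason[p$gene == "gconst"], "constant flux")
  expect_equal(p$reason[p$gene == "gzero"], "zero flux")
  expect_equal(p$reason[p$gene == "gflat"], "constant expression")
  # r is invariant under positive affine transforms of either profile
  em2 <- expression_matrix(rbind(gpos = 0.1 * (3 * flux + 7) + 100), times = 20:25)
  rep2 <- correlate(ts, em2, matching[1])
  expect_equal(rep2$profiles$r, 1.0, tolerance = 1e-12)
})

test_that("classification thresholds partition the non-excluded genes", {
  flux <- c(1, 2, 3, 5, 4, 6)
  ts <- make_ts(rbind(R1 = flux), times = 20:25)
  set.seed(1)
  vals <- rbind(ghi = flux + rnorm(6, 0, 0.1),
                glo = -flux + rnorm(6, 0, 0.1),
                gmid = c(6, 1, 5, 2, 4, 3))
  em <- expression_matrix(vals, times = 20:25)
  matching <- c(ghi = "R1", glo = "R1", gmid = "R1")
  attr(matching, "zero_flux") <- character(0)
  rep <- classify(correlate(ts, em, matching))
  p <- rep$profiles
  expect_equal(p$class[p$gene == "ghi"], "correlated")
  expect_equal(p$class[p$gene == "glo"], "anticorrelated")
  expect_equal(p$class[p$gene == "gmid"], "uncorrelated")
  expect_equal(sum(rep$class_counts), sum(!p$excluded))
  expect_equal(sum(attr(rep$class_counts, "fractions")), 1)
  expect_error(classify(rep, low = 0.5, high = -0.5))
})

test_that("zero-flux screen agrees with graph reachability on the toy network", {
  b <- small_bundle(seed = 61)
  zf <- zero_flux_genes(b$matching, b$analytic)
  # independent oracle: genes all of whose reactions are unreachable from
  # open exchange inputs must be in the zero-flux set
  blocked <- blocked_reactions(b$model)
  expect_true(all(b$record$blocked_rxns %in% blocked))
  grm <- gene_reaction_map(b$model)
  oracle_genes <- names(grm)[vapply(grm, function(r) all(r %in% blocked),
                                    logical(1))]
  expect_true(all(oracle_genes %in% zf))
  expect_setequal(oracle_genes, b$record$zero_flux_genes)
  # any further zero-flux genes sit on reactions that carry no flux at any
  # time even though they are structurally reachable (unused capacity)
  extra <- setdiff(zf, oracle_genes)
  if (length(extra)) {
    fm <- b$analytic$flux_matrix
    expect_true(all(vapply(extra, function(g)
      all(abs(fm[b$matching[[g]], ]) <= 1e-9), logical(1))))
  }
  # zero-flux and essential sets are disjoint
  ess <- essential_expression_summary(b$analytic, b$expr, b$matching)
  expect_length(intersect(zf, ess$essential_genes), 0L)
})

test_that("a multi-reaction gene follows its dominant reaction out of the zero set", {
  b <- small_bundle(seed = 67)
  # the multi-reaction gene sits on both the backbone and a blocked reaction
  expect_equal(unname(b$matching[b$record$multi_gene]),
               b$record$chain_rxns[1])
  expect_false(b$record$multi_gene %in% zero_flux_genes(b$matching, b$analytic))
})

test_that("essentiality screen recovers the injected expression shift", {
  b <- small_bundle(seed = 71)
  ess <- essential_expression_summary(b$analytic, b$expr, b$matching)
  truth_ess <- b$truth$gene[b$truth$essential]
  expect_setequal(ess$essential_genes, truth_ess)
  # essential genes were simulated with a +0.6 log2 baseline shift;
  # medians must recover a clearly positive difference
  expect_gt(ess$median_essential, ess$median_non_essential)
  expect_lt(ess$median_controls, ess$median_non_essential)
  # degenerate case: empty groups give NA medians, not zero
  em <- expression_matrix(matrix(5, 1, 3, dimnames = list("gX", NULL)),
                          times = 1:3)
  ts <- make_ts(rbind(R1 = c(1, 1, 1)), times = 1:3)
  matching <- c(gX = "R1")
  out <- essential_expression_summary(ts, em, matching)
  expect_equal(out$essential_genes, "gX")
  expect_true(is.na(out$median_non_essential))
  expect_true(is.na(out$median_controls))
})

test_that("expression samples align to flux times by nearest neighbour within 1 h", {
  flux <- c(1, 2, 3, 4)
  ts <- make_ts(rbind(R1 = flux), times = c(20, 22, 24, 26))
  # offset expression grid by 0.4 h: still aligned
  em <- expression_matrix(rbind(g1 = 2 * flux + 1),
                          times = c(20.4, 22.4, 24.4, 26.4))
  matching <- c(g1 = "R1"); attr(matching, "zero_flux") <- character(0)
  rep <- correlate(ts, em, matching)
  expect_equal(rep$profiles$r, 1.0, tolerance = 1e-12)
  expect_equal(rep$n_times_used, 4L)
  # far-off grid: no overlap within tolerance
  em2 <- expression_matrix(rbind(g1 = flux), times = c(50, 60, 70, 80))
  expect_error(suppressWarnings(correlate(ts, em2, matching)),
               "overlapping time points")
})
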