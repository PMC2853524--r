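test_that("SBML round-trip preserves the model field by field", {
  tm <- make_toy_model(synthetic_spec(n_genes = 40, seed = 13))
  m1 <- tm$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m1, path)
  m2 <- read_sbml(path)

  expect_identical(m2$metabolites$id, m1$metabolites$id)
  expect_identical(m2$metabolites$compartment, m1$metabolites$compartment)
  expect_identical(m2$metabolites$formula, m1$metabolites$formula)
  expect_identical(m2$reactions$id, m1$reactions$id)
  expect_equal(m2$reactions$lower_bound, m1$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m1$reactions$upper_bound)
  expect_identical(m2$reactions$gene_association, m1$reactions$gene_association)
  expect_identical(m2$reactions$kind, m1$reactions$kind)
  expect_identical(m2$reactions$subsystem, m1$reactions$subsystem)
  expect_equal(m2$objective, m1$objective)
  for (rid in m1$reactions$id) {
    a <- m1$stoichiometry[[rid]]; b <- m2$stoichiometry[[rid]]
    expect_equal(b[names(a)], a, info = rid)
  }
})

test_that("degenerate SBML inputs parse to degenerate models", {
  # 1 species, 0 reactions
  mets <- data.frame(id = "X_c", name = "X", compartment = "c")
  rxns <- data.frame(id = character(0), name = character(0),
                     lower_bound = numeric(0), upper_bound = numeric(0),
                     gene_association = character(0))
  m <- metabolic_model(mets, rxns, list(), objective = numeric(0))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(nrow(m2$metabolites), 1L)
  expect_equal(nrow(m2$reactions), 0L)

  # empty model -> valid skeleton re-parsing to (0, 0)
  empty <- metabolic_model(mets[0, ], rxns, list(), objective = numeric(0))
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(empty, path2)
  m3 <- read_sbml(path2)
  expect_equal(nrow(m3$metabolites), 0L)
  expect_equal(nrow(m3$reactions), 0L)
})

test_that("malformed and inconsistent SBML raise informative errors", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed>", path)
  expect_error(read_sbml(path), "malformed SBML")

  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfCompartments><compartment id="C_c"/></listOfCompartments>',
    '<listOfSpecies><species id="M_A_c" compartment="C_c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R_R1">',
    '<listOfReactants><speciesReference species="M_A_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_GHOST"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  expect_error(read_sbml(path), "undeclared species.*R1")

  expect_error(read_sbml(file.path(tempdir(), "no-such-file.xml")), "no such file")
})

test_that("legacy COBRA-style level 2 annotations are understood", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfCompartments><compartment id="C_c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_A_c" compartment="C_c"/>',
    '<species id="M_B_c" compartment="C_c"/>',
    '<species id="M_A_b" compartment="C_c" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="M_A_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_A_b"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-10"/><parameter id="UPPER_BOUND" value="0"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="R_R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (SCO1 and SCO2) or SCO3</p></body></notes>',
    '<listOfReactants><speciesReference species="M_A_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_B_c" stoichiometry="2"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  m <- read_sbml(path)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -10)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_A"], 0)
  # boundary species dropped, so the exchange stays single-metabolite
  expect_equal(m$reactions$kind[m$reactions$id == "EX_A"], "exchange")
  expect_equal(m$reactions$gene_association[m$reactions$id == "R1"],
               "(SCO1 and SCO2) or SCO3")
  expect_equal(m$stoichiometry$R1, c(A_c = -1, B_c = 2))
})

test_that("emitted SBML is readable by an independent constraint-based toolchain", {
  tm <- make_toy_model(synthetic_spec(n_genes = 40, seed = 17))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(tm$model, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "sol = m.optimize()",
    "print(len(m.metabolites), len(m.reactions), len(m.genes), sol.objective_value)"),
    script)
  out <- suppressWarnings(
    system2("python", c(script, path), stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    fail("cobra-based reference reader could not parse the emitted SBML")
  vals <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(vals[1], nrow(tm$model$metabolites))
  expect_equal(vals[2], nrow(tm$model$reactions))
  expect_equal(vals[3], length(gene_reaction_map(tm$model)))
  expect_equal(vals[4], solve_fba(tm$model)$objective_value, tolerance = 1e-6)
})

test_that("model tables export mirrors the supplementary-table layout", {
  tm <- make_toy_model(synthetic_spec(n_genes = 40, seed = 19))
  mp <- withr::local_tempfile(fileext = ".tsv")
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_model_tables(tm$model, mp, rp)
  mt <- read.delim(mp)
  rt <- read.delim(rp)
  expect_equal(nrow(mt), nrow(tm$model$metabolites))
  expect_equal(nrow(rt), nrow(tm$model$reactions))
  expect_true(all(c("id", "equation", "lower_bound", "upper_bound",
                    "genes", "kind") %in% names(rt)))
  expect_match(rt$equation[rt$id == "BIOMASS"], "bmpre_c")
})
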