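test_that("tabular dialect parses equations, defaults and gene lists", {
  path <- writeModelTSV(c(
    "R1\tA -> B\t\t\tg1\t0",
    "R2\tA <=> C\t\t\t\t0",
    "EX_A\tA ->\t-10\t\t\t0",
    "BIOMASS\t1 B + 1 C ->\t\t\t\t1"
  ))
  m <- readTabularModel(path)
  expect_s4_class(m, "MetabolicModel")
  S <- as.matrix(stoichMatrix(m))
  expect_equal(S[c("A", "B"), "R1"], c(A = -1, B = 1))
  expect_equal(unname(lowerBounds(m)[c("R1", "R2", "EX_A")]), c(0, -1000, -10))
  expect_equal(unname(upperBounds(m)[c("R1", "R2")]), c(1000, 1000))
  expect_equal(geneAssociations(m)$R1, "g1")
  expect_equal(geneAssociations(m)$R2, character(0))
  expect_identical(objectiveId(m), "BIOMASS")
  # only single-metabolite reactions are exchanges (biomass consumes two)
  expect_equal(unname(isExchange(m)), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("tabular dialect rejects malformed input with located errors", {
  bad <- writeModelTSV(c("R1\tA = B\t\t\t\t1"))
  expect_error(readTabularModel(bad), "equation", class = "fw_format_error")
  noObj <- writeModelTSV(c("R1\tA -> B\t\t\t\t0", "EX_A\tA ->\t-10\t\t\t0"))
  expect_error(readTabularModel(noObj), "objective", class = "fw_config_error")
  twoObj <- writeModelTSV(c("R1\tA -> B\t\t\t\t1", "EX_A\tA ->\t-10\t\t\t1"))
  expect_error(readTabularModel(twoObj), "objective", class = "fw_config_error")
  degenerate <- writeModelTSV(c("R1\tA -> A\t\t\t\t1"))
  expect_error(readTabularModel(degenerate), "stoichiometry", class = "fw_format_error")
})

test_that("tabular write/read round-trips every fixture exactly", {
  for (scenario in c("CHAIN3", "PARALLEL", "SELECTIVE", "CYCLE")) {
    m <- makeFixtureModel(scenario)
    tf <- tempfile(fileext = ".tsv")
    writeTabularModel(m, tf)
    expectModelsEqual(m, readTabularModel(tf))
  }
  # a larger random model with fractional bounds survives the round trip too
  m <- makeFixtureModel("RANDOM", seed = 11, size = 20)
  m <- fullConstrain(m, makeFixtureProfiles("RANDOM", seed = 11, size = 20)$target)
  tf <- tempfile(fileext = ".tsv")
  writeTabularModel(m, tf)
  expectModelsEqual(m, readTabularModel(tf))
})

test_that("SBML L3/fbc reader recovers species, bounds, genes and objective", {
  m <- readSBMLModel(system.file("extdata", "chain3_fbc.xml", package = "fluxwindow"))
  expect_equal(nReactions(m), 3L)
  expect_equal(nMetabolites(m), 2L)
  expect_identical(objectiveId(m), "BIOMASS")
  expect_equal(unname(lowerBounds(m)), c(-10, 0, 0))
  expect_equal(geneAssociations(m)$R1, "g1")
  # absence of a geneProductAssociation maps to an empty gene list
  expect_equal(geneAssociations(m)$EX_A, character(0))
  # SBML -> tabular -> model preserves the whole structure
  tf <- tempfile(fileext = ".tsv")
  writeTabularModel(m, tf)
  expectModelsEqual(m, readTabularModel(tf))
})

test_that("SBML without a declared objective needs an explicit one", {
  src <- readLines(system.file("extdata", "chain3_fbc.xml", package = "fluxwindow"))
  drop <- grep("listOfObjectives|fbc:objective|fluxObjective", src)
  tf <- tempfile(fileext = ".xml")
  writeLines(src[-drop], tf)
  expect_error(readSBMLModel(tf), "objective", class = "fw_config_error")
  m <- readSBMLModel(tf, objective = "BIOMASS")
  expect_identical(objectiveId(m), "BIOMASS")
  expect_error(readSBMLModel(tf, objective = "NOPE"), class = "fw_config_error")
})

test_that("legacy Level 2 COBRA dialect (kinetic-law bounds, notes genes) is read", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="toy">',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-5"/><parameter id="UPPER_BOUND" value="900"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (gA and gB) or gC</p></body></notes>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '</reaction>',
    '<reaction id="BIOMASS" reversible="false">',
    '<listOfReactants><speciesReference species="B"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>')
  tf <- tempfile(fileext = ".xml")
  writeLines(l2, tf)
  m <- readSBMLModel(tf, objective = "BIOMASS")
  expect_equal(unname(lowerBounds(m)[["EX_A"]]), -5)
  expect_equal(unname(upperBounds(m)[["EX_A"]]), 900)
  expect_equal(unname(lowerBounds(m)[["R1"]]), 0)   # irreversible default
  expect_setequal(geneAssociations(m)$R1, c("gA", "gB", "gC"))
})

test_that("flux tables round-trip bit-exactly, signs and header included", {
  fl <- new("FluxDistribution",
            fluxes = c(R1 = 1 / 3, EX_A = -2.5e-7, BIOMASS = 0.108),
            objectiveValue = 0.108, status = "optimal")
  tf <- tempfile(fileext = ".tsv")
  writeFluxTable(fl, tf, config = targetingConfig())
  back <- readFluxTable(tf)
  expect_identical(fluxes(back), fluxes(fl))            # bit-exact
  expect_identical(objectiveValue(back), 0.108)
  expect_true(fluxes(back)[["EX_A"]] < 0)
  hdr <- readLines(tf, n = 1)
  expect_match(hdr, "^# objective=")
  expect_match(hdr, sprintf("config=%s", configHash(targetingConfig())))

  empty <- new("FluxDistribution", fluxes = stats::setNames(numeric(0), character(0)),
               objectiveValue = NA_real_, status = "infeasible")
  writeFluxTable(empty, tf)
  expect_length(fluxes(readFluxTable(tf)), 0)
  expect_identical(solverStatus(readFluxTable(tf)), "infeasible")
})
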