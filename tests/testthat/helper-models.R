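# Small builders shared across test files.

# write a tabular model file from rows of "id\tequation\tlb\tub\tgenes\tobj"
writeModelTSV <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound\tgenes\tobjective",
               lines), path)
  path
}

# the reference-constrained form of a named fixture
constrainedFixture <- function(scenario, which = "reference", ...) {
  m <- makeFixtureModel(scenario, ...)
  pr <- makeFixtureProfiles(scenario, ...)
  fullConstrain(m, pr[[which]])
}

expectModelsEqual <- function(a, b) {
  expect_equal(reactionIds(a), reactionIds(b))
  expect_equal(metaboliteIds(a), metaboliteIds(b))
  expect_equal(as.matrix(stoichMatrix(a)), as.matrix(stoichMatrix(b)))
  expect_equal(lowerBounds(a), lowerBounds(b))
  expect_equal(upperBounds(a), upperBounds(b))
  expect_equal(geneAssociations(a), geneAssociations(b))
  expect_identical(objectiveId(a), objectiveId(b))
}
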