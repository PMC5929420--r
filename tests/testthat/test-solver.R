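test_that("FBA finds the chain bottleneck and reports degenerate statuses honestly", {
  mc <- constrainedFixture("CHAIN3", "target")
  f <- fba(mc)
  expect_identical(solverStatus(f), "optimal")
  expect_equal(objectiveValue(f), 0.108, tolerance = 1e-9)
  expect_equal(unname(fluxes(f)[["EX_A"]]), -0.108, tolerance = 1e-9)

  # closing the only uptake stops growth but stays feasible
  closed <- mc
  lowerBounds(closed)["EX_A"] <- 0
  upperBounds(closed)["EX_A"] <- 0
  expect_equal(objectiveValue(fba(closed)), 0, tolerance = 1e-9)

  # an unbounded production loop is reported, not raised
  loop <- readTabularModel(writeModelTSV(c(
    "MAKE\t-> X\t0\tInf\t\t0",
    "OBJ\tX ->\t0\tInf\t\t1")))
  fu <- fba(loop)
  expect_identical(solverStatus(fu), "unbounded")
  expect_length(fluxes(fu), 0)

  # infeasible demands are reported too
  inf <- mc
  lowerBounds(inf)["BIOMASS"] <- 1   # demand above the expression cap
  expect_identical(solverStatus(fba(inf)), "infeasible")
})

test_that("FBA matches the brute-force vertex oracle on every fixture", {
  for (scenario in c("CHAIN3", "PARALLEL", "SELECTIVE", "CYCLE")) {
    for (which in c("target", "reference")) {
      mc <- constrainedFixture(scenario, which)
      f <- fba(mc)
      expect_identical(solverStatus(f), "optimal")
      expect_equal(objectiveValue(f), bruteFBA(mc), tolerance = 1e-6,
                   label = sprintf("%s/%s objective", scenario, which))
      expect_true(checkSteadyState(mc, f))
    }
  }
})

test_that("pFBA achieves the optimum with minimal total flux", {
  # unique optimum: pFBA and FBA coincide on the chain
  mc <- constrainedFixture("CHAIN3", "target")
  expect_equal(objectiveValue(pfba(mc)), objectiveValue(fba(mc)), tolerance = 1e-6)

  # two equivalent routes: no flux-split inflation
  pc <- constrainedFixture("PARALLEL", "target")
  pf <- pfba(pc)
  z <- bruteFBA(pc)
  expect_gte(objectiveValue(pf), (1 - 1e-7) * z)
  expect_equal(sum(abs(fluxes(pf))), brutePFBASum(pc, z), tolerance = 1e-4)

  # a balanced futile cycle carries zero parsimonious flux
  cy <- constrainedFixture("CYCLE", "target")
  cf <- pfba(cy)
  expect_equal(unname(fluxes(cf)[c("C1", "C2")]), c(0, 0), tolerance = 1e-9)
  expect_equal(sum(abs(fluxes(cf))), brutePFBASum(cy, bruteFBA(cy)), tolerance = 1e-4)

  # a non-optimal first stage propagates its status
  inf <- mc
  lowerBounds(inf)["BIOMASS"] <- 1
  expect_identical(solverStatus(pfba(inf)), "infeasible")
})

test_that("FBA optimum scales linearly with the bounds", {
  for (scenario in c("CHAIN3", "SELECTIVE")) {
    mc <- constrainedFixture(scenario, "reference")
    z1 <- objectiveValue(fba(mc))
    for (alpha in c(0.25, 3)) {
      ms <- mc
      lowerBounds(ms) <- lowerBounds(mc) * alpha
      upperBounds(ms) <- upperBounds(mc) * alpha
      expect_equal(objectiveValue(fba(ms)), alpha * z1, tolerance = 1e-6)
    }
  }
})

test_that("alternative-optima sampling explores the optimal face deterministically", {
  # unique optimum: every flux pinned, sd ~ 0
  mc <- constrainedFixture("CHAIN3", "target")
  s0 <- sampleAlternativeOptima(mc, n = 20, seed = 5)
  expect_true(all(s0@sd < 1e-6))

  # degenerate parallel routes: spread on the routes, conservation of the total
  pc <- constrainedFixture("PARALLEL", "target")
  s <- sampleAlternativeOptima(pc, n = 50, seed = 7)
  expect_gt(s@sd[["R1"]], 0)
  expect_equal(s@mean[["R1"]] + s@mean[["R2"]], s@mean[["BIOMASS"]],
               tolerance = 1e-6)
  z <- objectiveValue(fba(pc))
  for (smp in s@samples) {
    expect_gte(objectiveValue(smp), (1 - 1e-7) * z)
    expect_true(checkSteadyState(pc, smp))
  }

  # determinism under the seed, and RNG state is not leaked
  set.seed(123); before <- stats::runif(1)
  s2 <- sampleAlternativeOptima(pc, n = 50, seed = 7)
  set.seed(123); after <- stats::runif(1)
  expect_identical(lapply(s@samples, fluxes), lapply(s2@samples, fluxes))
  expect_identical(before, after)

  expect_error(sampleAlternativeOptima(pc, n = 0), class = "fw_validation_error")
})
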