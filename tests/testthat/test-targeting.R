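test_that("throttling ratios distinguish coupled, compensated and idle reactions", {
  mc <- constrainedFixture("CHAIN3", "target")
  b <- pfba(mc)
  # fully coupled chain: the objective follows the throttle exactly
  expect_equal(blockReactions(mc, b, "R1")@ratio, 0.1, tolerance = 1e-6)
  # redundant route with spare capacity: full compensation
  pc <- constrainedFixture("PARALLEL", "target")
  pb <- pfba(pc)
  expect_equal(blockReactions(pc, pb, "R1")@ratio, 1.0, tolerance = 1e-6)
  # a zero-flux target closes a reaction nobody uses: no effect
  idle <- names(which(abs(fluxes(pb)) < 1e-9))[1]
  expect_equal(blockReactions(pc, pb, idle)@ratio, 1.0, tolerance = 1e-6)

  expect_error(blockReactions(mc, b, "NOPE"), class = "fw_validation_error")
  expect_error(blockReactions(mc, b, "R1", fraction = 1.5),
               class = "fw_validation_error")
})

test_that("throttling a superset of reactions never raises the growth ratio", {
  set.seed(77)
  models <- list(constrainedFixture("SELECTIVE", "reference"),
                 constrainedFixture("CYCLE", "target"))
  for (mc in models) {
    b <- pfba(mc)
    ids <- reactionIds(mc)
    for (rep in 1:10) {
      pair <- sample(ids, 2)
      r1 <- blockReactions(mc, b, pair[1])@ratio
      r2 <- blockReactions(mc, b, pair[2])@ratio
      r12 <- blockReactions(mc, b, pair)@ratio
      expect_lte(r12, min(r1, r2) + 1e-6)
      expect_gte(r12, 0.1 - 1e-6)   # zero-bracketing bounds keep 10% feasible
    }
  }
})

test_that("group screening separates coupled from compensated reactions", {
  tM <- constrainedFixture("SELECTIVE", "target")
  rM <- constrainedFixture("SELECTIVE", "reference")
  targets <- stats::setNames(list(tM, tM, tM), paste0("t", 1:3))
  refs <- stats::setNames(list(rM, rM, rM), paste0("r", 1:3))
  tab <- screenTargets(targets, refs, c("S", "T", "BIOMASS"))
  expect_equal(nrow(tab), 3L)
  sRow <- tab[tab$reaction_id == "S", ]
  expect_equal(sRow$mean_target, 0.1, tolerance = 1e-6)
  expect_equal(sRow$mean_reference, 1.0, tolerance = 1e-6)
  expect_equal(sRow$mean_diff, 0.9, tolerance = 1e-6)
  expect_lt(sRow$p, 0.05)
  # identical groups show no signal
  same <- screenTargets(refs, stats::setNames(refs, paste0("x", 1:3)), c("S", "BIOMASS"))
  expect_true(all(abs(same$p - 1) < 1e-9))
  # empty reaction list gives an empty table
  expect_equal(nrow(screenTargets(targets, refs, character(0))), 0L)
  expect_error(screenTargets(targets[1], refs, "S"), class = "fw_validation_error")
})

test_that("the greedy search recovers the selective vulnerability and nothing else", {
  tC <- constrainedFixture("SELECTIVE", "target")
  rC <- constrainedFixture("SELECTIVE", "reference")
  ts <- findTargetSet(tC, rC)
  expect_identical(acceptedTargets(ts), "S")
  expect_true(ts@converged)
  expect_equal(ts@finalTargetRatio, 0.1, tolerance = 1e-6)
  expect_equal(ts@finalReferenceRatio, 1.0, tolerance = 1e-6)
  tr <- decisionTrace(ts)
  expect_true(all(tr$target_ratio_after[tr$accepted] < 0.9))
  expect_true(all((tr$reference_ratio_after - tr$target_ratio_after)[tr$accepted] > 0.05))

  # symmetric profiles: selectivity is impossible, search exhausts candidates
  sym <- findTargetSet(rC, rC)
  expect_identical(acceptedTargets(sym), character(0))
  expect_false(sym@converged)
  expect_equal(sym@finalTargetRatio, 1.0)
})

test_that("relaxed thresholds accept the first passing candidate immediately", {
  tC <- constrainedFixture("SELECTIVE", "target")
  rC <- constrainedFixture("SELECTIVE", "reference")
  cfg <- targetingConfig(singleThreshold = 0.99, selectivityMargin = 0,
                         stopRatio = 0.98)
  ts <- findTargetSet(tC, rC, cfg)
  expect_true(ts@converged)
  expect_length(acceptedTargets(ts), 1L)
  # the one accepted candidate is the first trace row that passes the margin
  tr <- decisionTrace(ts)
  expect_identical(tr$reaction_id[tr$accepted], acceptedTargets(ts))
  expect_identical(tr$accepted[nrow(tr)], TRUE)
})

test_that("replaying the accepted constraints reproduces the final ratios", {
  tC <- constrainedFixture("SELECTIVE", "target")
  rC <- constrainedFixture("SELECTIVE", "reference")
  ts <- findTargetSet(tC, rC)
  bT <- pfba(tC); bR <- pfba(rC)
  repT <- blockReactions(tC, bT, acceptedTargets(ts))
  repR <- blockReactions(rC, bR, acceptedTargets(ts))
  expect_equal(repT@ratio, ts@finalTargetRatio, tolerance = 1e-6)
  expect_equal(repR@ratio, ts@finalReferenceRatio, tolerance = 1e-6)
})

test_that("the search refuses models without positive growth", {
  tC <- constrainedFixture("SELECTIVE", "target")
  dead <- tC
  upperBounds(dead)["BIOMASS"] <- 0
  expect_error(findTargetSet(dead, tC), class = "fw_contract_error")
  expect_error(findTargetSet(tC, dead), class = "fw_contract_error")
})
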