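test_that("Welch t matches the closed-form computation and pins degenerate cases", {
  o <- oracleWelch(c(1, 2, 3), c(4, 5, 6))
  w <- welchT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 3))
    y <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, -1, 1))
    o <- oracleWelch(x, y); w <- welchT(x, y)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
  }

  x <- c(2.5, 1.5, 3)
  same <- welchT(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welchT(c(1, 1), c(1, 1)), list(t = 0, p = 1, degenerate = FALSE))
  deg <- welchT(c(1, 1), c(2, 2))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(welchT(1, c(1, 2)), class = "fw_validation_error")
})

test_that("the Student variant uses the pooled-variance statistic", {
  # unequal group sizes: the pooled and Welch statistics genuinely differ
  x <- c(1, 2, 3, 7); y <- c(2, 4, 9, 12, 6)
  st <- welchT(x, y, pooled = TRUE)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(st$t, unname(ref$statistic), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(st$t, welchT(x, y)$t)))
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(0.5), 0.5)
  expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
  set.seed(17)
  p <- stats::runif(200)
  expect_equal(bhFDR(p), oracleBH(p), tolerance = 1e-10)
  perm <- sample(200)
  expect_equal(bhFDR(p[perm]), bhFDR(p)[perm])     # permutation-equivariant
  expect_true(all(bhFDR(p) >= p))
  expect_error(bhFDR(c(0.5, 1.2)), class = "fw_validation_error")
})

test_that("differential use flags a planted signal and nothing in pure noise", {
  set.seed(91)
  A <- matrix(stats::rnorm(10 * 5), nrow = 10)
  B <- matrix(stats::rnorm(10 * 5), nrow = 10)
  A[4, ] <- stats::rnorm(5, mean = 5, sd = 0.1)
  B[4, ] <- stats::rnorm(5, mean = 0, sd = 0.1)
  rownames(A) <- rownames(B) <- paste0("f", 1:10)
  tab <- differentialUse(A, B, fdrLevel = 0.01)
  expect_identical(tab$feature_id[tab$significant], "f4")
  expect_true(all(tab$q >= tab$p))

  none <- differentialUse(A, A, fdrLevel = 0.01)
  expect_false(any(none$significant))
  expect_true(all(abs(none$p - 1) < 1e-12))

  expect_error(differentialUse(A[, 1, drop = FALSE], B[, 1, drop = FALSE]),
               class = "fw_validation_error")
  expect_warning(differentialUse(A[1, , drop = FALSE], B[1, , drop = FALSE],
                                 featureIds = "f1"),
                 "fewer than 2 features")
})

test_that("hallmarks are significant reactions backed by a significant gene", {
  m <- makeFixtureModel("SELECTIVE")
  dr <- data.frame(feature_id = c("S", "T", "R1"),
                   q = c(0.001, 0.5, 0.002))
  dg <- data.frame(feature_id = c("gS", "gT", "g1"),
                   q = c(0.005, 0.001, 0.9))
  h <- hallmarks(dr, dg, m, fdrLevel = 0.01)
  # S: significant reaction + significant gene -> hallmark
  # R1: significant reaction, gene g1 not significant -> excluded
  # T: gene significant but reaction not -> excluded
  expect_identical(h$reaction_id, "S")
  expect_identical(h$genes, "gS")
  expect_equal(h$min_gene_q, 0.005)
  empty <- hallmarks(dr[dr$q > 0.1, , drop = FALSE], dg, m)
  expect_equal(nrow(empty), 0L)
})
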