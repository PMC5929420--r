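# Independent oracles used against the package's implementations.
#
# The LP oracle enumerates every basic feasible solution (vertex) of
# {A v = b, lb <= v <= ub} by brute force over basis/bound assignments; on the
# toy fixtures (<= 12 reactions) this is exhaustive, so the maximum over
# vertices IS the LP optimum and the minimum of sum(|v|) over vertices of the
# optimum-fixed polytope IS the parsimonious optimum.

enumVertices <- function(A, b, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  rk <- qr(A)$rank
  verts <- list()
  basisSets <- if (rk == 0) list(integer(0)) else asplit(utils::combn(n, rk), 2)
  for (B in basisSets) {
    B <- as.integer(B)
    AB <- A[, B, drop = FALSE]
    if (rk > 0 && qr(AB)$rank < rk) next
    nbs <- setdiff(seq_len(n), B)
    nAssign <- 2^length(nbs)
    for (mask in seq_len(nAssign) - 1L) {
      pickUpper <- as.logical(bitwAnd(mask, 2^(seq_along(nbs) - 1L)))
      xn <- ifelse(pickUpper, ub[nbs], lb[nbs])
      if (any(!is.finite(xn))) next
      rhs <- b - (if (length(nbs)) as.vector(A[, nbs, drop = FALSE] %*% xn) else 0)
      xb <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n)
      x[nbs] <- xn
      x[B] <- xb
      if (max(abs(A %*% x - b)) < tol && all(x >= lb - tol) && all(x <= ub + tol))
        verts[[length(verts) + 1L]] <- x
    }
  }
  if (!length(verts)) return(NULL)
  do.call(rbind, verts)
}

# brute-force FBA: maximum objective flux over all vertices
bruteFBA <- function(model, tol = 1e-8) {
  S <- as.matrix(stoichMatrix(model))
  oi <- match(objectiveId(model), reactionIds(model))
  V <- enumVertices(S, rep(0, nrow(S)),
                    lowerBounds(model), upperBounds(model), tol)
  if (is.null(V)) return(NULL)
  max(V[, oi])
}

# brute-force pFBA: minimal sum(|v|) over vertices with the objective pinned
brutePFBASum <- function(model, zstar, tol = 1e-8) {
  S <- as.matrix(stoichMatrix(model))
  oi <- match(objectiveId(model), reactionIds(model))
  n <- ncol(S)
  crow <- rep(0, n); crow[oi] <- 1
  V <- enumVertices(rbind(S, crow), c(rep(0, nrow(S)), zstar),
                    lowerBounds(model), upperBounds(model), tol)
  if (is.null(V)) return(NULL)
  min(rowSums(abs(V)))
}

# hand-coded Welch t and BH step-up, independent of stats::t.test/p.adjust
oracleWelch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df))
}

oracleBH <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[order(o)]
}

# feasibility of a flux distribution against a model, for invariant checks
checkSteadyState <- function(model, flux, tol = 1e-6) {
  v <- fluxes(flux)[reactionIds(model)]
  resid <- max(abs(as.vector(stoichMatrix(model) %*% v)))
  inLB <- all(v >= lowerBounds(model) - tol)
  inUB <- all(v <= upperBounds(model) + tol)
  resid < tol && inLB && inUB
}
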