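# Dense bounded-variable primal simplex.
#
# Solves  max/min  obj' x   s.t.  A x = b,  lb <= x <= ub
# with possibly infinite bounds, via a two-phase method with artificial
# variables and Bland's smallest-index anti-cycling rule. The problems this
# package generates are small (tens of variables), so a dense pure-R
# implementation is ample; it sits behind this single entry point so a
# different backend can be swapped in.
#
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, objval).

.solveLP <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  lb <- pmin(lb, ub)  # collapse inverted-by-rounding pairs

  # start nonbasic variables at a finite bound (free variables at 0)
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  stat0 <- ifelse(is.finite(lb), 1L, ifelse(is.finite(ub), 2L, 0L))
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)

  N <- n + m
  Afull <- cbind(A, diag(sgn, nrow = m, ncol = m))
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))

  basis <- n + seq_len(m)
  nbstat <- integer(N)                 # 1 at lower, 2 at upper, 0 free; basic entries ignored
  nbstat[seq_len(n)] <- stat0
  xval <- numeric(N)

  rebuild <- function() {
    nb <- setdiff(seq_len(N), basis)
    xnb <- ifelse(nbstat[nb] == 1L, LB[nb], ifelse(nbstat[nb] == 2L, UB[nb], 0))
    xval[nb] <<- xnb
    B <- Afull[, basis, drop = FALSE]
    rhs <- b - if (length(nb)) as.vector(Afull[, nb, drop = FALSE] %*% xnb) else numeric(m)
    xval[basis] <<- solve(B, rhs)
  }

  run <- function(cost) {
    for (it in seq_len(maxit)) {
      rebuild()
      B <- Afull[, basis, drop = FALSE]
      y <- solve(t(B), cost[basis])
      nb <- setdiff(seq_len(N), basis)
      d <- cost[nb] - as.vector(crossprod(Afull[, nb, drop = FALSE], y))
      fixed <- is.finite(LB[nb]) & is.finite(UB[nb]) & (UB[nb] - LB[nb]) < tol
      canUp <- (nbstat[nb] != 2L) & (d > tol) & !fixed
      canDn <- (nbstat[nb] != 1L) & (d < -tol) & !fixed
      elig <- canUp | canDn
      if (!any(elig)) return("optimal")
      e <- min(nb[elig])                              # Bland: smallest index enters
      de <- d[match(e, nb)]
      dir <- if (de > 0) 1 else -1
      w <- solve(B, Afull[, e])
      delta <- -dir * w                               # basic change per unit step

      tFlip <- if (is.finite(LB[e]) && is.finite(UB[e])) UB[e] - LB[e] else Inf
      xB <- xval[basis]
      tlim <- rep(Inf, m)
      dn <- delta < -tol                              # basic decreasing -> its lower bound
      up <- delta > tol                               # basic increasing -> its upper bound
      tlim[dn] <- ifelse(is.finite(LB[basis][dn]),
                         (xB[dn] - LB[basis][dn]) / (-delta[dn]), Inf)
      tlim[up] <- ifelse(is.finite(UB[basis][up]),
                         (UB[basis][up] - xB[up]) / delta[up], Inf)
      tlim[tlim < 0] <- 0                             # degeneracy guard
      tmin <- if (m) min(tlim) else Inf
      if (!is.finite(min(tmin, tFlip))) return("unbounded")

      if (tFlip <= tmin) {
        nbstat[e] <<- if (nbstat[e] == 1L) 2L else 1L # bound flip, basis unchanged
      } else {
        cand <- which(tlim <= tmin + tol * (1 + abs(tmin)))
        l <- cand[which.min(basis[cand])]             # Bland: smallest variable leaves
        leaving <- basis[l]
        nbstat[leaving] <<- if (delta[l] < 0) 1L else 2L
        basis[l] <<- e
      }
    }
    "maxit"
  }

  # Phase 1: drive artificials to zero.
  s1 <- run(c(rep(0, n), rep(-1, m)))
  if (s1 == "maxit")
    .fwError("LP solver exceeded its iteration limit in phase 1", "fw_solver_error")
  rebuild()
  if (sum(xval[n + seq_len(m)]) > 1e-7 * (1 + max(abs(b), 1)))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  UB[n + seq_len(m)] <- 0                             # pin artificials at zero
  nbstat[n + seq_len(m)][nbstat[n + seq_len(m)] == 0L] <- 1L

  # Phase 2: the real objective.
  cc <- if (maximize) obj else -obj
  s2 <- run(c(cc, rep(0, m)))
  if (s2 == "maxit")
    .fwError("LP solver exceeded its iteration limit in phase 2", "fw_solver_error")
  if (s2 == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
  rebuild()
  x <- xval[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(obj * x))
}
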