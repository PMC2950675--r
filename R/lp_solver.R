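#' Linear-programming core
#'
#' Bounded-variable two-phase primal simplex used by all flux balance
#' computations: minimize (or maximize) `c'x` subject to `A x = b` and
#' `lb <= x <= ub` with finite bounds. The basis inverse is maintained by
#' pivot updates with periodic refactorization; Dantzig pricing switches to
#' Bland's rule after a run of degenerate pivots to guarantee termination.
#'
#' This solver exists because flux models need exact vertex solutions of
#' small/medium LPs; it is fuzz-tested against a brute-force
#' vertex-enumeration oracle in the package test suite.
#'
#' @param cc Objective coefficient vector.
#' @param A Constraint matrix (dense or sparse), one row per equality.
#' @param b Right-hand side vector.
#' @param lb,ub Finite variable bounds.
#' @param maximize Maximize instead of minimize.
#' @param tol Pivot/feasibility tolerance.
#' @param warm Optional warm-start state (the `warm` element of a previous
#'   solution on the same constraint matrix and bounds); phase 1 is skipped
#'   when the recorded basis is still primal-feasible.
#' @return List with `status` (`"optimal"`, `"infeasible"`), `objective`
#'   (`NA` when not optimal), `x` (primal solution, `NULL` when not optimal)
#'   and `warm` (opaque warm-start state for follow-up solves).
#' @export
solve_lp <- function(cc, A, b, lb, ub, maximize = FALSE, tol = 1e-9, warm = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_lp requires finite variable bounds", call. = FALSE)
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL, warm = NULL))
  }
  lb <- pmin(lb, ub)
  obj <- if (maximize) -cc else cc
  if (m == 0) {
    x <- ifelse(obj > 0, lb, ub)
    val <- sum(obj * x)
    return(list(status = "optimal", objective = if (maximize) -val else val,
                x = x, warm = NULL))
  }

  # extended problem: m artificial columns, pinned to zero in phase 2
  start <- NULL
  if (!is.null(warm)) start <- warm_restore(warm, A, b, lb, ub, m, n, tol)
  if (is.null(start)) {
    # phase 1: artificial variables close the residual of a bound-feasible start
    x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
    r <- as.vector(b - A %*% x0)
    sgn <- ifelse(r >= 0, 1, -1)
    Aext <- cbind(A, diag(sgn, nrow = m))
    lbe <- c(lb, rep(0, m))
    ube <- c(ub, pmax(abs(r), 1) * 2)
    xe <- c(x0, abs(r))
    basis <- n + seq_len(m)
    cost1 <- c(rep(0, n), rep(1, m))
    st <- simplex_core(Aext, cost1, lbe, ube, xe, basis, tol)
    if (st$status != "optimal" ||
        sum(cost1 * st$x) > 1e-7 * max(1, max(abs(b)))) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL, warm = NULL))
    }
    ube[n + seq_len(m)] <- 0
    x2 <- st$x
    x2[n + seq_len(m)] <- 0
    start <- list(Aext = Aext, lbe = lbe, ube = ube, x = x2, basis = st$basis)
  }

  st2 <- simplex_core(start$Aext, c(obj, rep(0, m)), start$lbe, start$ube,
                      start$x, start$basis, tol)
  if (st2$status != "optimal") {
    return(list(status = st2$status, objective = NA_real_, x = NULL, warm = NULL))
  }
  x <- pmin(pmax(st2$x[seq_len(n)], lb), ub)
  val <- sum(obj * x)
  list(status = "optimal", objective = if (maximize) -val else val, x = x,
       warm = list(basis = st2$basis, x = st2$x, Aext = start$Aext,
                   lbe = start$lbe, ube = start$ube, n = n))
}

# Rebuild a primal-feasible start from a previous solution on the same A;
# returns NULL when the recorded basis is unusable (caller falls back to
# the cold two-phase start).
warm_restore <- function(warm, A, b, lb, ub, m, n, tol) {
  if (is.null(warm$basis) || warm$n != n) return(NULL)
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(0, m))
  x <- pmin(pmax(warm$x, lbe), ube)
  Bmat <- warm$Aext[, warm$basis, drop = FALSE]
  xB <- tryCatch({
    nonb <- setdiff(seq_len(n + m), warm$basis)
    solve(Bmat, b - warm$Aext[, nonb, drop = FALSE] %*% x[nonb])
  }, error = function(e) NULL)
  if (is.null(xB)) return(NULL)
  xB <- drop(xB)
  scale <- max(1, max(abs(b)))
  if (any(xB < lbe[warm$basis] - 1e-8 * scale) ||
      any(xB > ube[warm$basis] + 1e-8 * scale)) return(NULL)
  x[warm$basis] <- xB
  list(Aext = warm$Aext, lbe = lbe, ube = ube, x = x, basis = warm$basis)
}

simplex_core <- function(A, cost, lb, ub, x, basis, tol) {
  m <- nrow(A); n <- ncol(A)
  in_basis <- rep(FALSE, n); in_basis[basis] <- TRUE
  at_upper <- x >= (lb + ub) / 2  # only meaningful for nonbasic variables
  Binv <- tryCatch(solve(A[, basis, drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(Binv)) return(list(status = "singular", x = x, basis = basis))
  max_iter <- 200L * (m + n) + 2000L
  degen <- 0L; bland <- FALSE
  free <- lb < ub
  for (iter in seq_len(max_iter)) {
    if (iter %% 80L == 0L) {
      Binv <- tryCatch(solve(A[, basis, drop = FALSE]), error = function(e) Binv)
    }
    y <- drop(crossprod(Binv, cost[basis]))
    d <- cost - drop(y %*% A)
    cand <- which(!in_basis & free &
                    ((!at_upper & d < -tol) | (at_upper & d > tol)))
    if (length(cand) == 0) {
      return(list(status = "optimal", x = x, basis = basis))
    }
    j <- if (bland) cand[1] else cand[which.max(abs(d[cand]))]
    sigma <- if (at_upper[j]) -1 else 1
    w <- drop(Binv %*% A[, j])
    sw <- sigma * w
    xB <- x[basis]
    ratio <- rep(Inf, m)
    up <- sw > tol
    dn <- sw < -tol
    ratio[up] <- (xB[up] - lb[basis][up]) / sw[up]
    ratio[dn] <- (ub[basis][dn] - xB[dn]) / (-sw[dn])
    ratio[ratio < 0] <- 0
    t_flip <- ub[j] - lb[j]
    t_basic <- min(ratio)
    if (t_flip <= t_basic) {
      # entering variable swings to its other bound; basis unchanged
      x[basis] <- xB - sigma * t_flip * w
      x[j] <- if (at_upper[j]) lb[j] else ub[j]
      at_upper[j] <- !at_upper[j]
      degen <- if (t_flip < tol) degen + 1L else 0L
    } else {
      hits <- which(ratio <= t_basic + 1e-12)
      i_star <- if (bland) hits[which.min(basis[hits])] else hits[which.max(abs(sw[hits]))]
      t <- t_basic
      x[basis] <- xB - sigma * t * w
      x[j] <- x[j] + sigma * t
      leave <- basis[i_star]
      # snap the leaving variable onto the bound it hit
      if (sw[i_star] > 0) {
        x[leave] <- lb[leave]; at_upper[leave] <- FALSE
      } else {
        x[leave] <- ub[leave]; at_upper[leave] <- TRUE
      }
      in_basis[leave] <- FALSE
      in_basis[j] <- TRUE
      basis[i_star] <- j
      piv <- w[i_star]
      Binv[i_star, ] <- Binv[i_star, ] / piv
      other <- seq_len(m)[-i_star]
      if (length(other) > 0) {
        Binv[other, ] <- Binv[other, ] - outer(w[other], Binv[i_star, ])
      }
      degen <- if (t < tol) degen + 1L else 0L
    }
    if (degen > 40L) bland <- TRUE
  }
  list(status = "maxiter", x = x, basis = basis)
}
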