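# Linear programming core: a dense bounded-variable two-phase primal simplex.
#
# Every constraint-based operation in the package (FBA, FVA, loopless FVA,
# blocked-reaction detection, GIMME) reduces to LPs of the form
#
#   max / min  c'x   s.t.  A x = b,  lb <= x <= ub
#
# with a few dozen variables. Bounds are handled natively (variables are
# nonbasic at either bound), which keeps the basis at the number of rows of A.
# Phase 1 drives artificial variables out of the basis; redundant rows of A
# (metabolite conservation relations) simply leave their artificial basic at
# zero, where it is frozen for phase 2. The basis inverse is refactorised at
# every iteration via solve(), trading speed for numerical robustness; at the
# problem sizes this package targets that is far from the bottleneck.

#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x == b` and
#' `lb <= x <= ub`, using a two-phase primal simplex with Bland's rule as an
#' anti-cycling fallback. All bounds must be finite.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m; defaults to zeros, the steady-state
#'   case).
#' @param lb,ub finite lower/upper variable bounds (length n).
#' @param maximize logical; minimize when `FALSE`.
#' @param tol pivot tolerance.
#' @param max_iter iteration cap before giving up with an error.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (on the caller's scale) and `x` (primal solution, `NULL`
#'   unless optimal).
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  ub <- pmax(ub, lb)

  sense <- if (maximize) 1 else -1
  nt <- n + m                        # structural + artificial
  lbf <- c(lb, numeric(m))
  ubf <- c(ub, numeric(m))           # artificial ub filled below

  # start structurals at the bound of smaller magnitude
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_lower <- abs(lb) <= abs(ub)
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  xfull <- c(x, abs(r))
  ubf[(n + 1):nt] <- abs(r) + 1      # room enough; never needs to grow
  at_lower_full <- c(at_lower, rep(TRUE, m))

  basis <- (n + 1):nt
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))

  run_phase <- function(cost, allow, xfull, basis, is_basic, at_lower_full) {
    iter <- 0L
    bland_from <- 4L * nt
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit exceeded")
      B <- Afull[, basis, drop = FALSE]
      Binv_ok <- TRUE
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) { Binv_ok <<- FALSE; NULL })
      if (!Binv_ok) stop("singular basis encountered in simplex")
      d <- cost - as.vector(t(Afull) %*% y)
      cand_up <- which(!is_basic & allow & at_lower_full & d > tol)
      cand_dn <- which(!is_basic & allow & !at_lower_full & d < -tol)
      cand <- c(cand_up, cand_dn)
      if (length(cand) == 0L) {
        return(list(xfull = xfull, basis = basis, is_basic = is_basic,
                    at_lower_full = at_lower_full, optimal = TRUE))
      }
      if (iter > bland_from) {
        e <- min(cand)                               # Bland
      } else {
        e <- cand[which.max(abs(d[cand]))]           # Dantzig
      }
      sigma <- if (at_lower_full[e]) 1 else -1
      w <- solve(B, Afull[, e]) * sigma
      # ratio test
      t_own <- ubf[e] - lbf[e]
      t_best <- t_own
      leave <- 0L
      leave_to_lower <- TRUE
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (w[i] > tol) {
          lim <- (xfull[bi] - lbf[bi]) / w[i]
          if (lim < t_best - 1e-15) { t_best <- lim; leave <- i; leave_to_lower <- TRUE }
        } else if (w[i] < -tol) {
          lim <- (ubf[bi] - xfull[bi]) / (-w[i])
          if (lim < t_best - 1e-15) { t_best <- lim; leave <- i; leave_to_lower <- FALSE }
        }
      }
      if (!is.finite(t_best)) return(list(unbounded = TRUE))
      t_best <- max(t_best, 0)
      # apply step
      xfull[basis] <- xfull[basis] - w * t_best
      xfull[e] <- xfull[e] + sigma * t_best
      if (leave == 0L) {
        # entering variable runs to its other bound: status flip only
        at_lower_full[e] <- !at_lower_full[e]
      } else {
        lv <- basis[leave]
        is_basic[lv] <- FALSE
        at_lower_full[lv] <- leave_to_lower
        xfull[lv] <- if (leave_to_lower) lbf[lv] else ubf[lv]
        basis[leave] <- e
        is_basic[e] <- TRUE
      }
      # refresh basic values from scratch for robustness
      nb <- which(!is_basic)
      rhs <- b - as.vector(Afull[, nb, drop = FALSE] %*% xfull[nb])
      xfull[basis] <- solve(Afull[, basis, drop = FALSE], rhs)
    }
  }

  # phase 1: minimize sum of artificials (maximize the negative)
  cost1 <- c(numeric(n), rep(-1, m))
  allow1 <- rep(TRUE, nt)
  ph1 <- run_phase(cost1, allow1, xfull, basis, is_basic, at_lower_full)
  if (isTRUE(ph1$unbounded)) stop("phase-1 unbounded: internal error")
  art_sum <- sum(ph1$xfull[(n + 1):nt])
  if (art_sum > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  # freeze artificials at zero for phase 2
  xfull <- ph1$xfull
  basis <- ph1$basis
  is_basic <- ph1$is_basic
  at_lower_full <- ph1$at_lower_full
  ubf[(n + 1):nt] <- 0
  xfull[(n + 1):nt][!is_basic[(n + 1):nt]] <- 0
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))

  cost2 <- c(sense * obj, numeric(m))
  ph2 <- run_phase(cost2, allow2, xfull, basis, is_basic, at_lower_full)
  if (isTRUE(ph2$unbounded))
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  xs <- ph2$xfull[seq_len(n)]
  # snap tiny bound violations from round-off
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", objective = sum(obj * xs), x = xs)
}
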