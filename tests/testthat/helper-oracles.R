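# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the LP oracle enumerates basic solutions by
# brute force, and boot::simplex provides a second, independently
# implemented simplex for cross-checking.

# brute-force optimum of max/min c'x s.t. Ax = b, lb <= x <= ub by
# enumerating candidate vertices (nonbasic variables pinned at bounds)
brute_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- ncol(A)
  rk <- qr(A)$rank
  nfree <- n - rk
  best <- -Inf
  feas <- FALSE
  sense <- if (maximize) 1 else -1
  for (nb in utils::combn(n, nfree, simplify = FALSE)) {
    bs <- setdiff(seq_len(n), nb)
    B <- A[, bs, drop = FALSE]
    if (qr(B)$rank < rk) next
    for (mask in 0:(2^nfree - 1)) {
      vals <- ifelse(bitwAnd(mask, 2^(seq_len(nfree) - 1)) > 0, ub[nb], lb[nb])
      rhs <- b - if (nfree) as.vector(A[, nb, drop = FALSE] %*% vals) else 0
      xb <- tryCatch(qr.solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n)
      x[bs] <- xb
      x[nb] <- vals
      if (max(abs(A %*% x - b)) > 1e-7) next
      if (all(x >= lb - 1e-7 & x <= ub + 1e-7)) {
        feas <- TRUE
        best <- max(best, sense * sum(obj * x))
      }
    }
  }
  if (!feas) return(list(status = "infeasible"))
  list(status = "optimal", objective = sense * best)
}

# second-opinion simplex: boot::simplex on the shifted nonnegative form
boot_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  # x = v - lb >= 0; A x = b - A lb; x <= ub - lb
  # boot::simplex requires nonnegative right-hand sides: flip equality rows
  b2 <- b - as.vector(A %*% lb)
  neg <- b2 < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b2[neg] <- -b2[neg]
  r <- tryCatch(boot::simplex(a = obj, A1 = diag(ncol(A)), b1 = ub - lb,
                              A3 = A, b3 = b2, maxi = maximize),
                error = function(e) NULL)
  if (is.null(r) || r$solved != 1) return(list(status = "not_optimal"))
  list(status = "optimal", objective = sum(obj * (r$soln + lb)))
}

# brute-force FVA: per-reaction min/max via the enumeration oracle
brute_fva <- function(model, med = NULL) {
  model <- apply_medium(model, med)
  S <- stoichiometric_matrix(model)
  res <- t(vapply(seq_len(n_reactions(model)), function(i) {
    obj <- numeric(n_reactions(model))
    obj[i] <- 1
    lo <- brute_lp(obj, S, numeric(nrow(S)), model$reactions$lb,
                   model$reactions$ub, maximize = FALSE)
    hi <- brute_lp(obj, S, numeric(nrow(S)), model$reactions$lb,
                   model$reactions$ub, maximize = TRUE)
    c(lo$objective, hi$objective)
  }, numeric(2)))
  data.frame(reaction = model$reactions$id, min = res[, 1], max = res[, 2])
}

# random GPR tree over the given genes, depth-limited
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  args <- replicate(k, random_gpr(genes, depth - 1), simplify = FALSE)
  list(op = op, args = args)
}

# element-count balance oracle: sums parsed formulas directly
balance_oracle <- function(model, rid) {
  st <- model$stoichiometry[[rid]]
  idx <- match(names(st), model$metabolites$id)
  total <- list()
  for (k in seq_along(st)) {
    el <- parse_formula(model$metabolites$formula[idx[k]])
    for (s in names(el)) total[[s]] <- (total[[s]] %||0% 0) + st[[k]] * el[[s]]
  }
  all(abs(unlist(total)) < 1e-9) &&
    abs(sum(st * model$metabolites$charge[idx])) < 1e-9
}
`%||0%` <- function(a, b) if (is.null(a)) b else a
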