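# Dynamic FBA: batch fermentation simulated by iterating FBA over a fixed
# sampling grid with exponential biomass/substrate updates,
#
#   X(t+dt) = X(t) * exp(mu dt)
#   C(t+dt) = C(t) + v_EX * (M/1000) * X(t) * (exp(mu dt) - 1) / mu
#
# with the exchange-flux sign convention (uptake negative, so uptake lowers
# the concentration); at mu = 0 the analytic limit C + v*M/1000*X*dt is
# used. Exchange fluxes are in mmol/gdw/h, concentrations in g/L, hence the
# molar-mass/1000 conversion. When the primary substrate is exhausted the
# exchange bounds of accumulated products open for uptake, so diauxic
# re-consumption (ethanol after glucose) can occur.

#' Parameters of a dynamic FBA batch run
#'
#' Defaults follow conventional yeast batch fermentations: 20 g/L initial
#' substrate, 0.05 g/L inoculum, 50 h horizon sampled every 0.5 h, substrate
#' uptake capped at 2.28 mmol/gdw/h, oxygen per regime (1000 aerobic, 0.25
#' anaerobic).
#'
#' @param substrate_exchange exchange id of the primary substrate.
#' @param initial_substrate g/L.
#' @param initial_biomass g/L.
#' @param total_time h.
#' @param dt sampling interval, h.
#' @param substrate_uptake kinetic cap on substrate uptake, mmol/gdw/h.
#' @param o2_exchange exchange id of oxygen (NULL: no oxygen handling).
#' @param o2_uptake oxygen uptake bound, mmol/gdw/h.
#' @param products named numeric vector: product exchange id -> molar mass
#'   (g/mol) for tracked secretion products (they start at 0 g/L).
#' @param substrate_mass molar mass of the substrate (g/mol).
#' @param product_reuptake logical: open product uptake after substrate
#'   exhaustion (sequential, not simultaneous, utilization).
#' @return an object of class `dfba_params`.
#' @export
dfba_params <- function(substrate_exchange, substrate_mass,
                        initial_substrate = 20, initial_biomass = 0.05,
                        total_time = 50, dt = 0.5,
                        substrate_uptake = 2.28,
                        o2_exchange = NULL, o2_uptake = LK_BIG_BOUND,
                        products = numeric(), product_reuptake = TRUE) {
  stopifnot(initial_substrate > 0, initial_biomass > 0, total_time > 0,
            dt > 0, dt <= total_time, substrate_uptake > 0, o2_uptake >= 0,
            substrate_mass > 0)
  structure(list(substrate_exchange = substrate_exchange,
                 substrate_mass = substrate_mass,
                 initial_substrate = initial_substrate,
                 initial_biomass = initial_biomass,
                 total_time = total_time, dt = dt,
                 substrate_uptake = substrate_uptake,
                 o2_exchange = o2_exchange, o2_uptake = o2_uptake,
                 products = products, product_reuptake = product_reuptake),
            class = "dfba_params")
}

#' One concentration update step of dynamic FBA
#'
#' @param X biomass, g/L.
#' @param conc named numeric vector of species concentrations, g/L.
#' @param fluxes named exchange fluxes, mmol/gdw/h (uptake negative).
#' @param dt step, h.
#' @param mu specific growth rate, 1/h.
#' @param molar_mass named numeric vector, g/mol, same names as `conc`.
#' @return list with `X` (updated biomass), `conc` (updated concentrations,
#'   clamped at 0) and `clamped` (ids whose draw overshot the pool).
#' @export
step_update <- function(X, conc, fluxes, dt, mu, molar_mass) {
  growth <- exp(mu * dt)
  Xn <- X * growth
  # integral of X(t) over the step: X*(e^{mu dt}-1)/mu, with the mu -> 0 limit
  xint <- if (abs(mu) > 1e-12) X * (growth - 1) / mu else X * dt
  v <- fluxes[names(conc)]
  v[is.na(v)] <- 0
  newc <- conc + v * (molar_mass[names(conc)] / 1000) * xint
  clamped <- names(conc)[newc < 0]
  newc[newc < 0] <- 0
  list(X = Xn, conc = newc, clamped = clamped)
}

#' Uptake bound available from a finite pool
#'
#' Caps a kinetic uptake bound so that a full-step draw cannot exceed the
#' dissolved pool: `min(kinetic, conc * 1000 / (M * X * dt))`.
#'
#' @param conc concentration, g/L.
#' @param X biomass, g/L.
#' @param dt step, h.
#' @param molar_mass g/mol.
#' @param kinetic_bound configured uptake cap, mmol/gdw/h.
#' @return admissible uptake magnitude, mmol/gdw/h.
#' @export
availability_bound <- function(conc, X, dt, molar_mass, kinetic_bound) {
  stopifnot(conc >= 0, X >= 0, dt > 0, molar_mass > 0, kinetic_bound >= 0)
  if (X == 0) return(0)
  min(kinetic_bound, conc * 1000 / (molar_mass * X * dt))
}

#' Simulate a batch fermentation by dynamic FBA
#'
#' @param model a `metabolic_model`.
#' @param params a [dfba_params()].
#' @param med base [medium()] (nitrogen source, trace elements); the
#'   substrate, oxygen and product exchanges are managed by the simulation.
#' @return an object of class `batch_trajectory`: data.frame with columns
#'   `time`, `biomass`, `mu`, `substrate`, one column per product, plus a
#'   `flag` column ("" normally, "stationary" when FBA went infeasible,
#'   "clamped:<id>" when a pool was drawn below zero and clamped).
#' @export
simulate_batch <- function(model, params, med = NULL) {
  model <- apply_medium(model, med)
  sx <- params$substrate_exchange
  .rxn_index(model, c(sx, names(params$products), params$o2_exchange))
  if (!is.null(params$o2_exchange))
    model <- set_bounds(model, params$o2_exchange, lb = -params$o2_uptake)
  X <- params$initial_biomass
  conc <- c(stats::setNames(params$initial_substrate, sx),
            stats::setNames(rep(0, length(params$products)), names(params$products)))
  mm <- c(stats::setNames(params$substrate_mass, sx), params$products)
  times <- seq(0, params$total_time, by = params$dt)
  nT <- length(times)
  rows <- vector("list", nT)
  flags <- character(nT)
  mu <- 0
  for (k in seq_len(nT)) {
    rows[[k]] <- c(time = times[k], biomass = X, mu = mu, conc)
    if (k == nT) break
    # bounds for this interval: substrate from its pool; products open for
    # secretion always, for uptake only once the primary substrate is gone
    m2 <- set_bounds(model, sx,
      lb = -availability_bound(conc[[sx]], X, params$dt, mm[[sx]],
                               params$substrate_uptake))
    substrate_gone <- conc[[sx]] < 1e-9
    for (pid in names(params$products)) {
      up <- if (params$product_reuptake && substrate_gone)
        availability_bound(conc[[pid]], X, params$dt, mm[[pid]],
                           params$substrate_uptake) else 0
      m2 <- set_bounds(m2, pid, lb = -up)
    }
    sol <- fba(m2)
    flag <- ""
    if (sol$status != "optimal" || sol$objective < 0) {
      mu <- 0
      flag <- "stationary"
      fl <- stats::setNames(numeric(length(conc)), names(conc))
    } else {
      mu <- sol$objective
      fl <- sol$fluxes
    }
    st <- step_update(X, conc, fl, params$dt, mu, mm)
    if (length(st$clamped))
      flag <- paste(c(flag[nzchar(flag)],
                      paste0("clamped:", st$clamped)), collapse = ";")
    X <- st$X
    conc <- st$conc
    flags[k + 1L] <- flag
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time", "biomass", "mu", names(conc))
  out$flag <- flags
  structure(out, params = params,
            class = c("batch_trajectory", "data.frame"))
}

#' @export
print.batch_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat("Batch trajectory:", nrow(x), "samples over", max(x$time), "h\n")
  cat("  final biomass:", signif(x$biomass[nrow(x)], 5), "g/L\n")
  cat("  final", p$substrate_exchange, ":",
      signif(x[[p$substrate_exchange]][nrow(x)], 5), "g/L\n")
  invisible(x)
}

#' @export
plot.batch_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  species <- c(p$substrate_exchange, names(p$products))
  graphics::matplot(x$time, cbind(x$biomass, x[species]), type = "l", lty = 1,
                    xlab = "time (h)", ylab = "concentration (g/L)", ...)
  graphics::legend("topright", legend = c("biomass", species), lty = 1,
                   col = seq_len(length(species) + 1), cex = 0.8)
  invisible(x)
}
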