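# Comparison with experiment: growth-rate estimation from OD600 time
# courses, condition-table driven prediction runs, and correlation of
# predicted vs measured growth rates / respiratory quotients.

#' Estimate the specific growth rate from an OD time course
#'
#' mu = ln(OD(t_final) / OD(t_initial)) / (t_final - t_initial), positive
#' for growth. Natural log, consistent with the exponential-growth model
#' used by the batch simulation.
#'
#' @param series data.frame with columns `time` (h, strictly increasing) and
#'   `od` (OD600, > 0).
#' @param window length-2 vector `c(t_initial, t_final)`; both must be
#'   sampled time points. Defaults to the full series.
#' @return mu in 1/h.
#' @export
estimate_growth_rate <- function(series, window = range(series$time)) {
  stopifnot(all(diff(series$time) > 0), all(series$od > 0))
  if (window[2] <= window[1]) stop("t_final must exceed t_initial")
  i0 <- match(window[1], series$time)
  i1 <- match(window[2], series$time)
  if (is.na(i0) || is.na(i1))
    stop("window endpoints must be sampled time points")
  log(series$od[i1] / series$od[i0]) / (window[2] - window[1])
}

#' Run FBA over an experimental condition table
#'
#' One FBA per row, constraining the stated substrate and oxygen uptakes on
#' top of a base medium; predicted growth rate and respiratory quotient are
#' recorded next to the measured values. A failing row is marked and the
#' table continues.
#'
#' @param model a `metabolic_model`.
#' @param table data.frame with columns `condition`, `substrate_exchange`,
#'   `substrate_uptake`, `o2_uptake`, and optionally `measured_mu`,
#'   `measured_rq`.
#' @param base_medium [medium()] supplying nitrogen/trace components.
#' @param o2_exchange,co2_exchange exchange ids for the respiratory gases.
#' @return data.frame: the input plus `predicted_mu`, `predicted_rq`,
#'   `status`.
#' @export
run_condition_table <- function(model, table, base_medium,
                                o2_exchange, co2_exchange) {
  out <- table
  out$predicted_mu <- NA_real_
  out$predicted_rq <- NA_real_
  out$status <- "ok"
  for (k in seq_len(nrow(table))) {
    res <- tryCatch({
      up <- base_medium$uptake
      up[table$substrate_exchange[k]] <- table$substrate_uptake[k]
      up[o2_exchange] <- table$o2_uptake[k]
      sol <- fba(model, medium(paste0("cond_", table$condition[k]), up))
      if (sol$status != "optimal") stop("FBA ", sol$status)
      rq <- tryCatch(respiratory_quotient(sol, co2_exchange, o2_exchange),
                     error = function(e) NA_real_)
      list(mu = sol$objective, rq = rq)
    }, error = function(e) conditionMessage(e))
    if (is.list(res)) {
      out$predicted_mu[k] <- res$mu
      out$predicted_rq[k] <- res$rq
    } else {
      out$status[k] <- res
    }
  }
  out
}

#' Pearson correlation with a one-sided test for positive association
#'
#' @param predicted,measured numeric vectors (n >= 3, finite).
#' @return list with `r`, `p_value` (one-sided, H1: r > 0), `n`.
#' @export
correlate <- function(predicted, measured) {
  ok <- is.finite(predicted) & is.finite(measured)
  x <- predicted[ok]; y <- measured[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
  list(r = r, p_value = p, n = n)
}
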