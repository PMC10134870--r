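# Growth-rate, biomass-yield and substrate-uptake estimation from OD600 and
# substrate concentration time series.
#
# The specific growth rate over a window [t_start, t_end] is
#   mu = (ln OD(t_end) - ln OD(t_start)) / (t_end - t_start)   [h^-1]
# (natural log: mu only makes dimensional sense ln-based). Yield is
#   lambda = delta biomass (g/L) / delta substrate (mol/L)     [g/mol]
# and the specific uptake rate q = 1000 * mu / lambda          [mmol/gDW/h].

# OD600 -> cell dry weight conversion factors (g/L per OD unit) for the two
# growth temperatures, overridable per call.
DEFAULT_OD_FACTORS <- c("15C" = 0.74, "0C" = 0.66)

#' Specific growth rate from an OD600 time series
#'
#' Two-point log-ratio rate over a sampling window, computed on the
#' replicate-mean OD; per-replicate rates (and their s.d.) are attached
#' when replicate information is present.
#'
#' @param curve data.frame with columns `time_h`, `od600` and optionally
#'   `replicate` (a single condition's curve).
#' @param t_start,t_end window endpoints; must be sampled times with
#'   `t_start < t_end`.
#' @return list with `mu` (h^-1), `mu_replicates` (named vector or NULL)
#'   and `mu_sd`.
#' @export
growth_rate <- function(curve, t_start, t_end) {
  if (t_start >= t_end) stop("t_start must be strictly before t_end")
  if (any(curve$od600 <= 0)) stop("all OD600 values must be positive")
  for (t in c(t_start, t_end)) {
    if (!any(abs(curve$time_h - t) < 1e-9)) stop("time ", t, " h was not sampled")
  }
  od_at <- function(df, t) mean(df$od600[abs(df$time_h - t) < 1e-9])
  mu <- (log(od_at(curve, t_end)) - log(od_at(curve, t_start))) / (t_end - t_start)
  mu_reps <- NULL
  if (!is.null(curve$replicate)) {
    reps <- unique(curve$replicate)
    if (length(reps) > 1L) {
      mu_reps <- vapply(reps, function(rr) {
        df <- curve[curve$replicate == rr, ]
        (log(od_at(df, t_end)) - log(od_at(df, t_start))) / (t_end - t_start)
      }, numeric(1))
      names(mu_reps) <- as.character(reps)
    }
  }
  list(mu = mu, mu_replicates = mu_reps,
       mu_sd = if (is.null(mu_reps)) NA_real_ else stats::sd(mu_reps))
}

#' Convert OD600 to biomass concentration
#'
#' @param od600 OD600 reading(s), >= 0.
#' @param condition condition label, e.g. "15C" or "0C".
#' @param factors named conversion factors (g/L per OD unit);
#'   defaults to 0.74 at 15 degrees C and 0.66 at 0 degrees C.
#' @return biomass in g/L.
#' @export
od_to_biomass <- function(od600, condition, factors = DEFAULT_OD_FACTORS) {
  if (any(od600 < 0)) stop("OD600 must be >= 0")
  if (!condition %in% names(factors)) {
    stop("no OD-to-biomass factor configured for condition '", condition, "'")
  }
  od600 * factors[[condition]]
}

#' Substrate uptake rate from growth and consumption data
#'
#' Combines the window growth rate with the biomass yield on the substrate:
#' `q = 1000 * mu / lambda` in mmol/gDW/h.
#'
#' @param curve OD600 data.frame as in [growth_rate()], plus its condition
#'   label in a `condition` column (single condition).
#' @param substrate data.frame with columns `time_h`, `substrate_id`,
#'   `concentration` (mol/L) and optionally `replicate`.
#' @param substrate_id which substrate to estimate.
#' @param t_start,t_end estimation window (sampled times).
#' @param factors OD-to-biomass factors, see [od_to_biomass()].
#' @return list with `substrate_id`, `mu` (h^-1), `yield_lambda` (g/mol)
#'   and `uptake` (mmol/gDW/h).
#' @export
uptake_rate <- function(curve, substrate, substrate_id, t_start, t_end,
                        factors = DEFAULT_OD_FACTORS) {
  condition <- unique(curve$condition)
  if (length(condition) != 1L) stop("curve must contain a single condition")
  gr <- growth_rate(curve, t_start, t_end)
  conc_at <- function(t) {
    sel <- substrate$substrate_id == substrate_id & abs(substrate$time_h - t) < 1e-9
    if (!any(sel)) stop("substrate '", substrate_id, "' not measured at ", t, " h")
    mean(substrate$concentration[sel])
  }
  od_at <- function(t) mean(curve$od600[abs(curve$time_h - t) < 1e-9])
  d_biomass <- od_to_biomass(od_at(t_end), condition, factors) -
    od_to_biomass(od_at(t_start), condition, factors)
  d_subst <- conc_at(t_start) - conc_at(t_end)
  if (d_subst <= 0) {
    stop("no substrate consumption for '", substrate_id,
         "' in the window; yield undefined")
  }
  yield_lambda <- d_biomass / d_subst
  list(substrate_id = substrate_id, mu = gr$mu, mu_sd = gr$mu_sd,
       yield_lambda = yield_lambda, uptake = 1000 * gr$mu / yield_lambda)
}
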