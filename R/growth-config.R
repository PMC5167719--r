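# Simulation constants for the fruit quality model. Everything a practitioner
# might reasonably recalibrate lives here, with literature-style peach
# defaults; the genotype-dependent quantities are the seven parameters in
# `fruit_parameters`, never in the config.

#' Growth-model configuration
#'
#' Constants of the fruit quality simulation. Defaults describe a peach
#' fruit followed from 87 to 150 days after bloom (DAB), on a daily grid,
#' with thermal time in growing degree-days (GDD).
#'
#' @param dm0 Initial fruit dry mass (g) at the start of the window.
#' @param dj0 Thermal time (GDD) corresponding to `dm0`. `NULL` (default)
#'   means "the cumulative GDD of the weather series at `start_dab`".
#' @param start_dab,end_dab Simulation window in days after bloom.
#' @param alpha Growth respiration coefficient (gC per g dry mass).
#' @param beta Carbon concentration of fruit biomass (gC per g dry mass).
#' @param ksugar Relative rate of carbon leaving the sugar pool for other
#'   compounds (per day). Genotype-independent here.
#' @param sigma_ts Mean carbon content of sugars (gC per g sugars), averaged
#'   over sucrose, glucose, fructose, sorbitol.
#' @param dmc Flesh dry matter content (g DM per g FM); closes the fresh-mass
#'   computation as `FMflesh = DMflesh / dmc`.
#' @param f0 Initial fraction of flesh structural carbon present as sugars;
#'   sets the sugar ODE initial condition `Csugar(t0) = f0 * beta * DMflesh(t0)`.
#' @param step Integration step (days).
#' @param base_temp Base temperature (deg C) for GDD accumulation.
#' @param asymptote_form How the logistic asymptote scale combines `A`, `B`
#'   and `dm0`: `"power"` for `A * dm0^B` (default) or `"product"` for
#'   `A * dm0 * B`.
#' @param sla_ref Optional reference specific leaf area (m2/g). When set, the
#'   realized growth is multiplied by `min(1, SLA / sla_ref)` so that a low
#'   leaf area can limit the carbon source; `NULL` (default) simulates a
#'   non-limiting source, under which SLA does not affect the three traits.
#' @param sr_max Maximum realizable stone share of fruit dry mass. The stone
#'   allometry alone can ask for more dry mass than the fruit holds when
#'   `kstone * Wstone` is large and the fruit still small; the realized stone
#'   mass is capped at `sr_max * DMfruit`, which keeps flesh mass positive
#'   and the stone ratio inside (0, 1) for every parameter combination.
#' @return A validated list of class `growth_config`.
#' @export
growth_config <- function(dm0 = 2, dj0 = NULL, start_dab = 87, end_dab = 150,
                          alpha = 0.08, beta = 0.44, ksugar = 0.05,
                          sigma_ts = 0.42, dmc = 0.15, f0 = 0.5, step = 1,
                          base_temp = 0,
                          asymptote_form = c("power", "product"),
                          sla_ref = NULL, sr_max = 0.9) {
  asymptote_form <- match.arg(asymptote_form)
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  for (nm in c("dm0", "alpha", "beta", "ksugar", "sigma_ts", "dmc", "f0", "step")) {
    check_pos(get(nm), nm)
  }
  if (dmc >= 1) abort("`dmc` must be in (0, 1).")
  if (end_dab <= start_dab) abort("`end_dab` must exceed `start_dab`.")
  if (!is.null(sla_ref)) check_pos(sla_ref, "sla_ref")
  check_pos(sr_max, "sr_max")
  if (sr_max >= 1) abort("`sr_max` must be in (0, 1).")
  structure(
    list(
      dm0 = dm0, dj0 = dj0, start_dab = start_dab, end_dab = end_dab,
      alpha = alpha, beta = beta, ksugar = ksugar, sigma_ts = sigma_ts,
      dmc = dmc, f0 = f0, step = step, base_temp = base_temp,
      asymptote_form = asymptote_form, sla_ref = sla_ref, sr_max = sr_max
    ),
    class = "growth_config"
  )
}

#' Synthetic constant-temperature weather series
#'
#' A packaged stand-in for a season's weather record: constant daily mean
#' temperature over the whole season, which makes thermal time linear in
#' calendar time. Any real weather table with columns `day` (DAB) and
#' `tmean` (deg C) can be used instead; see [read_weather()].
#'
#' @param days Day axis (days after bloom).
#' @param tmean Daily mean temperature(s), recycled to `length(days)`.
#' @return A tibble with columns `day`, `tmean`.
#' @export
synthetic_weather <- function(days = 0:160, tmean = 22) {
  tibble(day = days, tmean = rep_len(tmean, length(days)))
}

#' Cumulative growing degree-days of a weather series
#'
#' @param weather Tibble with columns `day` and `tmean` (and optionally a
#'   precomputed `gdd` column, returned as-is).
#' @param base_temp Base temperature (deg C).
#' @return The weather tibble with a non-decreasing `gdd` column anchored at
#'   zero on the first day.
#' @export
accumulate_gdd <- function(weather, base_temp = 0) {
  weather <- as_tibble(weather)
  stopifnot(all(c("day", "tmean") %in% names(weather)))
  if (is.unsorted(weather$day, strictly = TRUE)) {
    abort("`weather$day` must be strictly increasing.")
  }
  if ("gdd" %in% names(weather)) {
    if (is.unsorted(weather$gdd)) abort("Precomputed `gdd` must be non-decreasing.")
    return(weather)
  }
  inc <- pmax(weather$tmean - base_temp, 0)
  weather$gdd <- cumsum(inc) - inc[1]
  weather
}

# Interpolators day -> GDD and day -> GDD rate (piecewise constant).
thermal_time <- function(weather, config) {
  w <- accumulate_gdd(weather, config$base_temp)
  if (max(w$day) < config$end_dab || min(w$day) > config$start_dab) {
    abort("Weather series does not cover the simulation window.")
  }
  gdd_fun <- approxfun(w$day, w$gdd, rule = 2)
  rate <- diff(w$gdd) / diff(w$day)
  rate_fun <- approxfun(head(w$day, -1), rate, method = "constant", rule = 2)
  dj0 <- if (is.null(config$dj0)) gdd_fun(config$start_dab) else config$dj0
  list(gdd = gdd_fun, rate = rate_fun, dj0 = dj0)
}

# Accept a one-row data frame, named vector or list of the seven parameters.
as_fruit_parameters <- function(p) {
  if (is.data.frame(p)) {
    if (nrow(p) != 1) abort("Expected a single parameter set (one row).")
    p <- unlist(p[, intersect(names(p), param_names())])
  }
  p <- unlist(p)
  missing <- setdiff(param_names(), names(p))
  if (length(missing) > 0) {
    abort(paste0("Missing fruit parameter(s): ", paste(missing, collapse = ", ")))
  }
  p <- p[param_names()]
  if (any(!is.finite(p)) || any(p <= 0)) {
    abort("All fruit parameters must be finite and strictly positive.")
  }
  p
}
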