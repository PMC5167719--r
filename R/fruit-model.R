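# Process-based fruit quality model: logistic dry-mass growth in thermal
# time, exponential stone allometry, and a linear carbon-balance ODE for the
# flesh sugar pool. The carbon source is demand-driven: realized growth
# follows the logistic potential, and the flesh carbon supply covers the
# structural carbon plus growth respiration of the realized flesh growth.

# logistic asymptote scale; optional SLA-limited source multiplier
asymptote_scale <- function(pars, config, dm0 = config$dm0) {
  s <- switch(config$asymptote_form,
    power = pars[["A"]] * dm0^pars[["B"]],
    product = pars[["A"]] * dm0 * pars[["B"]]
  )
  if (!is.null(config$sla_ref)) {
    s <- s * pmin(1, pars[["SLA"]] / config$sla_ref)
  }
  s
}

#' Fruit dry mass at a thermal time (logistic growth)
#'
#' Logistic potential growth in growing degree-days, anchored so that the
#' mass at `dj0` is exactly `dm0`. `plogis()` keeps the logistic terms finite
#' for arbitrarily large |dj|.
#'
#' @param dj Thermal time(s), GDD.
#' @param pars Fruit parameters (named vector or one-row data frame with
#'   `A`, `B`, `RGRini`, `P3`, `kstone`, `Wstone`, `SLA`).
#' @param config A [growth_config()].
#' @param dj0,dm0 Initial thermal time and the dry mass there; default from
#'   `config` (with `dj0 = config$dj0`, which must then be non-`NULL`).
#' @return Fruit dry mass (g), vectorized over `dj`; strictly increasing in
#'   `dj` for positive parameters.
#' @export
dm_fruit <- function(dj, pars, config = growth_config(),
                     dj0 = config$dj0, dm0 = config$dm0) {
  pars <- as_fruit_parameters(pars)
  if (is.null(dj0)) abort("`dj0` is required (set it in the config or pass it).")
  asym <- asymptote_scale(pars, config, dm0)
  r <- pars[["RGRini"]]; p3 <- pars[["P3"]]
  dm0 + asym * (plogis(r * (dj - p3)) - plogis(r * (dj0 - p3)))
}

# d(DMfruit)/d(dj), same anchoring
dm_fruit_rate_gdd <- function(dj, pars, config, dm0 = config$dm0) {
  asym <- asymptote_scale(pars, config, dm0)
  s <- plogis(pars[["RGRini"]] * (dj - pars[["P3"]]))
  asym * pars[["RGRini"]] * s * (1 - s)
}

#' Stone dry mass from fruit dry mass (exponential allometry)
#'
#' `DMstone = Wstone * (1 - exp(-kstone * DMfruit))`: the stone saturates at
#' its potential maximal mass `Wstone`.
#'
#' @param dmfruit Fruit dry mass(es), g.
#' @inheritParams dm_fruit
#' @return Stone dry mass (g), in `[0, Wstone)`.
#' @export
dm_stone <- function(dmfruit, pars) {
  pars <- as_fruit_parameters(pars)
  if (any(dmfruit < 0)) abort("`dmfruit` must be non-negative.")
  pars[["Wstone"]] * (1 - exp(-pars[["kstone"]] * dmfruit))
}

#' Stone-to-fruit dry mass ratio at a thermal time
#'
#' Composition of [dm_fruit()] and [dm_stone()].
#'
#' @inheritParams dm_fruit
#' @return Stone ratio, dimensionless.
#' @export
stone_ratio <- function(dj, pars, config = growth_config(),
                        dj0 = config$dj0, dm0 = config$dm0) {
  dm <- dm_fruit(dj, pars, config, dj0, dm0)
  if (any(dm <= 0)) abort("Fruit dry mass must be positive to form a stone ratio.")
  dm_stone(dm, pars) / dm
}

# Realized stone mass: the allometric demand capped at sr_max * DMfruit so
# flesh mass stays positive for every parameter combination.
dm_stone_realized <- function(dmfruit, wstone, kstone, sr_max) {
  pmin(wstone * (1 - exp(-kstone * dmfruit)), sr_max * dmfruit)
}

#' Flesh carbon supply at a calendar time
#'
#' Demand-driven closure of the carbon source: the supply equals
#' `(alpha + beta) * d(DMflesh)/dt`, i.e. the structural carbon plus growth
#' respiration of the realized flesh growth. Flesh growth is the fruit
#' growth minus the realized stone growth, evaluated analytically from the
#' logistic and allometric derivatives and the GDD accumulation rate of the
#' weather series.
#'
#' @param t Calendar time(s), days after bloom.
#' @inheritParams dm_fruit
#' @param weather Weather series (see [synthetic_weather()]).
#' @return Carbon supply (gC per day), non-negative.
#' @export
flesh_carbon_supply <- function(t, pars, config = growth_config(),
                                weather = synthetic_weather()) {
  pars <- as_fruit_parameters(pars)
  tt <- thermal_time(weather, config)
  (config$alpha + config$beta) *
    flesh_growth_rate(t, pars, config, tt, config$dm0)
}

# d(DMflesh)/dt, analytic (vectorized over t or over individuals)
flesh_growth_rate <- function(t, pars, config, tt, dm0) {
  dj <- tt$gdd(t)
  dm <- dm_fruit(dj, pars, config, tt$dj0, dm0)
  rate_dm <- dm_fruit_rate_gdd(dj, pars, config, dm0) * tt$rate(t)
  ws <- pars[["Wstone"]]; ks <- pars[["kstone"]]
  capped <- ws * (1 - exp(-ks * dm)) > config$sr_max * dm
  share <- ifelse(capped, config$sr_max, ws * ks * exp(-ks * dm))
  rate_dm * (1 - share)
}

#' Integrate the sugar carbon balance
#'
#' Solves `dCsugar/dt = FCsupp(t) * (1 - alpha/(alpha+beta)) - ksugar * Csugar`
#' with a classical fixed-step 4th-order Runge-Kutta scheme
#' (`deSolve::ode(method = "rk4")`).
#'
#' @param fcsupp The flesh carbon supply: either a function of time (gC/day;
#'   full 4th-order accuracy) or a data frame with columns `day` and
#'   `fc_supp`, interpolated linearly.
#' @param times Output time grid (days); the integration step is the grid
#'   spacing.
#' @param csugar0 Initial sugar carbon (gC) at `times[1]`. May be a vector to
#'   integrate many independent fruits at once (then `fcsupp(t)` must return
#'   a vector of matching length).
#' @param config A [growth_config()].
#' @return A tibble with columns `day` and `c_sugar` (or a `day` column plus
#'   one column per fruit when `csugar0` has length > 1).
#' @export
integrate_sugar <- function(fcsupp, times, csugar0, config = growth_config()) {
  if (is.data.frame(fcsupp)) {
    stopifnot(all(c("day", "fc_supp") %in% names(fcsupp)))
    fcsupp <- approxfun(fcsupp$day, fcsupp$fc_supp, rule = 2)
  }
  stopifnot(is.function(fcsupp))
  gain <- 1 - config$alpha / (config$alpha + config$beta)
  deriv <- function(t, y, parms) list(fcsupp(t) * gain - config$ksugar * y)
  out <- deSolve::ode(y = csugar0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  sol <- out[, -1, drop = FALSE]
  if (min(sol) < -1e-12 * max(abs(sol), 1)) {
    abort("Sugar carbon went negative during integration; use a smaller step.")
  }
  res <- as_tibble(as.data.frame(out))
  names(res)[1] <- "day"
  if (length(csugar0) == 1) names(res)[2] <- "c_sugar"
  res
}

#' Sugar concentration of the flesh
#'
#' `SU = 100 * Csugar / (sigma_ts * FMflesh)`, in g per 100 g fresh mass.
#'
#' @param csugar Sugar carbon (gC).
#' @param fmflesh Flesh fresh mass (g), positive.
#' @param config A [growth_config()].
#' @return Sugar concentration, g (100 g FM)^-1.
#' @export
sugar_concentration <- function(csugar, fmflesh, config = growth_config()) {
  if (any(fmflesh <= 0)) abort("`fmflesh` must be positive.")
  100 * csugar / (config$sigma_ts * fmflesh)
}

#' Simulate the full fruit trajectory
#'
#' Runs the growth, stone and sugar equations over the simulation window on
#' the configured time grid.
#'
#' @inheritParams flesh_carbon_supply
#' @return A tibble of class `fruit_trajectory`, one row per time step, with
#'   columns `day`, `dj` (GDD), `dm_fruit`, `dm_stone`, `dm_flesh` (g),
#'   `fc_supp` (gC/day), `c_sugar` (gC), `fm_flesh` (g), `sr` and `su`.
#' @export
simulate_trajectory <- function(pars, config = growth_config(),
                                weather = synthetic_weather()) {
  pars <- as_fruit_parameters(pars)
  tt <- thermal_time(weather, config)
  times <- seq(config$start_dab, config$end_dab, by = config$step)
  dj <- tt$gdd(times)
  dm <- dm_fruit(dj, pars, config, tt$dj0, config$dm0)
  stone <- dm_stone_realized(dm, pars[["Wstone"]], pars[["kstone"]], config$sr_max)
  flesh <- dm - stone
  fcs <- (config$alpha + config$beta) *
    flesh_growth_rate(times, pars, config, tt, config$dm0)
  c0 <- config$f0 * config$beta * flesh[1]
  sugar <- integrate_sugar(
    function(t) (config$alpha + config$beta) *
      flesh_growth_rate(t, pars, config, tt, config$dm0),
    times, c0, config
  )
  fm <- flesh / config$dmc
  out <- tibble(
    day = times, dj = dj, dm_fruit = dm, dm_stone = stone, dm_flesh = flesh,
    fc_supp = fcs, c_sugar = sugar$c_sugar, fm_flesh = fm,
    sr = stone / dm, su = sugar_concentration(sugar$c_sugar, fm, config)
  )
  class(out) <- c("fruit_trajectory", class(out))
  out
}

#' Simulate the phenotype triplet of one parameter set
#'
#' Runs the model over the window and reports the three target traits at the
#' final date: fruit dry mass `DM` (g), stone ratio `SR` (dimensionless) and
#' flesh sugar concentration `SU` (g per 100 g FM).
#'
#' @inheritParams flesh_carbon_supply
#' @param trajectory If `TRUE`, attach the full trajectory as attribute
#'   `"trajectory"`.
#' @return A one-row tibble with columns `DM`, `SR`, `SU`.
#' @export
simulate_phenotype <- function(pars, config = growth_config(),
                               weather = synthetic_weather(),
                               trajectory = FALSE) {
  traj <- simulate_trajectory(pars, config, weather)
  last <- traj[nrow(traj), ]
  out <- tibble(DM = last$dm_fruit, SR = last$sr, SU = last$su)
  if (trajectory) attr(out, "trajectory") <- traj
  out
}

#' Simulate phenotypes for many parameter sets at once
#'
#' Vectorized version of [simulate_phenotype()]: all individuals share the
#' weather and configuration, and the sugar ODE is integrated for the whole
#' batch in one fixed-step Runge-Kutta pass. This is what the optimizer, the
#' random-draw datasets and the exhaustive allele enumeration call.
#'
#' @param params Data frame or matrix of fruit parameters, one row per
#'   individual, columns `A`, `B`, `RGRini`, `P3`, `kstone`, `Wstone`, `SLA`.
#' @inheritParams flesh_carbon_supply
#' @param chunk_size Individuals integrated per pass (memory guard).
#' @return A tibble with one row per individual and columns `DM`, `SR`, `SU`.
#' @export
simulate_phenotypes <- function(params, config = growth_config(),
                                weather = synthetic_weather(),
                                chunk_size = 32768L) {
  P <- as_parameter_matrix(params)
  n <- nrow(P)
  if (n == 0) return(tibble(DM = numeric(), SR = numeric(), SU = numeric()))
  tt <- thermal_time(weather, config)
  starts <- seq(1L, n, by = chunk_size)
  res <- lapply(starts, function(s) {
    idx <- s:min(s + chunk_size - 1L, n)
    phenotype_batch(P[idx, , drop = FALSE], config, tt)
  })
  bind_rows(res)
}

as_parameter_matrix <- function(params) {
  if (is.data.frame(params)) {
    missing <- setdiff(param_names(), names(params))
    if (length(missing) > 0) {
      abort(paste0("Missing fruit parameter column(s): ", paste(missing, collapse = ", ")))
    }
    P <- as.matrix(params[, param_names()])
  } else {
    P <- as.matrix(params)
    if (is.null(colnames(P))) {
      if (ncol(P) != 7) abort("Parameter matrix must have 7 columns.")
      colnames(P) <- param_names()
    } else {
      P <- P[, param_names(), drop = FALSE]
    }
  }
  storage.mode(P) <- "double"
  if (anyNA(P) || any(P <= 0)) abort("All fruit parameters must be positive.")
  P
}

# Vectorized core: one RK4 integration over the window for a whole block of
# individuals, with the forcing evaluated analytically at every sub-step.
phenotype_batch <- function(P, config, tt) {
  A <- P[, "A"]; B <- P[, "B"]; R <- P[, "RGRini"]; P3 <- P[, "P3"]
  ks <- P[, "kstone"]; ws <- P[, "Wstone"]; sla <- P[, "SLA"]
  dm0 <- config$dm0
  asym <- switch(config$asymptote_form,
    power = A * dm0^B,
    product = A * dm0 * B
  )
  if (!is.null(config$sla_ref)) asym <- asym * pmin(1, sla / config$sla_ref)
  s0 <- plogis(R * (tt$dj0 - P3))
  gain <- 1 - config$alpha / (config$alpha + config$beta)
  supply_gain <- (config$alpha + config$beta) * gain
  srm <- config$sr_max

  dmf <- function(t) {
    dm0 + asym * (plogis(R * (tt$gdd(t) - P3)) - s0)
  }
  flesh_rate <- function(t) {
    s <- plogis(R * (tt$gdd(t) - P3))
    dm <- dm0 + asym * (s - s0)
    rate <- asym * R * s * (1 - s) * tt$rate(t)
    capped <- ws * (1 - exp(-ks * dm)) > srm * dm
    share <- ifelse(capped, srm, ws * ks * exp(-ks * dm))
    rate * (1 - share)
  }

  times <- seq(config$start_dab, config$end_dab, by = config$step)
  dm_start <- dmf(times[1])
  stone_start <- dm_stone_realized(dm_start, ws, ks, srm)
  c0 <- config$f0 * config$beta * (dm_start - stone_start)

  # fixed-step RK4 on the daily grid, forcing evaluated at sub-steps
  y <- c0
  h <- config$step
  deriv <- function(t, y) supply_gain * flesh_rate(t) - config$ksugar * y
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]
    k1 <- deriv(t0, y)
    k2 <- deriv(t0 + h / 2, y + h / 2 * k1)
    k3 <- deriv(t0 + h / 2, y + h / 2 * k2)
    k4 <- deriv(t0 + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  dm_end <- dmf(times[length(times)])
  stone_end <- dm_stone_realized(dm_end, ws, ks, srm)
  flesh_end <- dm_end - stone_end
  fm_end <- flesh_end / config$dmc
  tibble(
    DM = dm_end,
    SR = stone_end / dm_end,
    SU = 100 * y / (config$sigma_ts * fm_end)
  )
}

#' Objective triple of phenotypes
#'
#' Converts trait columns to the minimized objective vector
#' `(-DM, SR, -SU)`: dry mass and sugar are maximized, stone ratio
#' minimized.
#'
#' @param phenotypes Data frame with columns `DM`, `SR`, `SU`.
#' @return A numeric matrix with columns `obj1`, `obj2`, `obj3`.
#' @export
phenotype_objectives <- function(phenotypes) {
  m <- cbind(obj1 = -phenotypes$DM, obj2 = phenotypes$SR, obj3 = -phenotypes$SU)
  m
}
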