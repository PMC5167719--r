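# Synthetic stand-in for the BC2 mapping progeny: genotypes with linkage
# between close loci, parameter values with a controlled genetic share of
# the variance, weekly phenotype kinetics with observation noise, and the
# two estimation stages (nonlinear curve fitting per individual, allele-
# effect regression) that turn such data back into a genetic model.

#' Synthetic-progeny specification
#'
#' Describes the backcross progeny the generator emulates: in a BC2 between
#' a wild donor (D) and a cultivated recurrent parent (S), the expected wild
#' allele frequency at a locus is 1/4. QTL explain only part of the
#' parameter variance (here 10-50% depending on the parameter), so a
#' non-genetic noise share is added on top of the genetic prediction.
#'
#' @param n_individuals Progeny size.
#' @param wild_allele_freq Probability of the wild D allele (coded 0).
#' @param variance_explained Named fractions in (0, 1] per parameter: the
#'   share of the parameter variance attributable to the genetic model
#'   (1 means no non-genetic noise).
#' @param recombination_rate Probability that an allele within a haplotype
#'   block is redrawn rather than copied from its neighbour (per adjacent
#'   inseparable pair). Loci under 12.5 cM apart are tightly but not
#'   absolutely linked; a rate of 0 gives strict co-inheritance.
#' @param fruits_per_individual Fruits monitored per tree; each fruit has
#'   its own initial dry mass, which is what makes the asymptote parameters
#'   `A` and `B` separately identifiable from growth curves.
#' @param dm0_range Range (g) of per-fruit initial dry mass, drawn uniform.
#' @param obs_interval Days between phenotype observations (weekly = 7).
#' @param noise_dm,noise_sr,noise_su Observation noise standard deviations
#'   for fruit dry mass (g), stone ratio (dimensionless) and sugar
#'   concentration (g/100 g FM).
#' @return A list of class `progeny_spec`.
#' @export
progeny_spec <- function(n_individuals = 159, wild_allele_freq = 0.25,
                         variance_explained = c(
                           A = 0.5, B = 0.2, RGRini = 0.3, P3 = 0.4,
                           kstone = 0.5, Wstone = 0.4, SLA = 0.5
                         ),
                         recombination_rate = 0.1,
                         fruits_per_individual = 3,
                         dm0_range = c(1.5, 2.5), obs_interval = 7,
                         noise_dm = 0.2, noise_sr = 0.02, noise_su = 0.5) {
  if (n_individuals < 2) abort("`n_individuals` must be >= 2.")
  if (wild_allele_freq < 0 || wild_allele_freq > 1) {
    abort("`wild_allele_freq` must be in [0, 1].")
  }
  missing <- setdiff(param_names(), names(variance_explained))
  if (length(missing) > 0) {
    abort(paste0("`variance_explained` lacks: ", paste(missing, collapse = ", ")))
  }
  if (any(variance_explained <= 0 | variance_explained > 1)) {
    abort("`variance_explained` fractions must be in (0, 1].")
  }
  if (recombination_rate < 0 || recombination_rate > 1) {
    abort("`recombination_rate` must be in [0, 1].")
  }
  if (any(c(noise_dm, noise_sr, noise_su) < 0)) {
    abort("Observation noise standard deviations must be non-negative.")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      wild_allele_freq = wild_allele_freq,
      variance_explained = variance_explained[param_names()],
      recombination_rate = recombination_rate,
      fruits_per_individual = as.integer(fruits_per_individual),
      dm0_range = dm0_range, obs_interval = obs_interval,
      noise_dm = noise_dm, noise_sr = noise_sr, noise_su = noise_su
    ),
    class = "progeny_spec"
  )
}

#' Simulate progeny genotypes with linkage
#'
#' Alleles are drawn with the configured wild-allele frequency. Within a
#' haplotype block, alleles are transmitted along the chain of inseparable
#' pairs: each locus copies its neighbour with probability
#' `1 - recombination_rate` and is redrawn otherwise, which preserves the
#' marginal frequency while correlating linked loci. Blocks and singleton
#' loci are independent across loci and individuals.
#'
#' @param spec A [progeny_spec()].
#' @param pairs Inseparable pairs defining the haplotype blocks.
#' @param n_loci Number of loci.
#' @return A genotype tibble `loc1..locN`, one row per individual.
#' @export
simulate_genotypes <- function(spec = progeny_spec(),
                               pairs = peach_inseparable_pairs(),
                               n_loci = 31L) {
  n <- spec$n_individuals
  p_s <- 1 - spec$wild_allele_freq
  r <- spec$recombination_rate
  blocks <- build_blocks(pairs, n_loci)
  g <- matrix(0, n, n_loci)
  for (b in blocks) {
    g[, b[1]] <- as.double(runif(n) < p_s)
    for (k in seq_along(b)[-1]) {
      fresh <- runif(n) < r
      g[, b[k]] <- ifelse(fresh, as.double(runif(n) < p_s), g[, b[k - 1]])
    }
  }
  genotype_tibble(g)
}

#' Simulate per-individual parameter values with a genetic variance share
#'
#' Adds independent Gaussian noise to the genetic-model prediction of each
#' parameter, with the noise variance set from the empirical genetic
#' variance of the simulated genotypes so that
#' `Var(genetic) / Var(total) = variance_explained`. Rare draws that would
#' leave a parameter non-positive are redrawn (parameters are physical
#' quantities; see the methods vignette).
#'
#' @param genotypes Genotype table.
#' @param model A [genetic_model].
#' @param spec A [progeny_spec()].
#' @return A tibble of parameter values, one row per individual, with the
#'   noiseless genetic predictions attached as attribute `"genetic"`.
#' @export
simulate_parameter_values <- function(genotypes, model = peach_genetic_model(),
                                      spec = progeny_spec()) {
  genetic <- predict_parameters(genotypes, model)
  n <- nrow(genetic)
  out <- genetic
  for (p in param_names()) {
    v <- spec$variance_explained[[p]]
    var_g <- var(genetic[[p]])
    sd_e <- if (v >= 1 || var_g == 0) 0 else sqrt(var_g * (1 - v) / v)
    if (sd_e > 0) {
      floor_p <- 0.01 * model$intercepts[[p]]
      val <- genetic[[p]] + rnorm(n, 0, sd_e)
      for (it in 1:100) {
        bad <- val <= floor_p
        if (!any(bad)) break
        val[bad] <- genetic[[p]][bad] + rnorm(sum(bad), 0, sd_e)
      }
      val[val <= floor_p] <- floor_p
      out[[p]] <- val
    }
  }
  attr(out, "genetic") <- genetic
  out
}

#' Simulate observed phenotype kinetics for one individual
#'
#' Weekly observations of several fruits of the same tree: each fruit gets
#' its own initial dry mass, its noiseless model trajectory is sampled at
#' the observation dates, and i.i.d. Gaussian observation noise is added
#' per trait.
#'
#' @param pars The individual's fruit parameters (one-row data frame or
#'   named vector).
#' @param config,weather Simulation configuration and weather.
#' @param spec A [progeny_spec()].
#' @return A tibble with columns `fruit`, `day`, `dj`, `dm0`, `dm_obs`,
#'   `sr_obs`, `su_obs`.
#' @export
simulate_kinetics <- function(pars, config = growth_config(),
                              weather = synthetic_weather(),
                              spec = progeny_spec()) {
  pars <- as_fruit_parameters(pars)
  tt <- thermal_time(weather, config)
  days <- seq(config$start_dab, config$end_dab, by = spec$obs_interval)
  out <- lapply(seq_len(spec$fruits_per_individual), function(f) {
    dm0 <- runif(1, spec$dm0_range[1], spec$dm0_range[2])
    cfg <- config
    cfg$dm0 <- dm0
    traj <- simulate_trajectory(pars, cfg, weather)
    obs <- traj[match(days, traj$day), ]
    tibble(
      fruit = f, day = days, dj = obs$dj, dm0 = dm0,
      dm_obs = pmax(obs$dm_fruit + rnorm(length(days), 0, spec$noise_dm), 0.05),
      sr_obs = pmin(pmax(obs$sr + rnorm(length(days), 0, spec$noise_sr), 0.005), 0.995),
      su_obs = pmax(obs$su + rnorm(length(days), 0, spec$noise_su), 0)
    )
  })
  list_rbind(out)
}

# Bounds for the curve fits: the union of the observed progeny box and the
# genetic-model box. Tight physical bounds matter here: weakly identified
# fits (an inflection point outside the observation window, a stone curve
# short of its plateau) otherwise run away along trade-off ridges and bias
# the downstream allele-effect regression.
fit_bounds <- function() {
  obs <- space_obs_bounds()$bounds
  gen <- parameter_bounds(peach_genetic_model())
  nm <- c("A", "B", "RGRini", "P3", "kstone", "Wstone")
  lo <- pmin(obs$min[match(nm, obs$parameter)], gen$min[match(nm, gen$parameter)])
  hi <- pmax(obs$max[match(nm, obs$parameter)], gen$max[match(nm, gen$parameter)])
  list(lower = setNames(lo, nm), upper = setNames(hi, nm))
}

#' Fit the growth and stone equations to observed kinetics
#'
#' Estimates `A`, `B`, `RGRini`, `P3` by least squares on the logistic
#' dry-mass curve (jointly across fruits, each with its own known initial
#' mass) and `kstone`, `Wstone` on the stone-vs-fruit allometry, using
#' bounded Levenberg-Marquardt ([minpack.lm::nlsLM()]) with multi-start:
#' one start at the observed-box midpoint plus random restarts inside the
#' observed parameter box; the converged fit with the lowest residual sum
#' of squares wins.
#'
#' @param kinetics Observations as produced by [simulate_kinetics()].
#' @param config,weather Simulation configuration and weather (for the
#'   thermal-time mapping and the initial date).
#' @param n_starts Total number of starts per equation.
#' @return A one-row tibble with the six estimated parameters, `converged`
#'   (logical) and the residual sums of squares `rss_growth`, `rss_stone`.
#' @export
fit_parameters <- function(kinetics, config = growth_config(),
                           weather = synthetic_weather(), n_starts = 8) {
  tt <- thermal_time(weather, config)
  dj0 <- tt$dj0
  kin <- as_tibble(kinetics)
  stopifnot(all(c("day", "dm0", "dm_obs", "sr_obs") %in% names(kin)))
  if (length(unique(kin$day)) < 6) {
    abort("At least 6 observation dates are required.")
  }
  dj <- if ("dj" %in% names(kin)) kin$dj else tt$gdd(kin$day)

  bounds <- fit_bounds()
  obs_box <- space_obs_bounds()$bounds

  growth_data <- data.frame(dm = kin$dm_obs, dj = dj, dm0 = kin$dm0)
  growth_fit <- multi_start_nls(
    dm ~ dm0 + A * dm0^B * (plogis(RGRini * (dj - P3)) - plogis(RGRini * (dj0 - P3))),
    data = growth_data,
    par_names = c("A", "B", "RGRini", "P3"),
    lower = bounds$lower[c("A", "B", "RGRini", "P3")],
    upper = bounds$upper[c("A", "B", "RGRini", "P3")],
    start_box = obs_box[match(c("A", "B", "RGRini", "P3"), obs_box$parameter), ],
    n_starts = n_starts, extra = list(dj0 = dj0)
  )

  # Fit the realized stone curve (allometry capped at sr_max * DM), which is
  # what the trajectories actually produce for extreme kstone * Wstone.
  # The regressor is the fitted growth curve, not the noisy observed mass:
  # regressing on dm_obs puts the same measurement error in x and y
  # (dmstone = sr * dm), which attenuates kstone and Wstone.
  dm_pred <- if (growth_fit$converged) {
    gp <- growth_fit$par
    kin$dm0 + gp[["A"]] * kin$dm0^gp[["B"]] *
      (plogis(gp[["RGRini"]] * (dj - gp[["P3"]])) -
         plogis(gp[["RGRini"]] * (dj0 - gp[["P3"]])))
  } else {
    kin$dm_obs
  }
  # stone-mass noise scales with fruit mass (the stone ratio is what is
  # observed with constant error), so the fit is weighted by 1/dm^2
  stone_data <- data.frame(dmstone = kin$sr_obs * dm_pred, dm = dm_pred)
  stone_fit <- multi_start_nls(
    dmstone ~ pmin(Wstone * (1 - exp(-kstone * dm)), srm * dm),
    data = stone_data,
    par_names = c("kstone", "Wstone"),
    lower = bounds$lower[c("kstone", "Wstone")],
    upper = bounds$upper[c("kstone", "Wstone")],
    start_box = obs_box[match(c("kstone", "Wstone"), obs_box$parameter), ],
    n_starts = n_starts, extra = list(srm = config$sr_max),
    weights = 1 / dm_pred^2
  )

  tibble(
    A = growth_fit$par[["A"]], B = growth_fit$par[["B"]],
    RGRini = growth_fit$par[["RGRini"]], P3 = growth_fit$par[["P3"]],
    kstone = stone_fit$par[["kstone"]], Wstone = stone_fit$par[["Wstone"]],
    converged = growth_fit$converged && stone_fit$converged,
    rss_growth = growth_fit$rss, rss_stone = stone_fit$rss
  )
}

# bounded LM with multi-start; returns best converged fit (or NA estimates)
multi_start_nls <- function(formula, data, par_names, lower, upper, start_box,
                            n_starts, extra = list(), weights = NULL) {
  env <- list2env(extra, parent = environment(formula))
  environment(formula) <- env
  if (is.null(weights)) weights <- rep(1, nrow(data))
  data$.w <- weights
  mid <- setNames((start_box$min + start_box$max) / 2, par_names)
  starts <- list(as.list(mid))
  for (s in seq_len(max(n_starts - 1, 0))) {
    starts[[s + 1]] <- as.list(setNames(
      runif(length(par_names), start_box$min, start_box$max), par_names
    ))
  }
  best <- list(par = setNames(rep(NA_real_, length(par_names)), par_names),
               rss = Inf, converged = FALSE)
  run_lm <- function(st, maxiter) {
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        weights = .w,
        control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-15,
                                             ptol = 1e-15)
      )),
      error = function(e) NULL
    )
  }
  for (st in starts) {
    fit <- run_lm(st, 300)
    if (is.null(fit)) next
    rss <- stats::deviance(fit)
    if (rss < best$rss) {
      best <- list(par = coef(fit), rss = rss, converged = TRUE)
    }
  }
  if (best$converged) {
    # polish from the winning start: cheap, and pins near-flat directions down
    polish <- run_lm(as.list(best$par), 500)
    if (!is.null(polish)) {
      rss <- stats::deviance(polish)
      if (rss <= best$rss) best <- list(par = coef(polish), rss = rss,
                                        converged = TRUE)
    }
  }
  best
}

#' Run the full estimation pipeline on a synthetic progeny
#'
#' End-to-end emulation of the mapping study: simulate genotypes, parameter
#' values and observed kinetics; fit the growth and stone curves per
#' individual; regress the fitted parameter values on the loci of the
#' genetic model; and compare the recovered allele effects with the
#' generating ones. `SLA` is not observable from fruit kinetics and is
#' taken from the direct per-tree leaf measurement (the simulated parameter
#' value). Individuals whose curve fits fail to converge are excluded from
#' the regression and counted.
#'
#' @param spec A [progeny_spec()].
#' @param model The generating [genetic_model].
#' @param pairs Inseparable pairs (linkage structure of the genotypes).
#' @param config,weather Simulation configuration and weather.
#' @param seed Optional RNG seed (the pipeline is deterministic given the
#'   seed and spec).
#' @param n_starts Multi-start count for the curve fits.
#' @return A list of class `progeny_estimation` with `genotypes`,
#'   `true_parameters`, `fitted_parameters`, `fit` (the
#'   [estimate_allele_effects()] result), `report` (tibble comparing
#'   recovered and generating terms) and `n_flagged`. [tidy()] returns the
#'   report, [glance()] a one-row summary.
#' @export
run_estimation_pipeline <- function(spec = progeny_spec(),
                                    model = peach_genetic_model(),
                                    pairs = peach_inseparable_pairs(),
                                    config = growth_config(),
                                    weather = synthetic_weather(),
                                    seed = NULL, n_starts = 8) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- simulate_genotypes(spec, pairs, model$n_loci)
  true_params <- simulate_parameter_values(genotypes, model, spec)

  fitted <- lapply(seq_len(nrow(true_params)), function(i) {
    kin <- simulate_kinetics(true_params[i, ], config, weather, spec)
    fit_parameters(kin, config, weather, n_starts)
  }) %>% list_rbind()
  fitted$SLA <- true_params$SLA

  ok <- fitted$converged & complete.cases(fitted[, param_names()])
  n_flagged <- sum(!ok)
  fit <- estimate_allele_effects(
    genotypes[ok, ], fitted[ok, param_names()],
    model_loci(model), model$n_loci
  )

  report <- tidy(model) %>%
    rename(true = "effect") %>%
    left_join(
      fit$terms %>% select("parameter", "term", "estimate", "std.error"),
      by = c("parameter", "term")
    ) %>%
    mutate(error = .data$estimate - .data$true)

  structure(
    list(spec = spec, genotypes = genotypes, true_parameters = true_params,
         fitted_parameters = fitted, fit = fit, report = report,
         n_flagged = n_flagged),
    class = "progeny_estimation"
  )
}

#' @export
print.progeny_estimation <- function(x, ...) {
  cat("<progeny_estimation>", nrow(x$genotypes), "individuals,",
      x$n_flagged, "flagged (non-converged)\n")
  eff <- x$report[x$report$term != "(Intercept)", ]
  cat(sprintf("  allele effects: median |error| / |true| = %.3f\n",
              median(abs(eff$error) / abs(eff$true))))
  invisible(x)
}

#' @method tidy progeny_estimation
#' @export
tidy.progeny_estimation <- function(x, ...) x$report

#' @method glance progeny_estimation
#' @export
glance.progeny_estimation <- function(x, ...) {
  eff <- x$report[x$report$term != "(Intercept)", ]
  tibble(
    n_individuals = nrow(x$genotypes), n_flagged = x$n_flagged,
    n_terms = nrow(eff),
    median_abs_rel_error = median(abs(eff$error) / abs(eff$true)),
    sign_recovery = mean(sign(eff$estimate) == sign(eff$true))
  )
}
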