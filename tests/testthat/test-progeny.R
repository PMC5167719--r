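test_that("genotype simulation honours allele frequency and block structure", {
  # degenerate frequencies
  set.seed(71)
  all_s <- simulate_genotypes(progeny_spec(n_individuals = 5, wild_allele_freq = 0))
  expect_true(all(as.matrix(all_s) == 1))
  all_d <- simulate_genotypes(progeny_spec(n_individuals = 5, wild_allele_freq = 1))
  expect_true(all(as.matrix(all_d) == 0))
  # strict co-inheritance at recombination rate zero
  g0 <- simulate_genotypes(progeny_spec(n_individuals = 400, recombination_rate = 0))
  expect_identical(linkage_violations(g0), rep(0L, 400))
  # empirical wild-allele frequency ~ 1/4
  g <- simulate_genotypes(progeny_spec(n_individuals = 10000))
  freq_d <- 1 - mean(as.matrix(g))
  expect_lt(abs(freq_d - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  # linked loci are correlated, unlinked ones are not
  gm <- as.matrix(g)
  expect_gt(cor(gm[, 4], gm[, 5]), 0.7)
  expect_lt(abs(cor(gm[, 1], gm[, 2])), 0.05)
})

test_that("parameter values carry the requested genetic variance share", {
  set.seed(72)
  spec <- progeny_spec(n_individuals = 5000)
  g <- simulate_genotypes(spec)
  vals <- simulate_parameter_values(g, spec = spec)
  genetic <- attr(vals, "genetic")
  for (p in c("kstone", "A", "P3")) {
    noise <- vals[[p]] - genetic[[p]]
    v_hat <- var(genetic[[p]]) / var(vals[[p]])
    expect_equal(v_hat, spec$variance_explained[[p]], tolerance = 0.05)
    expect_lt(abs(cor(noise, vals$SLA - genetic$SLA)), 0.05)
  }
  # full variance explained: exact genetic values
  spec1 <- progeny_spec(variance_explained = setNames(rep(1, 7), names(spec$variance_explained)))
  vals1 <- simulate_parameter_values(g, spec = spec1)
  expect_equal(as.data.frame(vals1), as.data.frame(genetic), ignore_attr = TRUE)
})

test_that("noiseless kinetics lie on the model curves at the weekly dates", {
  set.seed(73)
  spec <- progeny_spec(noise_dm = 0, noise_sr = 0, noise_su = 0,
                       fruits_per_individual = 2)
  cfg <- growth_config()
  p <- intercept_params()
  kin <- simulate_kinetics(p, cfg, spec = spec)
  expect_identical(nrow(kin), 2L * length(seq(87, 150, by = 7)))
  for (f in unique(kin$fruit)) {
    rows <- kin[kin$fruit == f, ]
    cfg_f <- cfg
    cfg_f$dm0 <- rows$dm0[1]
    traj <- simulate_trajectory(p, cfg_f)
    expect_equal(rows$dm_obs, traj$dm_fruit[match(rows$day, traj$day)],
                 tolerance = 1e-12)
    expect_equal(rows$sr_obs, traj$sr[match(rows$day, traj$day)],
                 tolerance = 1e-12)
  }
  # with noise, residual spread matches the specification
  specn <- progeny_spec(noise_dm = 0.3, fruits_per_individual = 40)
  kin_n <- simulate_kinetics(p, cfg, spec = specn)
  resid <- kin_n$dm_obs - vapply(seq_len(nrow(kin_n)), function(i) {
    cfg_f <- cfg; cfg_f$dm0 <- kin_n$dm0[i]
    traj <- simulate_trajectory(p, cfg_f)
    traj$dm_fruit[match(kin_n$day[i], traj$day)]
  }, numeric(1))
  expect_equal(sd(resid), 0.3, tolerance = 0.15)
})

test_that("curve fitting recovers the generating parameters from clean data", {
  set.seed(74)
  spec <- progeny_spec(noise_dm = 0, noise_sr = 0, noise_su = 0)
  p <- c(A = 10.5, B = 0.9, RGRini = 0.003, P3 = 2400,
         kstone = 0.12, Wstone = 5.2, SLA = 0.018)
  kin <- simulate_kinetics(p, spec = spec)
  fit <- fit_parameters(kin, n_starts = 6)
  expect_true(fit$converged)
  for (nm in c("A", "B", "RGRini", "P3", "kstone", "Wstone")) {
    expect_equal(fit[[nm]], unname(p[nm]), tolerance = 1e-4)
  }
})

test_that("Wstone is better identified when observations span the stone plateau", {
  set.seed(75)
  spec <- progeny_spec(noise_sr = 0.02)
  base <- c(A = 10, B = 1.0, RGRini = 0.004, P3 = 2200,
            kstone = 0.2, Wstone = 5, SLA = 0.018)
  err <- function(a_value) {
    p <- base; p["A"] <- a_value
    errs <- replicate(8, {
      kin <- simulate_kinetics(p, spec = spec)
      abs(fit_parameters(kin, n_starts = 4)$Wstone - p[["Wstone"]])
    })
    mean(errs)
  }
  # large fruit pushes kstone * DM well past the plateau; small fruit stops
  # before it, leaving Wstone poorly determined
  expect_lt(err(28), err(2.2))
})

test_that("the end-to-end pipeline inverts a noiseless progeny", {
  spec <- progeny_spec(
    n_individuals = 60,
    variance_explained = setNames(rep(1, 7), ideofruit:::param_names()),
    noise_dm = 0, noise_sr = 0, noise_su = 0
  )
  est <- run_estimation_pipeline(spec, seed = 76, n_starts = 4)
  expect_identical(est$n_flagged, 0L)
  eff <- est$report[est$report$term != "(Intercept)", ]
  expect_lt(max(abs(eff$error / eff$true)), 1e-3)
  # deterministic given the seed
  est2 <- run_estimation_pipeline(spec, seed = 76, n_starts = 4)
  expect_identical(est$report$estimate, est2$report$estimate)
})

test_that("shuffled genotypes decouple the effects (negative control)", {
  set.seed(77)
  spec <- progeny_spec(n_individuals = 300)
  g <- simulate_genotypes(spec)
  vals <- attr(simulate_parameter_values(g, spec = spec), "genetic")
  shuffled <- g[sample(nrow(g)), ]
  fit <- estimate_allele_effects(shuffled, vals, model_loci())
  eff <- tidy(fit)[!is.na(tidy(fit)$locus), ]
  true <- tidy(peach_genetic_model())
  true_eff <- true$effect[!is.na(true$locus)]
  expect_lt(median(abs(eff$estimate) / abs(true_eff)), 0.35)
  expect_lt(mean(abs(eff$statistic) > 3), 0.1)
})
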