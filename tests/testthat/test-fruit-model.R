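test_that("logistic growth is anchored, saturates, and matches independent evaluation", {
  p <- intercept_params()
  cfg <- growth_config(dm0 = 0.5, dj0 = 300)
  expect_identical(dm_fruit(300, p, cfg), 0.5)
  # frozen values from an independent 40-digit evaluation of the closed form
  expect_equal(dm_fruit(2695.74, p, cfg), 2.2765741313745514, tolerance = 1e-14)
  expect_equal(dm_fruit(1e9, p, cfg), 4.1117804209694539, tolerance = 1e-14)
  # stays finite arbitrarily far out in both directions
  expect_true(all(is.finite(dm_fruit(c(-1e9, 1e12), p, cfg))))
  # strictly increasing in thermal time
  dj <- seq(300, 5000, by = 10)
  expect_true(all(diff(dm_fruit(dj, p, cfg)) > 0))
})

test_that("stone allometry starts at zero, saturates below Wstone, matches evaluation", {
  p <- intercept_params()
  expect_identical(dm_stone(0, p), 0)
  expect_equal(dm_stone(10, p), 3.3290754612419119, tolerance = 1e-14)
  expect_lt(dm_stone(150, p), p$Wstone)
  expect_equal(dm_stone(1e6, p), p$Wstone, tolerance = 1e-12)
  # stone_ratio is the literal composition of the two curves
  cfg <- growth_config(dm0 = 0.5, dj0 = 300)
  dm <- dm_fruit(2000, p, cfg)
  expect_equal(stone_ratio(2000, p, cfg), dm_stone(dm, p) / dm)
  expect_true(stone_ratio(2000, p, cfg) > 0 && stone_ratio(2000, p, cfg) < 1)
})

test_that("trait responses move in the expected directions", {
  p <- intercept_params()
  base <- simulate_phenotype(p)
  up_a <- p; up_a$A <- p$A * 1.2
  expect_gt(simulate_phenotype(up_a)$DM, base$DM)
  up_w <- p; up_w$Wstone <- p$Wstone * 1.2
  expect_gt(simulate_phenotype(up_w)$SR, base$SR)
})

test_that("flesh carbon supply matches a finite-difference oracle along the window", {
  p <- intercept_params()
  cfg <- growth_config()
  w <- synthetic_weather()
  traj_of <- function(t) {
    # flesh dry mass at arbitrary t, from the model curves
    cfg_t <- cfg
    dj <- ideofruit:::thermal_time(w, cfg)$gdd(t)
    dm <- dm_fruit(dj, p, cfg, ideofruit:::thermal_time(w, cfg)$dj0)
    dm - pmin(dm_stone(dm, p), cfg$sr_max * dm)
  }
  h <- 1e-4
  for (t in c(90, 105.3, 120, 149)) {
    fd <- (cfg$alpha + cfg$beta) * (traj_of(t + h) - traj_of(t - h)) / (2 * h)
    expect_equal(flesh_carbon_supply(t, p, cfg, w), fd, tolerance = 1e-5)
  }
  # far beyond the inflection the logistic has flattened out
  cfg_flat <- growth_config(start_dab = 87, end_dab = 400)
  w_long <- synthetic_weather(0:420)
  expect_lt(flesh_carbon_supply(395, p, cfg_flat, w_long),
            1e-3 * flesh_carbon_supply(120, p, cfg_flat, w_long))
})

test_that("sugar ODE holds its analytic steady state and accumulates when ksugar = 0", {
  cfg <- growth_config()
  gain <- 1 - cfg$alpha / (cfg$alpha + cfg$beta)
  s <- 0.06
  c_star <- s * gain / cfg$ksugar
  out <- integrate_sugar(function(t) rep(s, length(t)), seq(87, 150), c_star, cfg)
  expect_equal(out$c_sugar, rep(c_star, nrow(out)), tolerance = 1e-8)

  cfg0 <- growth_config(ksugar = 1e-12) # ksugar -> 0: pure accumulation
  supply <- function(t) 0.01 * t
  out0 <- integrate_sugar(supply, seq(0, 50), 0.2, cfg0)
  gain0 <- 1 - cfg0$alpha / (cfg0$alpha + cfg0$beta)
  expect_equal(out0$c_sugar[nrow(out0)], 0.2 + gain0 * 0.01 * 50^2 / 2,
               tolerance = 1e-9)
})

test_that("the integrator converges at fourth order on a smooth forcing", {
  cfg <- growth_config(ksugar = 0.3)
  supply <- function(t) 0.05 * (1 + sin(t / 5))
  sol_at <- function(step) {
    out <- integrate_sugar(supply, seq(0, 40, by = step), 0.1, cfg)
    out$c_sugar[nrow(out)]
  }
  ref <- sol_at(0.01)
  e1 <- abs(sol_at(2) - ref)
  e2 <- abs(sol_at(1) - ref)
  order <- log2(e1 / e2)
  expect_gte(order, 3.5)
})

test_that("negative-going integrations are rejected with a step hint", {
  cfg <- growth_config(ksugar = 0.05)
  expect_error(
    integrate_sugar(function(t) rep(-5, length(t)), seq(0, 20), 0.01, cfg),
    "smaller step"
  )
})

test_that("sugar concentration is the exact ratio and scales with its inputs", {
  cfg <- growth_config()
  expect_equal(sugar_concentration(cfg$sigma_ts * 42, 42, cfg), 100)
  expect_identical(sugar_concentration(0, 10, cfg), 0)
  expect_equal(sugar_concentration(2, 10, cfg), 2 * sugar_concentration(1, 10, cfg))
  expect_error(sugar_concentration(1, 0, cfg), "positive")
  # FM = DMflesh / dmc, so at fixed sugar carbon SU scales linearly with dmc
  p <- intercept_params()
  su1 <- simulate_phenotype(p, growth_config(dmc = 0.15))$SU
  su2 <- simulate_phenotype(p, growth_config(dmc = 0.30))$SU
  expect_equal(su2, 2 * su1, tolerance = 1e-10)
})

test_that("trajectories respect the mass bookkeeping invariants", {
  cfg <- growth_config()
  corner <- c(A = 64.147, B = 2.348, RGRini = 0.008, P3 = 1203.528,
              kstone = 0.378, Wstone = 12.885, SLA = 0.013)
  for (p in list(intercept_params(), corner)) {
    traj <- simulate_trajectory(p, cfg)
    pv <- as_tibble(as.list(p))
    expect_true(all(traj$dm_stone < pv$Wstone[1]))
    expect_true(all(traj$dm_flesh > 0))
    expect_true(all(traj$sr > 0 & traj$sr < 1))
    expect_true(all(traj$c_sugar >= 0))
    expect_true(all(diff(traj$dm_fruit) > 0))
  }
})

test_that("SLA does not move the traits unless a source limitation is configured", {
  p1 <- intercept_params()
  p2 <- p1; p2$SLA <- p1$SLA / 2
  expect_equal(simulate_phenotype(p1), simulate_phenotype(p2))
  cfg_lim <- growth_config(sla_ref = 0.021)
  expect_lt(simulate_phenotype(p2, cfg_lim)$DM, simulate_phenotype(p1, cfg_lim)$DM)
})

test_that("the intercept-genotype phenotype matches its pinned value", {
  ph <- simulate_phenotype(intercept_params())
  expect_equal(ph$DM, 11.963715242234, tolerance = 1e-9)
  expect_equal(ph$SR, 0.292704113339, tolerance = 1e-9)
  expect_equal(ph$SU, 4.883698886422, tolerance = 1e-9)
})

test_that("batch simulation agrees with the single-fruit path", {
  set.seed(41)
  b <- space_obs_bounds()$bounds
  P <- vapply(seq_len(7), function(j) runif(8, b$min[j], b$max[j]), numeric(8))
  colnames(P) <- b$parameter
  batch <- simulate_phenotypes(P)
  for (i in seq_len(nrow(P))) {
    one <- simulate_phenotype(P[i, ])
    expect_equal(batch$DM[i], one$DM, tolerance = 1e-10)
    expect_equal(batch$SR[i], one$SR, tolerance = 1e-10)
    expect_equal(batch$SU[i], one$SU, tolerance = 1e-10)
  }
})
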