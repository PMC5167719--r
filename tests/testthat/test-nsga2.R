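test_that("domination follows the Pareto rule with Deb's feasibility extension", {
  expect_true(dominates(c(1, 1, 1), c(2, 2, 2)))
  expect_false(dominates(c(1, 2, 3), c(2, 1, 3)))
  expect_false(dominates(c(2, 1, 3), c(1, 2, 3)))
  expect_false(dominates(c(1, 1), c(1, 1))) # equal: no strict improvement
  # feasible beats infeasible regardless of objectives
  expect_true(dominates(c(9, 9, 9), c(0, 0, 0), violation_a = 0, violation_b = 2))
  # among infeasible, smaller violation wins
  expect_true(dominates(c(9, 9, 9), c(0, 0, 0), violation_a = 1, violation_b = 2))
  expect_false(dominates(c(0, 0, 0), c(9, 9, 9), violation_a = 2, violation_b = 1))
})

test_that("fast non-dominated sorting matches the brute-force oracle", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    obj <- matrix(rnorm(n * 3), ncol = 3)
    cv <- if (rep %% 3 == 0) pmax(rnorm(n), 0) else NULL
    expect_identical(fast_non_dominated_sort(obj, cv),
                     brute_front_ranks(obj, cv))
  }
  # a strict chain gives singleton fronts; a single point gives one front
  chain <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_identical(fast_non_dominated_sort(chain), c(1L, 2L, 3L))
  expect_identical(fast_non_dominated_sort(matrix(1:3, 1)), 1L)
})

test_that("front ranks partition and later fronts never dominate earlier ones", {
  set.seed(52)
  obj <- matrix(rnorm(240), ncol = 3)
  rank <- fast_non_dominated_sort(obj)
  expect_identical(sort(unique(rank)), seq_len(max(rank)))
  for (i in seq_len(nrow(obj))) {
    for (j in seq_len(nrow(obj))) {
      if (rank[j] >= rank[i]) {
        expect_false(dominates(obj[j, ], obj[i, ]) && rank[j] > rank[i])
      }
    }
  }
})

test_that("crowding distance: boundaries infinite, interior the normalized gap sum", {
  expect_identical(crowding_distance(matrix(rnorm(3), 1)), Inf)
  expect_identical(crowding_distance(matrix(rnorm(6), 2)), c(Inf, Inf))
  # three collinear equally spaced points varying in one objective only
  obj <- cbind(c(0, 0.5, 1), 7, 7)
  expect_identical(crowding_distance(obj), c(Inf, 1, Inf))
  # order invariance
  set.seed(53)
  obj <- matrix(runif(30), ncol = 3)
  d <- crowding_distance(obj)
  perm <- sample(nrow(obj))
  expect_equal(crowding_distance(obj[perm, ]), d[perm])
})

test_that("the SBX spread factor follows its defining distribution", {
  eta <- 20
  set.seed(54)
  beta <- ideofruit:::sbx_spread(runif(1e4), eta)
  cdf <- function(b) ifelse(b <= 1, 0.5 * b^(eta + 1),
                            1 - 0.5 * b^-(eta + 1))
  ks <- suppressWarnings(stats::ks.test(beta, cdf))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(beta <= 1), 0.5, tolerance = 0.02)
})

test_that("variation operators honour their probabilities", {
  set.seed(55)
  P1 <- matrix(runif(40), 10, 4)
  P2 <- matrix(runif(40), 10, 4)
  # no crossover, no mutation: copies
  ch <- ideofruit:::sbx_crossover(P1, P2, rep(0, 4), rep(1, 4), 0, 20)
  expect_identical(ch[[1]], P1)
  expect_identical(ch[[2]], P2)
  expect_identical(ideofruit:::polynomial_mutation(P1, rep(0, 4), rep(1, 4), 0, 10), P1)
  # children stay inside the box
  ch <- ideofruit:::sbx_crossover(P1, P2, rep(0, 4), rep(1, 4), 1, 20)
  mu <- ideofruit:::polynomial_mutation(ch[[1]], rep(0, 4), rep(1, 4), 1, 10)
  expect_true(all(mu >= 0 & mu <= 1))

  B1 <- matrix(as.double(runif(310) < 0.5), 10, 31)
  B2 <- matrix(as.double(runif(310) < 0.5), 10, 31)
  idch <- ideofruit:::binary_variation(B1, B2, 0, 0)
  expect_identical(idch[[1]], B1)
  comp <- ideofruit:::binary_variation(B1, B2, 0, 1)
  expect_identical(comp[[1]], 1 - B1)
  # expected flips per 31-bit child at p = 0.01 is 0.31
  n <- 3000
  Z <- matrix(0, n, 31)
  fl <- ideofruit:::binary_variation(Z, Z, 0, 0.01)[[1]]
  expect_equal(mean(rowSums(fl)), 0.31,
               tolerance = 4 * sqrt(31 * 0.01 * 0.99 / n) / 0.31)
})

test_that("pareto_filter keeps exactly the distinct non-dominated rows", {
  one <- tibble::tibble(obj1 = 1, obj2 = 2, obj3 = 3)
  expect_identical(pareto_filter(one), one)
  two <- tibble::tibble(obj1 = c(1, 2), obj2 = c(1, 2), obj3 = c(1, 2))
  expect_identical(nrow(pareto_filter(two)), 1L)
  set.seed(56)
  rnd <- tibble::tibble(obj1 = rnorm(200), obj2 = rnorm(200), obj3 = rnorm(200))
  filtered <- pareto_filter(rnd)
  expect_identical(filtered, rnd[brute_nondominated(as.matrix(rnd)), ])
  expect_identical(pareto_filter(filtered), filtered) # idempotent
})

test_that("hypervolume matches hand values and a Monte-Carlo estimate", {
  # single point: a box
  expect_equal(hypervolume(matrix(c(1, 1, 1), 1), c(2, 3, 4)), 1 * 2 * 3)
  # point outside the reference contributes nothing
  expect_equal(hypervolume(rbind(c(1, 1, 1), c(5, 0, 0)), c(2, 2, 2)), 1)
  # 2D staircase
  expect_equal(hypervolume(rbind(c(0, 1), c(1, 0)), c(2, 2)), 2 + 2 - 1)
  set.seed(57)
  pts <- matrix(runif(45), ncol = 3)
  ref <- c(1.2, 1.2, 1.2)
  hv <- hypervolume(pts, ref)
  mc <- mc_hypervolume(pts, ref, c(0, 0, 0), n = 2e5)
  expect_equal(hv, mc, tolerance = 0.02)
})

test_that("the evolutionary loop is elitist, deterministic, and archives only rank-1", {
  sphere <- nsga_problem(
    evaluate = function(X) {
      list(objectives = cbind(rowSums((X - 0.2)^2), rowSums((X - 0.8)^2),
                              rowSums((X - 0.5)^2)))
    },
    n_var = 3, type = "continuous", lower = rep(0, 3), upper = rep(1, 3)
  )
  # no variation, one generation: children are copies, population cannot leave
  # the initial set
  res0 <- nsga2(sphere, nsga_control(pop_size = 4, generations = 1,
                                     p_crossover = 0, p_mutation = 0, seed = 1))
  set.seed(1)
  init <- matrix(runif(12), 4, 3) %*% diag(rep(1, 3))
  expect_true(all(apply(as.matrix(res0$population[, 1:3]), 1, function(r) {
    any(apply(init, 1, function(x) all(abs(x - r) < 1e-12)))
  })))

  ctrl <- nsga_control(pop_size = 20, generations = 30, seed = 99)
  r1 <- nsga2(sphere, ctrl)
  r2 <- nsga2(sphere, ctrl)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$population, r2$population)

  # archive is mutually non-dominated and distinct
  arch <- as.matrix(r1$archive[, c("obj1", "obj2", "obj3")])
  expect_true(all(brute_nondominated(arch)))
  expect_identical(anyDuplicated(r1$archive), 0L)

  # longer run of the same seed can only extend the dominated volume
  ref <- c(2, 2, 2)
  r_short <- nsga2(sphere, nsga_control(pop_size = 20, generations = 10, seed = 7))
  r_long <- nsga2(sphere, nsga_control(pop_size = 20, generations = 40, seed = 7))
  expect_gte(
    hypervolume(as.matrix(r_long$archive[, c("obj1", "obj2", "obj3")]), ref),
    hypervolume(as.matrix(r_short$archive[, c("obj1", "obj2", "obj3")]), ref)
  )
})

test_that("constraint domination drives binary populations to feasibility", {
  pairs <- peach_inseparable_pairs()
  prob <- nsga_problem(
    evaluate = function(X) {
      params <- predict_parameters(X)
      list(objectives = phenotype_objectives(simulate_phenotypes(params)),
           violation = as.double(linkage_violations(X, pairs)))
    },
    n_var = 31, type = "binary"
  )
  res <- nsga2(prob, nsga_control(pop_size = 30, generations = 40, seed = 3,
                                  constraint_mode = "constraint_domination"))
  expect_true(all(res$archive$violation == 0))
})
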