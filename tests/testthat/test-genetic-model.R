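test_that("the all-wild genotype returns the intercepts and all-S the SLA minimum", {
  m <- peach_genetic_model()
  p0 <- predict_parameters(rep(0, 31), m)
  expect_equal(p0$SLA, 0.02103)
  expect_equal(p0$RGRini, 0.00172)
  expect_equal(p0$A, 8.29138)
  expect_equal(p0$B, 1.17567)
  expect_equal(p0$P3, 2695.74)
  expect_equal(p0$kstone, 0.19725)
  expect_equal(p0$Wstone, 3.86701)
  # every SLA effect is negative, so the all-S genotype attains the minimum
  p1 <- predict_parameters(rep(1, 31), m)
  expect_equal(p1$SLA, 0.01593, tolerance = 1e-9)
})

test_that("loci without an effect on a parameter leave it unchanged", {
  m <- peach_genetic_model()
  base <- predict_parameters(rep(0, 31), m)
  for (locus in setdiff(1:31, c(9L, 27L))) {
    g <- rep(0, 31)
    g[locus] <- 1
    expect_identical(predict_parameters(g, m)$B, base$B)
  }
})

test_that("prediction is affine: effects of disjoint-support genotypes add", {
  m <- peach_genetic_model()
  set.seed(11)
  for (i in 1:20) {
    support <- sample(31, 16)
    g1 <- g2 <- rep(0, 31)
    g1[support[1:8]] <- 1
    g2[support[9:16]] <- 1
    lhs <- predict_parameters(g1, m) + predict_parameters(g2, m) -
      predict_parameters(rep(0, 31), m)
    expect_equal(as.data.frame(lhs),
                 as.data.frame(predict_parameters(pmax(g1, g2), m)))
  }
})

test_that("parameter bounds bracket every genotype and are attained", {
  m <- peach_genetic_model()
  b <- parameter_bounds(m, with_genotypes = TRUE)
  # the sign-determined genotypes attain the bounds exactly
  for (j in seq_len(nrow(b))) {
    p <- b$parameter[j]
    expect_equal(predict_parameters(b$genotype_min[[j]], m)[[p]], b$min[j])
    expect_equal(predict_parameters(b$genotype_max[[j]], m)[[p]], b$max[j])
  }
  # exhaustive over the 2^17 linkage-feasible genotypes
  g_all <- enumerate_block_genotypes(as_matrix = TRUE)
  pred <- predict_parameters(g_all, m)
  for (j in seq_len(nrow(b))) {
    p <- b$parameter[j]
    expect_gte(min(pred[[p]]) - b$min[j], -1e-12)
    expect_lte(max(pred[[p]]) - b$max[j], 1e-12)
  }
  # large random sample of the free 2^31 space
  set.seed(12)
  g_rand <- matrix(as.double(runif(1e5 * 31) < 0.5), ncol = 31)
  pred_r <- predict_parameters(g_rand, m)
  for (j in seq_len(nrow(b))) {
    p <- b$parameter[j]
    expect_gte(min(pred_r[[p]]) - b$min[j], -1e-12)
    expect_lte(max(pred_r[[p]]) - b$max[j], 1e-12)
  }
})

test_that("toy models behave linearly in their single effect", {
  m <- genetic_model(c(A = 2), tibble::tibble(parameter = "A", locus = 3, effect = 0.5),
                     n_loci = 5)
  b <- parameter_bounds(m)
  expect_equal(b$min[b$parameter == "A"], 2)
  expect_equal(b$max[b$parameter == "A"], 2.5)
  expect_equal(predict_parameters(c(0, 0, 1, 0, 0), m)$A, 2.5)
})

test_that("invalid genotypes are rejected", {
  m <- peach_genetic_model()
  expect_error(predict_parameters(rep(0, 30), m), "31")
  g <- rep(0, 31); g[5] <- 2
  expect_error(predict_parameters(g, m), "0.*1")
})

test_that("the packaged serialized model matches the in-code model", {
  path <- system.file("extdata", "peach_genetic_model.yaml", package = "ideofruit")
  m <- read_genetic_model(path)
  expect_identical(tidy(m), tidy(peach_genetic_model()))
  # write/read round-trip through a fresh file
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_genetic_model(m, tmp)
  expect_identical(tidy(read_genetic_model(tmp)), tidy(m))
})

test_that("allele-effect regression inverts the generating model exactly on noiseless data", {
  m <- peach_genetic_model()
  set.seed(21)
  g <- matrix(as.double(runif(200 * 31) < 0.5), ncol = 31)
  values <- predict_parameters(g, m)
  fit <- estimate_allele_effects(g, values, model_loci(m))
  expect_equal(tidy(fit)$estimate, tidy(m)$effect, tolerance = 1e-9)
  expect_true(all(glance(fit)$rss < 1e-18))
})

test_that("allele-effect regression is unbiased under noise", {
  m <- peach_genetic_model()
  set.seed(22)
  inside <- 0L
  n_rep <- 40L
  loci <- model_loci(m)$kstone
  true_eff <- m$effects$effect[m$effects$parameter == "kstone"]
  for (r in seq_len(n_rep)) {
    g <- matrix(as.double(runif(159 * 31) < 0.75), ncol = 31)
    y <- predict_parameters(g, m)$kstone + rnorm(159, 0, 0.02)
    fit <- estimate_allele_effects(g, tibble::tibble(kstone = y),
                                   list(kstone = loci))
    tt <- tidy(fit)
    eff <- tt[tt$term != "(Intercept)", ]
    inside <- inside + sum(abs(eff$estimate - true_eff) <= 3 * eff$std.error)
  }
  expect_gte(inside / (n_rep * length(loci)), 0.95)
})

test_that("regression on constant values gives zero effects, and collinear loci error", {
  m <- peach_genetic_model()
  set.seed(23)
  g <- matrix(as.double(runif(100 * 31) < 0.5), ncol = 31)
  fit <- estimate_allele_effects(g, tibble::tibble(A = rep(3.5, 100)),
                                 list(A = c(3L, 7L)))
  tt <- tidy(fit)
  expect_equal(tt$estimate[tt$term == "(Intercept)"], 3.5)
  expect_equal(max(abs(tt$estimate[tt$term != "(Intercept)"])), 0)

  g2 <- g
  g2[, 7] <- g2[, 3] # perfectly linked pair
  expect_error(
    estimate_allele_effects(g2, tibble::tibble(A = rnorm(100)), list(A = c(3L, 7L))),
    "collinear.*loc7"
  )
})
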