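# The stepwise ideotype study: four nested search spaces (observed parameter
# box, genetically restricted box, free allele space, linkage-constrained
# allele space), each explored by random draws and by NSGA-II, with
# dominance summaries comparing the two.

#' Search-space definitions
#'
#' * `space_obs_bounds()` — the parameter box spanned by the extreme values
#'   observed in the progeny (packaged constants; observed extremes are data,
#'   not derivable from the genetic model).
#' * `space_restricted()` — the box of values attainable under the genetic
#'   model, recomputed from its coefficients via [parameter_bounds()].
#' * `space_alleles()` — the free binary space of the model's loci.
#' * `space_alleles_linkage()` — the allele space restricted to genotypes
#'   respecting the inseparable-pair constraints.
#'
#' @param model A [genetic_model] (allele spaces and the restricted box).
#' @param pairs Inseparable pairs for the linkage-constrained space.
#' @return A list of class `space_definition` with fields `name`, `type`
#'   (`"parameter"` or `"allele"`), `bounds` (parameter boxes), `model` and
#'   `pairs` (allele spaces).
#' @export
space_obs_bounds <- function() {
  new_space(
    "parameters_obs-bounds", "parameter",
    bounds = tibble(
      parameter = param_names(),
      min = c(0.771, 0.01, 0.001, 1203.528, 0.036, 2.355, 0.013),
      max = c(64.147, 2.348, 0.008, 2991.884, 0.378, 12.885, 0.021)
    )
  )
}

#' @rdname space_obs_bounds
#' @export
space_restricted <- function(model = peach_genetic_model()) {
  new_space("parameters_restricted", "parameter",
            bounds = parameter_bounds(model), model = model)
}

#' @rdname space_obs_bounds
#' @export
space_alleles <- function(model = peach_genetic_model()) {
  new_space("alleles", "allele", model = model)
}

#' @rdname space_obs_bounds
#' @export
space_alleles_linkage <- function(model = peach_genetic_model(),
                                  pairs = peach_inseparable_pairs()) {
  new_space("alleles_with-linkage", "allele", model = model, pairs = pairs)
}

new_space <- function(name, type, bounds = NULL, model = NULL, pairs = NULL) {
  if (!is.null(bounds)) {
    bounds <- bounds[match(param_names(), bounds$parameter), ]
    if (any(bounds$min >= bounds$max)) abort("Each bound must satisfy min < max.")
  }
  structure(list(name = name, type = type, bounds = bounds, model = model,
                 pairs = pairs),
            class = "space_definition")
}

#' @export
print.space_definition <- function(x, ...) {
  cat("<space_definition>", x$name, "(", x$type, "space )\n")
  if (!is.null(x$bounds)) print(x$bounds)
  if (!is.null(x$pairs)) cat(" ", nrow(x$pairs), "linkage constraints\n")
  invisible(x)
}

#' Restricted parameter box implied by a genetic model
#'
#' Convenience wrapper: the search space whose boundaries are the minimal and
#' maximal parameter values attainable over all allele combinations.
#'
#' @param model A [genetic_model].
#' @return A `space_definition`.
#' @export
restricted_space_from_model <- function(model = peach_genetic_model()) {
  space_restricted(model)
}

#' Random exploration of a parameter space
#'
#' Draws `n` parameter sets i.i.d. uniformly inside the box and simulates
#' their phenotypes.
#'
#' @param space A parameter-type `space_definition`.
#' @param n Number of individuals.
#' @param seed Optional RNG seed.
#' @param config,weather Simulation configuration and weather series shared
#'   by the whole dataset.
#' @return A tibble with the seven parameter columns plus `DM`, `SR`, `SU`;
#'   attributes `dataset` and `provenance`.
#' @export
draw_random_parameters <- function(space, n = 500, seed = NULL,
                                   config = growth_config(),
                                   weather = synthetic_weather()) {
  stopifnot(inherits(space, "space_definition"), space$type == "parameter")
  if (!is.null(seed)) set.seed(seed)
  b <- space$bounds
  P <- vapply(seq_len(nrow(b)), function(j) runif(n, b$min[j], b$max[j]),
              numeric(n))
  if (n == 1) P <- matrix(P, nrow = 1)
  colnames(P) <- b$parameter
  out <- bind_cols(as_tibble(P),
                   if (n > 0) simulate_phenotypes(P, config, weather)
                   else tibble(DM = numeric(), SR = numeric(), SU = numeric()))
  as_dataset(out, sub("^parameters_", "parameters_random_", space$name),
             "random", seed)
}

#' Random exploration of the allele space
#'
#' Draws genotypes with i.i.d. fair bits per free dimension: per locus when
#' `pairs` is `NULL`, per haplotype block otherwise (so every draw respects
#' the linkage constraints), then predicts parameters and simulates
#' phenotypes.
#'
#' @param model A [genetic_model].
#' @inheritParams draw_random_parameters
#' @param pairs Optional inseparable pairs.
#' @return A tibble with `loc*` columns, the seven parameters and `DM`,
#'   `SR`, `SU`.
#' @export
draw_random_alleles <- function(model = peach_genetic_model(), n = 500,
                                seed = NULL, pairs = NULL,
                                config = growth_config(),
                                weather = synthetic_weather()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pairs)) {
    g <- matrix(as.double(runif(n * model$n_loci) < 0.5), n, model$n_loci)
  } else {
    blocks <- build_blocks(pairs, model$n_loci)
    bits <- matrix(as.double(runif(n * length(blocks)) < 0.5), n, length(blocks))
    g <- bits %*% block_incidence(blocks)
  }
  params <- predict_parameters(g, model)
  out <- bind_cols(genotype_tibble(g), params,
                   simulate_phenotypes(params, config, weather))
  as_dataset(out, if (is.null(pairs)) "alleles_random" else "alleles_random_with-linkage",
             "random", seed)
}

# --- optimization problems for the four spaces --------------------------

problem_for_space <- function(space, config, weather,
                              constraint_mode = "block_encoding") {
  if (space$type == "parameter") {
    b <- space$bounds
    return(nsga_problem(
      evaluate = function(X) {
        colnames(X) <- b$parameter
        list(objectives = phenotype_objectives(simulate_phenotypes(X, config, weather)))
      },
      n_var = nrow(b), type = "continuous",
      lower = b$min, upper = b$max, var_names = b$parameter
    ))
  }
  model <- space$model
  if (is.null(space$pairs)) {
    return(nsga_problem(
      evaluate = function(X) {
        params <- predict_parameters(X, model)
        list(objectives = phenotype_objectives(simulate_phenotypes(params, config, weather)))
      },
      n_var = model$n_loci, type = "binary",
      var_names = paste0("loc", seq_len(model$n_loci))
    ))
  }
  if (constraint_mode == "block_encoding") {
    blocks <- build_blocks(space$pairs, model$n_loci)
    B <- block_incidence(blocks)
    nsga_problem(
      evaluate = function(X) {
        g <- X %*% B
        params <- predict_parameters(g, model)
        list(objectives = phenotype_objectives(simulate_phenotypes(params, config, weather)))
      },
      n_var = length(blocks), type = "binary",
      var_names = paste0("block", seq_along(blocks))
    )
  } else {
    pairs <- space$pairs
    nsga_problem(
      evaluate = function(X) {
        params <- predict_parameters(X, model)
        list(
          objectives = phenotype_objectives(simulate_phenotypes(params, config, weather)),
          violation = as.double(linkage_violations(X, pairs, model$n_loci))
        )
      },
      n_var = model$n_loci, type = "binary",
      var_names = paste0("loc", seq_len(model$n_loci))
    )
  }
}

#' Optimize the three fruit traits over a search space
#'
#' Wraps [nsga2()] with the encoding appropriate to the space (box-bounded
#' reals, free bits, block-encoded bits or constraint domination) and
#' returns the distinct non-dominated archive as a dataset: decision
#' columns, derived parameters, simulated traits.
#'
#' @param space A `space_definition`.
#' @param control An [nsga_control()]; its `constraint_mode` selects how the
#'   linkage-constrained space is handled.
#' @inheritParams draw_random_parameters
#' @return A tibble of distinct mutually non-dominated individuals with the
#'   decision columns of the space, the seven parameters and `DM`, `SR`,
#'   `SU`; the full `nsga_result` is attached as attribute `"result"`.
#' @export
optimize_space <- function(space, control = nsga_control(), seed = NULL,
                           config = growth_config(),
                           weather = synthetic_weather()) {
  stopifnot(inherits(space, "space_definition"))
  if (!is.null(seed)) control$seed <- seed
  prob <- problem_for_space(space, config, weather, control$constraint_mode)
  res <- nsga2(prob, control)
  arch <- res$archive

  decision_cols <- prob$var_names
  phen <- tibble(DM = -arch$obj1, SR = arch$obj2, SU = -arch$obj3)
  decisions <- arch[, decision_cols]
  if (space$type == "parameter") {
    params <- decisions
    out <- bind_cols(params, phen)
  } else {
    if (startsWith(decision_cols[1], "block")) {
      blocks <- build_blocks(space$pairs, space$model$n_loci)
      g <- decode_blocks(as.matrix(decisions), blocks)
      decisions <- bind_cols(decisions, g)
      params <- predict_parameters(g, space$model)
    } else {
      params <- predict_parameters(decisions, space$model)
    }
    out <- bind_cols(decisions, params, phen)
  }
  out <- as_dataset(out, paste0(space$name, "_optim"), "optimized", control$seed)
  attr(out, "result") <- res
  out
}

as_dataset <- function(tbl, name, provenance, seed) {
  attr(tbl, "dataset") <- name
  attr(tbl, "provenance") <- provenance
  attr(tbl, "seed") <- if (is.null(seed)) NA_integer_ else seed
  tbl
}

#' Dominance comparison between a random and an optimized dataset
#'
#' Computes, on the objective scale `(-DM, SR, -SU)`, the fraction of
#' individuals of the first dataset dominated by at least one individual of
#' the second, plus per-trait range summaries for both.
#'
#' @param random_ds,optimized_ds Datasets with columns `DM`, `SR`, `SU`.
#' @return A list of class `dominance_report`: `fraction_dominated`,
#'   `fraction_reverse` (optimized individuals dominated by a random one)
#'   and a `summary` tibble of per-trait statistics.
#' @export
dominance_report <- function(random_ds, optimized_ds) {
  fr <- fraction_dominated(random_ds, optimized_ds)
  rev <- fraction_dominated(optimized_ds, random_ds)
  summarise_traits <- function(ds, which) {
    purrr::map(c("DM", "SR", "SU"), function(tr) {
      x <- ds[[tr]]
      if (length(x) == 0) x <- NA_real_
      tibble(dataset = which, trait = tr, min = min(x, na.rm = FALSE),
             median = median(x), max = max(x))
    }) %>% list_rbind()
  }
  structure(
    list(
      fraction_dominated = fr, fraction_reverse = rev,
      n_random = nrow(random_ds), n_optimized = nrow(optimized_ds),
      summary = bind_rows(summarise_traits(random_ds, "random"),
                          summarise_traits(optimized_ds, "optimized"))
    ),
    class = "dominance_report"
  )
}

# fraction of rows of a dominated by >= 1 row of b (objective scale)
fraction_dominated <- function(a, b) {
  if (nrow(b) == 0 || nrow(a) == 0) return(0)
  oa <- phenotype_objectives(a)
  ob <- phenotype_objectives(b)
  dominated <- vapply(seq_len(nrow(oa)), function(i) {
    le <- ob[, 1] <= oa[i, 1] & ob[, 2] <= oa[i, 2] & ob[, 3] <= oa[i, 3]
    lt <- ob[, 1] < oa[i, 1] | ob[, 2] < oa[i, 2] | ob[, 3] < oa[i, 3]
    any(le & lt)
  }, logical(1))
  mean(dominated)
}

#' @export
print.dominance_report <- function(x, ...) {
  cat("<dominance_report>\n")
  cat(sprintf("  %.1f%% of %d random individuals dominated by the optimized set\n",
              100 * x$fraction_dominated, x$n_random))
  cat(sprintf("  %.1f%% of %d optimized individuals dominated by a random one\n",
              100 * x$fraction_reverse, x$n_optimized))
  print(x$summary)
  invisible(x)
}

#' @method tidy dominance_report
#' @export
tidy.dominance_report <- function(x, ...) x$summary

#' @method glance dominance_report
#' @export
glance.dominance_report <- function(x, ...) {
  tibble(fraction_dominated = x$fraction_dominated,
         fraction_reverse = x$fraction_reverse,
         n_random = x$n_random, n_optimized = x$n_optimized)
}

#' Exhaustive Pareto front of the linkage-constrained allele space
#'
#' Enumerates all block-feasible genotypes (2^K for K haplotype blocks),
#' simulates every phenotype and keeps the distinct non-dominated set: the
#' exact reference front the evolutionary runs are judged against.
#'
#' @param model A [genetic_model].
#' @param pairs Inseparable pairs defining the blocks.
#' @inheritParams draw_random_parameters
#' @return A tibble with the genotype, parameter and trait columns of the
#'   non-dominated set, plus attribute `"n_enumerated"`.
#' @export
enumerate_constrained_front <- function(model = peach_genetic_model(),
                                        pairs = peach_inseparable_pairs(),
                                        config = growth_config(),
                                        weather = synthetic_weather()) {
  blocks <- build_blocks(pairs, model$n_loci)
  g <- enumerate_block_genotypes(blocks, as_matrix = TRUE)
  params <- predict_parameters(g, model)
  phen <- simulate_phenotypes(params, config, weather)
  obj <- phenotype_objectives(phen)
  nd <- nondominated_indices(obj)
  out <- bind_cols(genotype_tibble(g[nd, , drop = FALSE]),
                   params[nd, ], phen[nd, ])
  out <- distinct(out)
  attr(out, "n_enumerated") <- nrow(g)
  out
}

# indices of the non-dominated rows of a (possibly large) objective matrix;
# cheap pre-filter by sorting on the first objective before the O(n^2) pass
nondominated_indices <- function(obj) {
  n <- nrow(obj)
  ord <- order(obj[, 1], obj[, 2], obj[, 3])
  obj_s <- obj[ord, , drop = FALSE]
  keep <- logical(n)
  kept <- matrix(numeric(0), ncol = ncol(obj))
  for (i in seq_len(n)) {
    p <- obj_s[i, ]
    if (nrow(kept) == 0) {
      dominated <- FALSE
    } else {
      le <- kept[, 1] <= p[1] & kept[, 2] <= p[2] & kept[, 3] <= p[3]
      lt <- kept[, 1] < p[1] | kept[, 2] < p[2] | kept[, 3] < p[3]
      dominated <- any(le & lt)
    }
    if (!dominated) {
      keep[i] <- TRUE
      kept <- rbind(kept, p)
    }
  }
  sort(ord[keep])
}

#' Run the full stepwise study
#'
#' Builds the random and optimized datasets of the four nested spaces under
#' one shared configuration and weather series, so phenotypes are comparable
#' across datasets, and summarises each random/optimized pair with a
#' [dominance_report()].
#'
#' @param model A [genetic_model].
#' @param pairs Inseparable pairs.
#' @param n_random Random draws per space.
#' @param control NSGA-II settings shared by all optimizations.
#' @param seed Base seed; each dataset derives its own seed from it.
#' @inheritParams draw_random_parameters
#' @return A list of class `ideotype_study`: `datasets` (named list of
#'   tibbles), `reports` (named list of dominance reports) and the
#'   configuration used.
#' @export
run_study <- function(model = peach_genetic_model(),
                      pairs = peach_inseparable_pairs(),
                      n_random = 500, control = nsga_control(), seed = 1,
                      config = growth_config(),
                      weather = synthetic_weather()) {
  spaces <- list(
    obs = space_obs_bounds(),
    restricted = space_restricted(model),
    alleles = space_alleles(model),
    linkage = space_alleles_linkage(model, pairs)
  )
  datasets <- list()
  datasets[["parameters_random_obs-bounds"]] <-
    draw_random_parameters(spaces$obs, n_random, seed + 101L, config, weather)
  datasets[["parameters_random_restricted"]] <-
    draw_random_parameters(spaces$restricted, n_random, seed + 102L, config, weather)
  datasets[["alleles_random"]] <-
    draw_random_alleles(model, n_random, seed + 103L, NULL, config, weather)
  datasets[["parameters_optim_obs-bounds"]] <-
    optimize_space(spaces$obs, control, seed + 201L, config, weather)
  datasets[["parameters_optim_restricted"]] <-
    optimize_space(spaces$restricted, control, seed + 202L, config, weather)
  datasets[["alleles_optim"]] <-
    optimize_space(spaces$alleles, control, seed + 203L, config, weather)
  datasets[["alleles_optim_with-linkage"]] <-
    optimize_space(spaces$linkage, control, seed + 204L, config, weather)

  reports <- list(
    `obs-bounds` = dominance_report(datasets[["parameters_random_obs-bounds"]],
                                    datasets[["parameters_optim_obs-bounds"]]),
    restricted = dominance_report(datasets[["parameters_random_restricted"]],
                                  datasets[["parameters_optim_restricted"]]),
    alleles = dominance_report(datasets[["alleles_random"]],
                               datasets[["alleles_optim"]])
  )
  structure(list(datasets = datasets, reports = reports, seed = seed,
                 control = control, config = config),
            class = "ideotype_study")
}

#' @export
print.ideotype_study <- function(x, ...) {
  cat("<ideotype_study> seed", x$seed, "\n")
  for (nm in names(x$datasets)) {
    cat(sprintf("  %-32s %5d individuals\n", nm, nrow(x$datasets[[nm]])))
  }
  for (nm in names(x$reports)) {
    cat(sprintf("  dominance (%s): %.1f%% of random dominated\n",
                nm, 100 * x$reports[[nm]]$fraction_dominated))
  }
  invisible(x)
}
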