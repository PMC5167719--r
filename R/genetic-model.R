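# The additive QTL genetic model: seven fruit-model parameters predicted from
# a 31-locus binary genotype (0 = wild D allele, 1 = cultivated S allele).
# Intercepts therefore describe the all-D genotype.

#' Construct an additive allele-effect genetic model
#'
#' A genetic model maps a binary genotype (one 0/1 indicator per locus) to the
#' seven parameters of the fruit quality model by an additive linear system:
#' for each parameter, value = intercept + sum of the effects of the loci
#' carrying the S allele (coded 1).
#'
#' @param intercepts Named numeric vector, one entry per model parameter
#'   (names among `A`, `B`, `RGRini`, `P3`, `kstone`, `Wstone`, `SLA`).
#' @param effects Data frame with columns `parameter`, `locus` (positive
#'   integer), `effect` (signed numeric, the additive effect of substituting
#'   the S allele at that locus).
#' @param n_loci Number of loci indexed by the model (default: the largest
#'   locus referenced).
#'
#' @return An object of class `genetic_model`.
#' @seealso [peach_genetic_model()] for the packaged peach model,
#'   [predict_parameters()], [parameter_bounds()].
#' @export
genetic_model <- function(intercepts, effects, n_loci = NULL) {
  effects <- as_tibble(effects)
  stopifnot(all(c("parameter", "locus", "effect") %in% names(effects)))
  effects$locus <- as.integer(effects$locus)
  bad <- setdiff(unique(effects$parameter), param_names())
  if (length(bad) > 0) {
    abort(paste0("Unknown parameter(s) in effects: ", paste(bad, collapse = ", ")))
  }
  if (!all(names(intercepts) %in% param_names()) || is.null(names(intercepts))) {
    abort("`intercepts` must be a named vector with parameter names.")
  }
  if (any(effects$locus < 1L)) abort("Locus indices must be >= 1.")
  if (anyDuplicated(effects[, c("parameter", "locus")])) {
    abort("Duplicate (parameter, locus) effect terms.")
  }
  if (is.null(n_loci)) n_loci <- max(effects$locus)
  if (any(effects$locus > n_loci)) abort("Locus index exceeds `n_loci`.")
  structure(
    list(
      intercepts = intercepts[intersect(param_names(), names(intercepts))],
      effects = dplyr::arrange(effects, match(.data$parameter, param_names()), .data$locus),
      n_loci = as.integer(n_loci)
    ),
    class = "genetic_model"
  )
}

#' The packaged peach QTL genetic model
#'
#' The 31-locus, 37-term additive model for the seven parameters of the peach
#' fruit quality model, estimated in a *Prunus davidiana* x *P. persica*
#' backcross progeny. Five loci are pleiotropic (affect two or three
#' parameters). Allele coding: 0 = wild D allele, 1 = cultivated S allele, so
#' the intercepts are the parameter values of the all-D genotype.
#'
#' @return A [genetic_model] with 31 loci and 37 effect terms.
#' @examples
#' m <- peach_genetic_model()
#' predict_parameters(rep(0, 31), m) # the intercepts
#' @export
peach_genetic_model <- function() {
  intercepts <- c(
    A = 8.29138, B = 1.17567, RGRini = 0.00172, P3 = 2695.74,
    kstone = 0.19725, Wstone = 3.86701, SLA = 0.02103
  )
  effects <- tibble(
    parameter = c(
      rep("SLA", 5), rep("RGRini", 6), rep("A", 6), rep("B", 2),
      rep("P3", 5), rep("kstone", 7), rep("Wstone", 6)
    ),
    locus = c(
      5L, 10L, 15L, 21L, 26L,
      1L, 14L, 17L, 22L, 25L, 31L,
      3L, 7L, 12L, 20L, 23L, 26L,
      9L, 27L,
      14L, 18L, 22L, 25L, 30L,
      4L, 8L, 11L, 13L, 16L, 28L, 31L,
      2L, 6L, 14L, 19L, 24L, 29L
    ),
    effect = c(
      -0.00077, -0.00158, -0.00133, -0.00061, -0.00081,
      0.00059, 0.00038, 0.00066, 0.00119, -0.00041, 0.00079,
      2.66318, -4.17002, 2.55744, 2.51455, 3.07437, 3.55207,
      -0.25238, -0.20475,
      -227.64, -168.95, -260.25, 129, -278.73,
      -0.03115, -0.02533, -0.0174, -0.02218, -0.02466, -0.00724, -0.01467,
      1.33592, 0.92848, 1.83601, -0.22232, -2.02367, 1.33883
    )
  )
  genetic_model(intercepts, effects, n_loci = 31L)
}

#' @export
print.genetic_model <- function(x, ...) {
  cat("<genetic_model>", x$n_loci, "loci,", nrow(x$effects), "effect terms\n")
  counts <- table(x$effects$parameter)
  for (p in names(x$intercepts)) {
    cat(sprintf(
      "  %-7s intercept %-10g %d locus effect(s)\n",
      p, x$intercepts[[p]], if (p %in% names(counts)) counts[[p]] else 0L
    ))
  }
  invisible(x)
}

#' Summarise the structure of a genetic model
#'
#' @param x A [genetic_model].
#' @param ... Unused.
#' @return A one-row tibble with the number of parameters, distinct loci,
#'   effect terms and pleiotropic loci (loci affecting two or more
#'   parameters).
#' @method glance genetic_model
#' @export
glance.genetic_model <- function(x, ...) {
  per_locus <- table(unique(x$effects[, c("parameter", "locus")])$locus)
  tibble(
    n_parameters = length(x$intercepts),
    n_loci = length(unique(x$effects$locus)),
    n_effects = nrow(x$effects),
    n_pleiotropic = sum(per_locus >= 2L)
  )
}

#' @method tidy genetic_model
#' @export
tidy.genetic_model <- function(x, ...) {
  bind_rows(
    tibble(
      parameter = names(x$intercepts), locus = NA_integer_,
      term = "(Intercept)", effect = unname(x$intercepts)
    ),
    mutate(x$effects, term = paste0("loc", .data$locus))
  ) %>%
    arrange(match(.data$parameter, param_names()), !is.na(.data$locus), .data$locus)
}

# 0/1 genotype input (vector, matrix, or tibble with loc1..locN columns)
# -> n x n_loci integer matrix.
as_genotype_matrix <- function(genotypes, n_loci = 31L) {
  if (is.data.frame(genotypes)) {
    cols <- paste0("loc", seq_len(n_loci))
    missing <- setdiff(cols, names(genotypes))
    if (length(missing) > 0) {
      abort(paste0("Genotype table lacks column(s): ", paste(missing, collapse = ", ")))
    }
    g <- as.matrix(genotypes[, cols])
  } else if (is.matrix(genotypes)) {
    g <- genotypes
  } else {
    g <- matrix(genotypes, nrow = 1)
  }
  if (ncol(g) != n_loci) {
    abort(sprintf("Genotypes must have exactly %d loci, got %d.", n_loci, ncol(g)))
  }
  storage.mode(g) <- "double"
  if (anyNA(g) || !all(g %in% c(0, 1))) {
    abort("Genotype entries must all be 0 (wild D allele) or 1 (S allele).")
  }
  g
}

genotype_tibble <- function(g) {
  colnames(g) <- paste0("loc", seq_len(ncol(g)))
  as_tibble(g)
}

# n_loci x n_parameters effect matrix (zero where a locus carries no effect).
effect_matrix <- function(model) {
  E <- matrix(0, nrow = model$n_loci, ncol = length(model$intercepts),
              dimnames = list(NULL, names(model$intercepts)))
  E[cbind(model$effects$locus, match(model$effects$parameter, colnames(E)))] <-
    model$effects$effect
  E
}

#' Predict fruit-model parameters from genotypes
#'
#' Applies the additive genetic model: each parameter equals its intercept
#' plus the sum of the effects of the loci carrying the S allele.
#'
#' @param genotypes A genotype: numeric 0/1 vector of length `model$n_loci`, a
#'   matrix (individuals in rows), or a data frame with columns
#'   `loc1..locN`.
#' @param model A [genetic_model] (default: the packaged peach model).
#' @return A tibble with one row per individual and one column per model
#'   parameter.
#' @examples
#' predict_parameters(rep(1, 31))
#' @export
predict_parameters <- function(genotypes, model = peach_genetic_model()) {
  g <- as_genotype_matrix(genotypes, model$n_loci)
  E <- effect_matrix(model)
  values <- g %*% E
  values <- sweep(values, 2, -unlist(model$intercepts[colnames(E)]))
  as_tibble(values)
}

#' Extreme parameter values attainable under a genetic model
#'
#' Because effects are additive and loci independent in the model, the minimum
#' (maximum) of each parameter over all allele combinations is attained by
#' setting to 1 exactly the loci with negative (positive) effects.
#'
#' @param model A [genetic_model].
#' @param with_genotypes If `TRUE`, add list-columns `genotype_min` and
#'   `genotype_max` holding an attaining genotype for each bound.
#' @return A tibble with columns `parameter`, `min`, `max` (in the canonical
#'   parameter order).
#' @examples
#' parameter_bounds(peach_genetic_model())
#' @export
parameter_bounds <- function(model = peach_genetic_model(), with_genotypes = FALSE) {
  E <- effect_matrix(model)
  ic <- unlist(model$intercepts[colnames(E)])
  res <- tibble(
    parameter = colnames(E),
    min = unname(ic + colSums(pmin(E, 0))),
    max = unname(ic + colSums(pmax(E, 0)))
  )
  if (with_genotypes) {
    res$genotype_min <- lapply(seq_len(ncol(E)), function(j) as.integer(E[, j] < 0))
    res$genotype_max <- lapply(seq_len(ncol(E)), function(j) as.integer(E[, j] > 0))
  }
  res
}

#' Loci associated with each parameter of a genetic model
#'
#' @param model A [genetic_model].
#' @return Named list of integer locus vectors, one entry per parameter.
#' @export
model_loci <- function(model = peach_genetic_model()) {
  split(model$effects$locus, model$effects$parameter)[names(model$intercepts)]
}

#' Write / read a genetic model as structured text
#'
#' The serialization is a YAML document with the intercepts and the list of
#' (parameter, locus, effect) terms, so a model can be shipped, edited and
#' re-loaded without touching code. The packaged peach model is available
#' both from [peach_genetic_model()] and as
#' `system.file("extdata", "peach_genetic_model.yaml", package = "ideofruit")`.
#'
#' @param model A [genetic_model].
#' @param path File path.
#' @return `write_genetic_model()` returns `path` invisibly;
#'   `read_genetic_model()` returns a [genetic_model].
#' @export
write_genetic_model <- function(model, path) {
  obj <- list(
    n_loci = model$n_loci,
    intercepts = as.list(model$intercepts),
    effects = purrr::pmap(model$effects, function(parameter, locus, effect) {
      list(parameter = parameter, locus = locus, effect = effect)
    })
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_genetic_model
#' @export
read_genetic_model <- function(path) {
  obj <- yaml::read_yaml(path)
  effects <- purrr::map(obj$effects, as_tibble) %>% list_rbind()
  genetic_model(unlist(obj$intercepts), effects, n_loci = obj$n_loci)
}
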