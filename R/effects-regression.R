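# Re-estimation of allele effects from per-individual parameter values:
# one ordinary least-squares fit per parameter, restricted to the loci that
# carry a QTL for that parameter.

#' Estimate allele effects by linear regression
#'
#' For each model parameter, fits `value ~ intercept + sum(effect * locus)`
#' by ordinary least squares over the loci declared for that parameter. This
#' is the estimation stage that turns a phenotyped, genotyped progeny into an
#' additive genetic model.
#'
#' Perfectly collinear locus columns (e.g. two completely linked loci both
#' included for one parameter) make the effects unidentifiable; rather than
#' silently dropping terms, the fit errors and names the offending loci.
#'
#' @param genotypes Genotypes (one row per individual), as accepted by
#'   [predict_parameters()].
#' @param values Data frame of per-individual parameter values, one column
#'   per parameter named as in the model.
#' @param loci_per_parameter Named list mapping each parameter to the integer
#'   loci to regress on, e.g. `model_loci(peach_genetic_model())`.
#' @param n_loci Number of loci per genotype.
#' @return An object of class `genetic_model_fit` with elements `model` (the
#'   fitted [genetic_model]), `terms` (tibble of estimates with standard
#'   errors, t statistics and p values) and `fits` (per-parameter `lm`
#'   summaries). Use [tidy()] / [glance()] to extract tables.
#' @export
estimate_allele_effects <- function(genotypes, values,
                                    loci_per_parameter = model_loci(),
                                    n_loci = 31L) {
  g <- as_genotype_matrix(genotypes, n_loci)
  values <- as_tibble(values)
  params <- names(loci_per_parameter)
  missing <- setdiff(params, names(values))
  if (length(missing) > 0) {
    abort(paste0("`values` lacks column(s): ", paste(missing, collapse = ", ")))
  }

  fit_one <- function(p) {
    loci <- as.integer(loci_per_parameter[[p]])
    y <- values[[p]]
    keep <- !is.na(y)
    if (sum(keep) < length(loci) + 1L) {
      abort(sprintf("Parameter %s: %d non-missing individuals for %d loci + intercept.",
                    p, sum(keep), length(loci)))
    }
    X <- g[keep, loci, drop = FALSE]
    colnames(X) <- paste0("loc", loci)
    qrX <- qr(cbind(`(Intercept)` = 1, X))
    if (qrX$rank < ncol(X) + 1L) {
      dropped <- colnames(qr.R(qrX))[-seq_len(qrX$rank)]
      abort(sprintf(
        "Parameter %s: design is rank deficient; collinear term(s): %s.",
        p, paste(dropped, collapse = ", ")
      ))
    }
    fit <- lm(y[keep] ~ X)
    sm <- suppressWarnings(summary(fit)) # zero-residual fits are legitimate here
    est <- sm$coefficients
    rownames(est) <- sub("^X", "", rownames(est))
    locus_of <- rep(NA_integer_, nrow(est))
    is_loc <- grepl("^loc", rownames(est))
    locus_of[is_loc] <- as.integer(sub("^loc", "", rownames(est)[is_loc]))
    list(
      terms = tibble(
        parameter = p,
        term = rownames(est),
        locus = locus_of,
        estimate = unname(est[, "Estimate"]),
        std.error = unname(est[, "Std. Error"]),
        statistic = unname(est[, "t value"]),
        p.value = unname(est[, "Pr(>|t|)"])
      ),
      stats = tibble(
        parameter = p, n = sum(keep), r.squared = sm$r.squared,
        sigma = sm$sigma, rss = sum(sm$residuals^2)
      )
    )
  }

  fits <- lapply(params, fit_one)
  terms <- list_rbind(lapply(fits, `[[`, "terms"))
  stats <- list_rbind(lapply(fits, `[[`, "stats"))
  intercepts <- setNames(
    terms$estimate[terms$term == "(Intercept)"],
    terms$parameter[terms$term == "(Intercept)"]
  )
  eff <- terms[!is.na(terms$locus), c("parameter", "locus", "estimate")]
  names(eff)[3] <- "effect"
  structure(
    list(
      model = genetic_model(intercepts, eff, n_loci = n_loci),
      terms = terms,
      stats = stats
    ),
    class = "genetic_model_fit"
  )
}

#' @export
print.genetic_model_fit <- function(x, ...) {
  cat("<genetic_model_fit>", nrow(x$terms), "terms across",
      nrow(x$stats), "parameters\n")
  print(x$stats)
  invisible(x)
}

#' @method tidy genetic_model_fit
#' @export
tidy.genetic_model_fit <- function(x, ...) x$terms

#' @method glance genetic_model_fit
#' @export
glance.genetic_model_fit <- function(x, ...) x$stats
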