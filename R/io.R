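# Readers and writers shared by all modules. Datasets round-trip losslessly:
# numerics are printed with 17 significant digits ("%.17g"), enough to
# reconstruct every double exactly, with a locale-independent decimal point.

#' Write / read a dataset as CSV
#'
#' One row per individual; all numeric columns are serialized at full double
#' precision so `read_dataset(write_dataset(ds))` reproduces `ds` exactly.
#'
#' @param ds A data frame (e.g. from [draw_random_parameters()] or
#'   [optimize_space()]).
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` a
#'   tibble.
#' @export
write_dataset <- function(ds, path) {
  out <- as_tibble(ds)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  # base strtod parsing is correctly rounded, so "%.17g" output reparses to
  # the identical double
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read genotype tables
#'
#' Plain CSV with one row per individual and columns `loc1..locN` in {0, 1}.
#'
#' @param genotypes Genotypes as accepted by [predict_parameters()].
#' @param path File path.
#' @param n_loci Number of loci expected on read.
#' @export
write_genotypes <- function(genotypes, path, n_loci = 31L) {
  g <- as_genotype_matrix(genotypes, n_loci)
  readr::write_csv(as_tibble(genotype_tibble(g)), path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, n_loci = 31L) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  genotype_tibble(as_genotype_matrix(g, n_loci))
}

#' Read a weather table
#'
#' CSV with columns `day` (days after bloom) and `tmean` (deg C), optionally
#' a precomputed `gdd` column.
#'
#' @param path File path.
#' @return A weather tibble.
#' @export
read_weather <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("day", "tmean") %in% names(w))) {
    abort("Weather file must have columns `day` and `tmean`.")
  }
  w
}

#' Load a structured configuration file
#'
#' YAML file with optional top-level sections `growth`, `nsga` and
#' `progeny`, whose keys are the arguments of [growth_config()],
#' [nsga_control()] and [progeny_spec()]. Missing sections and keys fall
#' back to the defaults; unknown keys and out-of-range values are rejected
#' with the offending field named.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A list with elements `growth`, `nsga`, `progeny`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list() # empty file
  unknown <- setdiff(names(raw), c("growth", "nsga", "progeny"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration section(s): ", paste(unknown, collapse = ", ")))
  }
  build <- function(section, constructor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(constructor)))
    if (length(bad) > 0) {
      abort(sprintf("Unknown key(s) in `%s`: %s", section, paste(bad, collapse = ", ")))
    }
    do.call(constructor, args)
  }
  list(
    growth = build("growth", growth_config),
    nsga = build("nsga", nsga_control),
    progeny = build("progeny", progeny_spec)
  )
}

#' Write a run manifest
#'
#' JSON record sufficient to replay a run: command, configuration snapshot,
#' seed, package version, timestamp and the paths (with sizes) of the files
#' produced.
#'
#' @param path Manifest path.
#' @param command Character label of the command that ran.
#' @param config Configuration list (as from [load_config()]).
#' @param seed Integer seed used.
#' @param outputs Character vector of output file paths.
#' @export
write_manifest <- function(path, command, config = list(), seed = NA,
                           outputs = character()) {
  manifest <- list(
    command = command,
    package = "ideofruit",
    version = as.character(utils::packageVersion("ideofruit")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = lapply(outputs, function(f) {
      list(path = f, bytes = if (file.exists(f)) file.size(f) else NA)
    })
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
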