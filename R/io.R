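#' Dataset schemas
#'
#' All tabular interchange uses CSV with a header row, UTF-8 (BOM
#' tolerated), one of four schemas:
#' \describe{
#'   \item{sp}{`mouse_age_days, subset, sp_count, sp_ki67_frac`}
#'   \item{chimera}{`mouse_id, host_age, age_bmt, subset, total_count, fd,
#'     ki67_host, ki67_donor`}
#'   \item{cohort}{`mouse_id, group_age_days, time_since_label_days,
#'     labelled_count`}
#'   \item{reporter}{`mouse_age_days, gfp_count, pct_gfp_ki67pos,
#'     pct_gfp_ki67neg`}
#' }
#' @name schemas
NULL

.schemas <- list(
  sp = list(
    cols = c("mouse_age_days", "subset", "sp_count", "sp_ki67_frac"),
    rules = list(
      mouse_age_days = function(d) d$mouse_age_days > 0,
      sp_count = function(d) d$sp_count >= 0,
      sp_ki67_frac = function(d) d$sp_ki67_frac >= 0 & d$sp_ki67_frac <= 1)),
  chimera = list(
    cols = c("mouse_id", "host_age", "age_bmt", "subset", "total_count",
             "fd", "ki67_host", "ki67_donor"),
    rules = list(
      ages = function(d) d$host_age > d$age_bmt & d$age_bmt >= 0,
      total_count = function(d) d$total_count > 0,
      fd = function(d) is.na(d$fd) | (d$fd >= 0 & d$fd <= 1),
      ki67_host = function(d) is.na(d$ki67_host) |
        (d$ki67_host >= 0 & d$ki67_host <= 1),
      ki67_donor = function(d) is.na(d$ki67_donor) |
        (d$ki67_donor >= 0 & d$ki67_donor <= 1))),
  cohort = list(
    cols = c("mouse_id", "group_age_days", "time_since_label_days",
             "labelled_count"),
    rules = list(
      time_since_label_days = function(d) d$time_since_label_days >= 0,
      labelled_count = function(d) d$labelled_count >= 0,
      group_age_days = function(d) d$group_age_days > 0)),
  reporter = list(
    cols = c("mouse_age_days", "gfp_count", "pct_gfp_ki67pos",
             "pct_gfp_ki67neg"),
    rules = list(
      mouse_age_days = function(d) d$mouse_age_days > 0,
      gfp_count = function(d) d$gfp_count >= 0,
      pct_gfp_ki67pos = function(d) d$pct_gfp_ki67pos >= 0 &
        d$pct_gfp_ki67pos <= 100,
      pct_gfp_ki67neg = function(d) d$pct_gfp_ki67neg >= 0 &
        d$pct_gfp_ki67neg <= 100)))

#' Read and validate a dataset
#'
#' Reads a CSV in one of the registered schemas (see [schemas]), checks the
#' header and row-level invariants, and either fails with a violation report
#' or (with `drop_invalid = TRUE`) drops offending rows with a warning.
#' Windows line endings and a UTF-8 BOM are handled transparently.
#'
#' @param path CSV file path.
#' @param schema one of `"sp"`, `"chimera"`, `"cohort"`, `"reporter"`.
#' @param drop_invalid drop invalid rows instead of failing.
#' @return validated data frame; the violation report (if any rows were
#'   dropped) is attached as attribute `"violations"`.
#' @export
read_dataset <- function(path, schema, drop_invalid = FALSE) {
  if (!schema %in% names(.schemas)) stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .schemas[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8-BOM")
  if (!all(sc$cols %in% names(d)))
    stop("malformed ", schema, " CSV: missing columns ",
         paste(setdiff(sc$cols, names(d)), collapse = ", "))
  d <- d[, sc$cols, drop = FALSE]
  viol <- list()
  ok <- rep(TRUE, nrow(d))
  for (rule in names(sc$rules)) {
    pass <- sc$rules[[rule]](d)
    pass[is.na(pass)] <- FALSE
    if (any(!pass))
      viol[[rule]] <- data.frame(row = which(!pass), rule = rule)
    ok <- ok & pass
  }
  report <- do.call(rbind, viol)
  if (!is.null(report) && nrow(report) > 0) {
    if (!drop_invalid)
      stop(nrow(report), " invalid rows in ", path, " (first: row ",
           report$row[1], ", rule '", report$rule[1],
           "'); use drop_invalid = TRUE to drop them")
    warning("dropping ", sum(!ok), " invalid rows from ", path)
    d <- d[ok, , drop = FALSE]
  }
  attr(d, "violations") <- report
  d
}

#' Write a dataset in a registered schema
#'
#' @param data data frame containing at least the schema columns.
#' @param path output CSV path.
#' @param schema schema id (see [schemas]).
#' @export
write_dataset <- function(data, path, schema) {
  if (!schema %in% names(.schemas)) stop("unknown schema: ", schema)
  utils::write.csv(data[, .schemas[[schema]]$cols, drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records what produced an output bundle: inputs (with content hashes),
#' seed, parameters and package version, so any output is reproducible from
#' its manifest.
#'
#' @param path JSON file to write.
#' @param ... named entries to record (parameter lists, seeds, file paths).
#' @export
write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$package <- "naivedyn"
  entries$version <- as.character(utils::packageVersion("naivedyn"))
  paths <- vapply(entries, function(x)
    is.character(x) && length(x) == 1 && file.exists(x), TRUE)
  if (any(paths))
    entries$input_hashes <- lapply(entries[paths], function(f)
      unname(tools::md5sum(f)))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path config file; `.json` is parsed with jsonlite, anything else
#'   with yaml (if installed).
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) return(jsonlite::read_json(path,
                                                          simplifyVector = TRUE))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("yaml package needed for non-JSON configs")
  yaml::read_yaml(path)
}

#' Fit all candidate variants and rank them
#'
#' Convenience orchestration of the generate -> fit -> compare workflow:
#' fits each requested variant to a chimera dataset and returns the pseudo-
#' BMA ranking table.
#'
#' @param data chimera observations.
#' @param variants character vector of model variants to fit.
#' @param influx an [influx_descriptor()].
#' @param seed integer seed (per-variant streams are derived from it).
#' @param ... passed to [fit_model()].
#' @return comparison table from [compare_models()], with fits attached as
#'   attribute `"fits"`.
#' @export
compare_model_variants <- function(data, variants, influx, seed = 1, ...) {
  fits <- lapply(seq_along(variants), function(i)
    fit_model(data, variants[i], influx, seed = seed + i, ...))
  names(fits) <- variants
  out <- compare_models(fits, seed = seed)
  attr(out, "fits") <- fits
  out
}
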