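config_registry <- function() {
  p <- preprocess_params(); s <- search_params()
  list(
    preprocess.window_top_k = list(default = p$window_top_k, type = "integer"),
    preprocess.window_half_width = list(default = p$window_half_width, type = "numeric"),
    preprocess.apply_sqrt = list(default = p$apply_sqrt, type = "logical"),
    preprocess.remove_precursor_region = list(default = p$remove_precursor_region, type = "logical"),
    preprocess.precursor_exclusion_width = list(default = p$precursor_exclusion_width, type = "numeric"),
    search.parent_mass_tol = list(default = s$parent_mass_tol, type = "numeric"),
    search.ion_tol = list(default = s$ion_tol, type = "numeric"),
    search.min_matched_peaks = list(default = s$min_matched_peaks, type = "integer"),
    search.min_cosine = list(default = s$min_cosine, type = "numeric"),
    search.analog_mode = list(default = s$analog_mode, type = "logical"),
    search.max_precursor_shift = list(default = s$max_precursor_shift, type = "numeric")
  )
}

coerce_config_value <- function(key, value, type) {
  if (type == "logical") {
    v <- toupper(trimws(as.character(value)))
    if (v %in% c("TRUE", "T", "YES", "ON", "1")) return(TRUE)
    if (v %in% c("FALSE", "F", "NO", "OFF", "0")) return(FALSE)
    stop("config key '", key, "' expects a logical, got '", value, "'")
  }
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) stop("config key '", key, "' expects ",
                     if (type == "integer") "an integer" else "a number",
                     ", got '", value, "'")
  if (type == "integer") {
    if (v != as.integer(v)) stop("config key '", key, "' expects an integer, got '", value, "'")
    return(as.integer(v))
  }
  v
}

#' Load the effective run configuration
#'
#' Merges three layers with strict precedence — built-in defaults, then a
#' configuration file, then explicit overrides (command-line flags) — so
#' every parameter has exactly one effective value. The defaults are the
#' standard small-molecule identity-search settings (parent mass tolerance
#' 0.1 Da, ion tolerance 0.1 Da, 6 minimum matched peaks, cosine threshold
#' 0.65, top-6 / ±50 Da / square-root preprocessing).
#'
#' The file format is plain `key = value` text, one pair per line, `#`
#' comments allowed. Valid keys are the dotted names
#' `preprocess.window_top_k`, `preprocess.window_half_width`,
#' `preprocess.apply_sqrt`, `preprocess.remove_precursor_region`,
#' `preprocess.precursor_exclusion_width`, `search.parent_mass_tol`,
#' `search.ion_tol`, `search.min_matched_peaks`, `search.min_cosine`,
#' `search.analog_mode`, `search.max_precursor_shift`. Unknown keys are an
#' error listing the valid ones; so is a type mismatch.
#'
#' @param path optional configuration file path.
#' @param overrides named list of `key = value` pairs applied last.
#' @return an object of class `"run_config"`: a list with `$preprocess`
#'   (a [preprocess_params()]), `$search` (a [search_params()]) and
#'   `$effective` (the flat merged key-value list).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  reg <- config_registry()
  eff <- lapply(reg, `[[`, "default")

  apply_kv <- function(key, value, origin) {
    if (!key %in% names(reg))
      stop("unknown config key '", key, "' (", origin, "); valid keys: ",
           paste(names(reg), collapse = ", "))
    eff[[key]] <<- coerce_config_value(key, value, reg[[key]]$type)
  }

  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
      line <- trimws(sub("#.*$", "", lines[i]))
      if (!nzchar(line)) next
      if (!grepl("=", line, fixed = TRUE))
        stop("config parse error at line ", i, ": expected 'key = value', got '", lines[i], "'")
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      apply_kv(key, val, paste0("file ", path, " line ", i))
    }
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a fully named list")
    for (key in names(overrides)) apply_kv(key, overrides[[key]], "override")
  }

  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(eff), value = TRUE)
    stats::setNames(eff[keys], sub(paste0("^", prefix, "\\."), "", keys))
  }
  structure(list(
    preprocess = do.call(preprocess_params, pick("preprocess")),
    search = do.call(search_params, pick("search")),
    effective = eff
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x$effective))
    cat(sprintf("  %-38s %s\n", k, format(x$effective[[k]])))
  invisible(x)
}

#' Run a full repository search end to end
#'
#' Convenience composition of the pipeline the command line drives: build
#' (or reuse) an index, search one or more queries, and write the report
#' bundle. Provided so scripted use needs a single call.
#'
#' @param queries list of query `"spectrum"` objects (or a single spectrum).
#' @param index a `"reference_index"`.
#' @param o the `"food_ontology"`.
#' @param out_dir report output directory, or `NULL` to skip writing.
#' @param config a [load_config()] result.
#' @param provenance optional named list recorded in `summary.json`.
#' @return a list with `matches` (all queries pooled), `prevalence`,
#'   `stats`, and `files` (written paths, when `out_dir` given).
#' @export
run_search <- function(queries, index, o, out_dir = NULL,
                       config = load_config(), provenance = list()) {
  if (inherits(queries, "spectrum")) queries <- list(queries)
  matches <- do.call(rbind, c(list(empty_matches()),
                              lapply(queries, search_spectrum, index = index,
                                     p = config$search)))
  prev <- prevalence_table(unique(matches$sample_id), index$samples, o)
  out <- list(matches = matches,
              prevalence = prev,
              stats = summary_stats(matches, index))
  if (!is.null(out_dir))
    out$files <- write_reports(matches, index$samples, o, out_dir,
                               params = config$search, prep = config$preprocess,
                               provenance = provenance)
  out
}
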