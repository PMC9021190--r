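#' Matched-file metadata report
#'
#' One row per distinct matched sample: identifier, source file, terminal
#' ontology term, the best (highest) cosine among that sample's matches,
#' the matched-peak count of that best match, and every metadata column the
#' sample carries. Sorted by best score descending, ties by sample id.
#'
#' @param matches match `data.frame` from [search_spectrum()].
#' @param samples sample metadata `data.frame`.
#' @return a `data.frame`; zero matches give a header-only (zero-row) table.
#' @export
matched_files_report <- function(matches, samples) {
  unknown <- setdiff(unique(matches$sample_id), samples$sample_id)
  if (length(unknown))
    stop("match references unknown sample_id: ", paste(unknown, collapse = ", "))
  meta_cols <- setdiff(names(samples), c("sample_id", "filename", "terminal_term"))
  if (nrow(matches) == 0L) {
    out <- data.frame(sample_id = character(), filename = character(),
                      terminal_term = character(), best_score = numeric(),
                      best_n_matched_peaks = integer(), stringsAsFactors = FALSE)
    for (mc in meta_cols) out[[mc]] <- character()
    return(out)
  }
  # best match per sample: matches arrive score-sorted, but do not rely on it
  ord <- order(-matches$score, matches$sample_id, matches$spectrum_id)
  m <- matches[ord, , drop = FALSE]
  best <- m[!duplicated(m$sample_id), , drop = FALSE]
  ri <- match(best$sample_id, samples$sample_id)
  out <- data.frame(sample_id = best$sample_id,
                    filename = samples$filename[ri],
                    terminal_term = samples$terminal_term[ri],
                    best_score = best$score,
                    best_n_matched_peaks = best$n_matched_peaks,
                    stringsAsFactors = FALSE)
  for (mc in meta_cols) out[[mc]] <- samples[[mc]][ri]
  out <- out[order(-out$best_score, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical tree export of prevalence
#'
#' Nests the ontology into a tree rooted at the ontology root (a synthetic
#' super-root named `"(all)"` joins several roots), each node carrying the
#' term's total sample count, matched sample count and exact matched
#' fraction. This is the structure behind the pie-chart tree view — node
#' size encodes the total samples under a term, the pie encodes the matched
#' versus unmatched share. A term with multiple parents is duplicated under
#' each parent with identical counts, since the rendering is a tree view of
#' the DAG. Terms with zero samples are kept with zero counts so the tree
#' stays complete.
#'
#' @param prev prevalence `data.frame` from [prevalence_table()].
#' @param o the `"food_ontology"` the prevalence was computed from.
#' @param n_samples total number of reference samples.
#' @param n_matched number of distinct matched samples.
#' @return nested list: `list(name, total, matched, fraction, children)`,
#'   suitable for a flare-style JSON tree renderer.
#' @export
tree_export <- function(prev, o, n_samples, n_matched) {
  stopifnot(inherits(o, "food_ontology"))
  unknown <- setdiff(prev$term, o$terms)
  if (length(unknown))
    stop("prevalence term(s) absent from ontology: ", paste(unknown, collapse = ", "))
  kids <- ontology_children(o)
  totals <- stats::setNames(rep(0L, length(o$terms)), o$terms)
  matched <- totals
  totals[prev$term] <- prev$n_total
  matched[prev$term] <- prev$n_matched
  node <- function(t) {
    nt <- totals[[t]]; nm <- matched[[t]]
    list(name = t,
         total = nt,
         matched = nm,
         fraction = if (nt > 0L) nm / nt else 0,
         children = lapply(kids[[t]], node))
  }
  roots <- ontology_roots(o)
  if (length(roots) == 1L) return(node(roots))
  list(name = "(all)", total = as.integer(n_samples),
       matched = as.integer(n_matched),
       fraction = if (n_samples > 0) n_matched / n_samples else 0,
       children = lapply(sort(roots), node))
}

format_num <- function(x) {
  # fixed-notation, trailing-zero-free numeric formatting for stable bytes
  ifelse(x == as.integer(x), sprintf("%d", as.integer(x)),
         sub("0+$", "", sprintf("%.10f", x)))
}

write_tsv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cells <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) format_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(cells, sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write the full report bundle for one search
#'
#' Emits four files into `out_dir`:
#' \describe{
#'   \item{prevalence.tsv}{per-term counts with the matched percentage
#'     rendered to one decimal (the exact fraction lives in tree.json).}
#'   \item{matched_files.tsv}{the [matched_files_report()] table.}
#'   \item{summary.json}{search statistics plus a provenance block
#'     (package version, effective parameters, input digests when given)
#'     sufficient to re-run the identical search.}
#'   \item{tree.json}{the [tree_export()] hierarchy with exact fractions.}
#' }
#' Output bytes are deterministic for fixed input: stable sorting and fixed
#' numeric formatting throughout.
#'
#' @param matches match `data.frame` from [search_spectrum()].
#' @param samples sample metadata `data.frame`.
#' @param o the `"food_ontology"`.
#' @param out_dir output directory (created if needed).
#' @param params the [search_params()] used (recorded in provenance).
#' @param prep the [preprocess_params()] used (recorded in provenance).
#' @param provenance optional named list merged into the provenance block
#'   (e.g., input file digests from the command line).
#' @return character vector of the four file paths, invisibly.
#' @export
write_reports <- function(matches, samples, o, out_dir,
                          params = search_params(),
                          prep = preprocess_params(),
                          provenance = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  matched_ids <- unique(matches$sample_id)
  prev <- prevalence_table(matched_ids, samples, o)

  prev_out <- data.frame(term = prev$term,
                         n_matched = prev$n_matched,
                         n_total = prev$n_total,
                         percent = sprintf("%.1f", 100 * prev$fraction),
                         stringsAsFactors = FALSE)
  p_prev <- file.path(out_dir, "prevalence.tsv")
  write_tsv_stable(prev_out, p_prev)

  p_files <- file.path(out_dir, "matched_files.tsv")
  write_tsv_stable(matched_files_report(matches, samples), p_files)

  tree <- tree_export(prev, o, nrow(samples), length(matched_ids))
  p_tree <- file.path(out_dir, "tree.json")
  jsonlite::write_json(tree, p_tree, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stats <- list(
    n_matching_spectra = nrow(matches),
    n_samples_matched = length(matched_ids),
    n_files_matched = length(unique(samples$filename[samples$sample_id %in% matched_ids])),
    n_terminal_terms_matched = length(unique(samples$terminal_term[samples$sample_id %in% matched_ids]))
  )
  summary <- list(
    statistics = stats,
    provenance = c(list(tool = "spectront",
                        version = as.character(utils::packageVersion("spectront")),
                        parameters = c(unclass(params),
                                       stats::setNames(unclass(prep),
                                                       paste0("preprocess.", names(unclass(prep)))))),
                   provenance)
  )
  p_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(p_prev, p_files, p_sum, p_tree))
}
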