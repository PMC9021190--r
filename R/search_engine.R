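#' Search parameters
#'
#' Matching thresholds and mode flags for a repository search. The defaults
#' are the standard settings for an identity search of a small molecule on
#' Q-TOF data: 0.1 Da parent (precursor) mass tolerance, 0.1 Da ion
#' tolerance, at least 6 matched fragment peaks and a cosine score of at
#' least 0.65.
#'
#' @param parent_mass_tol precursor m/z tolerance in Da (identity mode).
#' @param ion_tol fragment ion tolerance in Da.
#' @param min_matched_peaks minimum one-to-one matched peak count.
#' @param min_cosine minimum cosine score, in (0, 1].
#' @param analog_mode search structural analogs with the modified cosine and
#'   a widened precursor window.
#' @param max_precursor_shift precursor window half-width in Da used in
#'   analog mode.
#' @return an object of class `"search_params"`.
#' @export
search_params <- function(parent_mass_tol = 0.1,
                          ion_tol = 0.1,
                          min_matched_peaks = 6L,
                          min_cosine = 0.65,
                          analog_mode = FALSE,
                          max_precursor_shift = 100) {
  min_matched_peaks <- as.integer(min_matched_peaks)
  stopifnot(parent_mass_tol > 0, ion_tol > 0, max_precursor_shift > 0,
            min_matched_peaks >= 1L, min_cosine > 0, min_cosine <= 1,
            is.logical(analog_mode))
  structure(list(parent_mass_tol = as.numeric(parent_mass_tol),
                 ion_tol = as.numeric(ion_tol),
                 min_matched_peaks = min_matched_peaks,
                 min_cosine = as.numeric(min_cosine),
                 analog_mode = isTRUE(analog_mode),
                 max_precursor_shift = as.numeric(max_precursor_shift)),
            class = "search_params")
}

#' Build a searchable reference index
#'
#' Preprocesses every reference spectrum once, drops spectra left empty by
#' preprocessing (with a warning), sorts by precursor m/z for binary range
#' queries, and links each spectrum to its sample.
#'
#' @param spectra list of `"spectrum"` objects (raw; preprocessing is
#'   applied here).
#' @param samples sample metadata `data.frame` as from
#'   [read_metadata_table()], or `NULL` for a bare spectral library in which
#'   each spectrum is its own pseudo-sample (see [library_annotate()]).
#' @param link named character vector or two-column `data.frame`
#'   (`spectrum_id`, `sample_id`) mapping each spectrum to one sample.
#'   Defaults to each spectrum id mapping to itself when `samples` is NULL.
#' @param prep a [preprocess_params()] object.
#' @return an object of class `"reference_index"`.
#' @export
build_index <- function(spectra, samples = NULL, link = NULL,
                        prep = preprocess_params()) {
  stopifnot(is.list(spectra))
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate spectrum_id in reference spectra: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.data.frame(link)) {
    stopifnot(all(c("spectrum_id", "sample_id") %in% names(link)))
    link <- stats::setNames(as.character(link$sample_id), link$spectrum_id)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = ids, filename = ids,
                          terminal_term = NA_character_,
                          stringsAsFactors = FALSE)
    if (is.null(link)) link <- stats::setNames(ids, ids)
  }
  if (is.null(link)) stop("a spectrum_id -> sample_id link is required")
  missing_link <- setdiff(ids, names(link))
  if (length(missing_link))
    stop("no sample link for spectrum_id: ", paste(missing_link, collapse = ", "))
  dangling <- setdiff(unname(link[ids]), samples$sample_id)
  if (length(dangling))
    stop("spectrum links to unknown sample_id: ", paste(dangling, collapse = ", "))

  prepped <- lapply(spectra, preprocess_spectrum, p = prep)
  empty <- vapply(prepped, function(s) isTRUE(attr(s, "empty_after_preprocess")),
                  logical(1))
  if (any(empty)) {
    warning(sum(empty), " reference spectrum/spectra empty after preprocessing, dropped: ",
            paste(ids[empty], collapse = ", "))
    prepped <- prepped[!empty]
    ids <- ids[!empty]
  }
  prec <- vapply(prepped, function(s) s$precursor_mz, numeric(1))
  ord <- order(prec, ids)
  structure(list(spectra = prepped[ord],
                 precursor_mz = prec[ord],
                 spectrum_id = ids[ord],
                 spectrum_sample = link[ids[ord]],
                 samples = samples,
                 prep = prep),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d spectra, %d samples\n",
              length(x$spectra), nrow(x$samples)))
  invisible(x)
}

#' Candidate spectra within the precursor window
#'
#' Identity mode retrieves indexed spectra with
#' `|precursor - query_precursor| <= parent_mass_tol`; analog mode widens
#' the window to `max_precursor_shift`. The binary range query over the
#' precursor-sorted index is equivalent to a linear scan.
#'
#' @param index a `"reference_index"`.
#' @param query_precursor query precursor m/z in Da.
#' @param p a [search_params()] object.
#' @return integer vector of positions into `index$spectra`.
#' @export
candidate_range <- function(index, query_precursor, p = search_params()) {
  stopifnot(inherits(index, "reference_index"))
  tol <- if (p$analog_mode) p$max_precursor_shift else p$parent_mass_tol
  lo <- findInterval(query_precursor - tol, index$precursor_mz, left.open = TRUE) + 1L
  hi <- findInterval(query_precursor + tol, index$precursor_mz)
  if (lo > hi) integer(0) else lo:hi
}

empty_matches <- function() {
  data.frame(query_id = character(), spectrum_id = character(),
             sample_id = character(), score = numeric(),
             n_matched_peaks = integer(), precursor_delta = numeric(),
             stringsAsFactors = FALSE)
}

#' Search a query spectrum against a reference index
#'
#' The query is preprocessed identically to the reference, candidates within
#' the precursor window are scored (cosine similarity in identity mode, the
#' modified cosine in analog mode), and every candidate passing both gates —
#' `score >= min_cosine` and `n_matched_peaks >= min_matched_peaks` — is
#' returned. All passing matches are reported; there is no top-N cap.
#'
#' @param query a `"spectrum"`.
#' @param index a `"reference_index"` from [build_index()].
#' @param p a [search_params()] object.
#' @return a `data.frame` of matches with columns `query_id`, `spectrum_id`
#'   (reference), `sample_id`, `score`, `n_matched_peaks`,
#'   `precursor_delta` (reference minus query, Da), sorted by score
#'   descending, then smaller `|precursor_delta|`, then reference id. A
#'   query empty after preprocessing returns zero rows with a warning.
#' @export
search_spectrum <- function(query, index, p = search_params()) {
  stopifnot(inherits(index, "reference_index"), inherits(p, "search_params"))
  q <- preprocess_spectrum(query, index$prep)
  if (isTRUE(attr(q, "empty_after_preprocess"))) {
    warning("query '", query$spectrum_id, "' is empty after preprocessing; no search performed")
    return(empty_matches())
  }
  cand <- candidate_range(index, q$precursor_mz, p)
  if (!length(cand)) return(empty_matches())
  rows <- lapply(cand, function(ci) {
    ref <- index$spectra[[ci]]
    sr <- if (p$analog_mode) modified_cosine(q, ref, p$ion_tol)
          else cosine_similarity(q, ref, p$ion_tol)
    if (sr$score >= p$min_cosine && sr$n_matched_peaks >= p$min_matched_peaks)
      data.frame(query_id = q$spectrum_id,
                 spectrum_id = index$spectrum_id[ci],
                 sample_id = unname(index$spectrum_sample[ci]),
                 score = sr$score,
                 n_matched_peaks = sr$n_matched_peaks,
                 precursor_delta = sr$precursor_delta,
                 stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_matches())
  m <- do.call(rbind, rows)
  m <- m[order(-m$score, abs(m$precursor_delta), m$spectrum_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Annotate a query against a spectral library
#'
#' Same gating as [search_spectrum()], run against an index built from
#' annotated library spectra. All passing annotations are reported — when
#' several isomer entries (e.g., leucine/isoleucine stereoisomers) score
#' above threshold, every one appears, sorted by score. An empty result
#' means the molecule is unknown to the library; a repository search can
#' still proceed.
#'
#' @param query a `"spectrum"`.
#' @param library_index a `"reference_index"` over library spectra. The
#'   annotation is taken from the sample metadata column `annotation` when
#'   present, else from the library spectrum id (typically the compound name
#'   in the MGF TITLE).
#' @param p a [search_params()] object.
#' @return the match `data.frame` of [search_spectrum()] with an extra
#'   `annotation` column.
#' @export
library_annotate <- function(query, library_index, p = search_params()) {
  m <- search_spectrum(query, library_index, p)
  ann <- if ("annotation" %in% names(library_index$samples)) {
    library_index$samples$annotation[match(m$sample_id, library_index$samples$sample_id)]
  } else {
    m$spectrum_id
  }
  m$annotation <- as.character(ann)
  m
}

#' Summary counts for one search
#'
#' @param matches match `data.frame` from one [search_spectrum()] call.
#' @param index the `"reference_index"` that produced them.
#' @return a list with `n_matching_spectra`, `n_files`, `n_samples`,
#'   `n_terminal_terms` (distinct terminal ontology terms among matched
#'   samples).
#' @export
summary_stats <- function(matches, index) {
  sm <- index$samples[match(unique(matches$sample_id), index$samples$sample_id), , drop = FALSE]
  list(n_matching_spectra = nrow(matches),
       n_files = length(unique(sm$filename)),
       n_samples = length(unique(matches$sample_id)),
       n_terminal_terms = length(unique(sm$terminal_term[!is.na(sm$terminal_term)])))
}
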