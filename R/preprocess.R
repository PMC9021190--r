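#' Preprocessing parameters
#'
#' Bundles the spectral cleanup settings applied before searching: windowed
#' top-k peak filtering followed by a square-root intensity transform. The
#' defaults keep the 6 most intense ions within a sliding +/-50 Da window
#' (100 Da effective width) and then square-root the intensities, which
#' makes searches robust to data collected with different collision
#' energies, noise levels or instruments.
#'
#' @param window_top_k peaks retained per window (default 6).
#' @param window_half_width half-width of the per-peak centered window in Da
#'   (default 50, i.e. a 100 Da effective window).
#' @param apply_sqrt square-root the intensities after filtering (default TRUE).
#' @param remove_precursor_region drop peaks near/above the precursor before
#'   filtering (default FALSE; not part of the standard cleanup but common
#'   in repository searching).
#' @param precursor_exclusion_width width in Da of the excluded region
#'   around the precursor (default 17; used only when
#'   `remove_precursor_region` is TRUE).
#' @return an object of class `"preprocess_params"`.
#' @export
preprocess_params <- function(window_top_k = 6L,
                              window_half_width = 50,
                              apply_sqrt = TRUE,
                              remove_precursor_region = FALSE,
                              precursor_exclusion_width = 17) {
  window_top_k <- as.integer(window_top_k)
  stopifnot(window_top_k >= 1L, window_half_width > 0,
            precursor_exclusion_width >= 0,
            is.logical(apply_sqrt), is.logical(remove_precursor_region))
  structure(list(window_top_k = window_top_k,
                 window_half_width = as.numeric(window_half_width),
                 apply_sqrt = isTRUE(apply_sqrt),
                 remove_precursor_region = isTRUE(remove_precursor_region),
                 precursor_exclusion_width = as.numeric(precursor_exclusion_width)),
            class = "preprocess_params")
}

#' Windowed top-k peak filter
#'
#' A peak survives iff it ranks among the `k` most intense peaks of the
#' spectrum whose m/z lies within `half_width` Da of its own m/z — a
#' per-peak centered (sliding) window, not fixed bins. Ranking is by
#' intensity descending, ties broken by lower m/z first, then by input
#' order, so the filter is deterministic. Retained peaks keep their original
#' m/z and intensity; the operation is idempotent.
#'
#' @param s a `"spectrum"`.
#' @param k peaks retained per window.
#' @param half_width window half-width in Da.
#' @return the filtered `"spectrum"` (possibly empty).
#' @export
window_top_k_filter <- function(s, k = 6L, half_width = 50) {
  validate_spectrum(s, allow_empty = TRUE)
  stopifnot(k >= 1L, half_width > 0)
  n <- length(s$mz)
  if (n <= k) return(s)
  keep <- logical(n)
  lo <- findInterval(s$mz - half_width, s$mz, left.open = TRUE) + 1L
  hi <- findInterval(s$mz + half_width, s$mz)
  for (i in seq_len(n)) {
    idx <- lo[i]:hi[i]
    # rank of i within its window: higher intensity first, ties by lower mz,
    # then lower index (mz ties share the sorted input order)
    better <- s$intensity[idx] > s$intensity[i] |
      (s$intensity[idx] == s$intensity[i] & idx < i)
    keep[i] <- sum(better) < k
  }
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Square-root intensity transform
#'
#' Replaces every intensity by its square root; m/z values and the rank
#' order of intensities are unchanged. Damps the dominance of base peaks so
#' the cosine reflects shared fragments rather than one tall ion.
#'
#' @param s a `"spectrum"`.
#' @return the transformed `"spectrum"`.
#' @export
sqrt_transform <- function(s) {
  validate_spectrum(s, allow_empty = TRUE)
  s$intensity <- sqrt(s$intensity)
  s
}

#' Preprocess a spectrum for searching
#'
#' Applies, in order: optional precursor-region removal, the windowed top-k
#' filter, and the square-root transform (when enabled). Deterministic:
#' identical input gives identical output. A spectrum left with zero peaks
#' is returned with attribute `empty_after_preprocess = TRUE`; the search
#' layer skips such spectra with a warning.
#'
#' @param s a `"spectrum"`.
#' @param p a [preprocess_params()] object.
#' @return the preprocessed `"spectrum"`.
#' @export
preprocess_spectrum <- function(s, p = preprocess_params()) {
  validate_spectrum(s)
  stopifnot(inherits(p, "preprocess_params"))
  if (p$remove_precursor_region) {
    keep <- abs(s$mz - s$precursor_mz) > p$precursor_exclusion_width
    s$mz <- s$mz[keep]
    s$intensity <- s$intensity[keep]
  }
  s <- window_top_k_filter(s, k = p$window_top_k, half_width = p$window_half_width)
  if (p$apply_sqrt) s <- sqrt_transform(s)
  if (length(s$mz) == 0L) attr(s, "empty_after_preprocess") <- TRUE
  s
}
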