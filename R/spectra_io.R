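#' Construct an MS/MS spectrum
#'
#' A spectrum is one tandem-MS scan: a precursor (parent) m/z plus a peak
#' list of fragment m/z values and intensities. Peaks are stored as parallel
#' numeric vectors sorted ascending by m/z; duplicate m/z values are
#' preserved (never merged), since downstream scoring uses a one-to-one peak
#' matching that handles duplicates naturally.
#'
#' @param spectrum_id opaque identifier (character scalar).
#' @param precursor_mz precursor m/z in Da; must be positive.
#' @param mz numeric vector of fragment m/z values (Da), each positive.
#' @param intensity numeric vector of non-negative abundances (arbitrary
#'   units), same length as `mz`.
#' @param charge optional positive integer precursor charge; `NA` means
#'   unknown. Charge is never used in scoring.
#' @param allow_empty allow a zero-peak spectrum (used internally for the
#'   empty-after-preprocess condition); user-constructed spectra need at
#'   least one peak.
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, mz, intensity, charge = NA_integer_,
                     allow_empty = FALSE) {
  s <- structure(
    list(
      spectrum_id = as.character(spectrum_id)[1L],
      precursor_mz = as.numeric(precursor_mz)[1L],
      charge = as.integer(charge)[1L],
      mz = as.numeric(mz),
      intensity = as.numeric(intensity)
    ),
    class = "spectrum"
  )
  if (length(s$mz) != length(s$intensity))
    stop("mz and intensity must have equal length")
  ord <- order(s$mz)
  s$mz <- s$mz[ord]
  s$intensity <- s$intensity[ord]
  validate_spectrum(s, allow_empty = allow_empty)
  s
}

#' Validate a spectrum's structural invariants
#'
#' Checks m/z positivity, non-negative intensities, ascending m/z order and
#' (unless `allow_empty`) the presence of at least one peak.
#'
#' @param s a `"spectrum"` object.
#' @param allow_empty permit zero peaks.
#' @return `s`, invisibly; errors otherwise.
#' @export
validate_spectrum <- function(s, allow_empty = FALSE) {
  stopifnot(inherits(s, "spectrum"))
  if (!is.character(s$spectrum_id) || length(s$spectrum_id) != 1L || is.na(s$spectrum_id))
    stop("spectrum_id must be a single non-NA string")
  if (!is.finite(s$precursor_mz) || s$precursor_mz <= 0)
    stop("precursor_mz must be a positive finite number")
  if (length(s$mz) != length(s$intensity))
    stop("mz and intensity must have equal length")
  if (!allow_empty && length(s$mz) == 0L)
    stop("spectrum '", s$spectrum_id, "' has no peaks")
  if (length(s$mz)) {
    if (any(!is.finite(s$mz)) || any(s$mz <= 0))
      stop("all peak m/z values must be positive and finite")
    if (any(!is.finite(s$intensity)) || any(s$intensity < 0))
      stop("all peak intensities must be non-negative and finite")
    if (is.unsorted(s$mz))  # ties allowed: non-strict ascending
      stop("peaks must be sorted ascending by m/z")
  }
  if (!is.na(s$charge) && s$charge <= 0L)
    stop("charge, when known, must be a positive integer")
  invisible(s)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s'> precursor m/z %.4f, %d peak%s",
              x$spectrum_id, x$precursor_mz, length(x$mz),
              if (length(x$mz) == 1L) "" else "s"))
  if (!is.na(x$charge)) cat(sprintf(", charge %d+", x$charge))
  cat("\n")
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$mz)

# parse CHARGE tokens like "2+", "2", "+2"; returns NA on anything else
parse_charge <- function(token) {
  token <- trimws(token)
  m <- regmatches(token, regexec("^\\+?([0-9]+)\\+?$", token))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

#' Read spectra from an MGF (Mascot Generic Format) file
#'
#' Parses BEGIN IONS / END IONS blocks. The first numeric value of PEPMASS
#' becomes the precursor m/z (an optional second, intensity, value is
#' ignored); TITLE becomes the spectrum id, falling back to
#' `spectrum_<ordinal>` when absent; CHARGE tokens like `"2+"` are parsed to
#' an integer and may be absent. Peaks are sorted ascending by m/z on load.
#'
#' @param path path to an MGF text file.
#' @return a list of `"spectrum"` objects; an empty file yields an empty
#'   list. Malformed blocks (missing PEPMASS, no peaks, a non-numeric peak
#'   line) raise a parse error naming the offending line number.
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- 0L
  title <- NULL; pepmass <- NULL; charge <- NA_integer_
  mz <- numeric(); inten <- numeric()
  ordinal <- 0L

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (!in_block) {
      if (line == "BEGIN IONS") {
        in_block <- TRUE; block_start <- i
        title <- NULL; pepmass <- NULL; charge <- NA_integer_
        mz <- numeric(); inten <- numeric()
      } else {
        stop("MGF parse error at line ", i, ": expected BEGIN IONS, got '", line, "'")
      }
    } else if (line == "END IONS") {
      ordinal <- ordinal + 1L
      if (is.null(pepmass))
        stop("MGF parse error: block ending at line ", i, " has no PEPMASS")
      if (length(mz) == 0L)
        stop("MGF parse error: block ending at line ", i, " has no peaks")
      id <- if (is.null(title)) sprintf("spectrum_%d", ordinal) else title
      spectra[[length(spectra) + 1L]] <-
        spectrum(id, pepmass, mz, inten, charge = charge)
      in_block <- FALSE
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "PEPMASS") {
        first <- strsplit(trimws(val), "[[:space:]]+")[[1]][1]
        pepmass <- suppressWarnings(as.numeric(first))
        if (is.na(pepmass))
          stop("MGF parse error at line ", i, ": non-numeric PEPMASS '", val, "'")
      } else if (key == "TITLE") {
        title <- trimws(val)
      } else if (key == "CHARGE") {
        charge <- parse_charge(val)
      } # other headers (RTINSECONDS, SCANS, ...) are ignored
    } else {
      tok <- strsplit(line, "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(tok[1:2]))
      if (length(tok) < 2L || any(is.na(vals)))
        stop("MGF parse error at line ", i, ": expected 'mz intensity', got '", line, "'")
      mz <- c(mz, vals[1]); inten <- c(inten, vals[2])
    }
  }
  if (in_block)
    stop("MGF parse error: block starting at line ", block_start, " has no END IONS")
  spectra
}

#' Write spectra to an MGF file
#'
#' Output is byte-stable: fixed field order (TITLE, PEPMASS, CHARGE when
#' known), peaks as `mz<space>intensity` with 6 decimal places, Unix line
#' endings. `read_mgf(write_mgf(x))` is the identity on spectra whose values
#' are representable at 6 decimals.
#'
#' @param spectra list of `"spectrum"` objects (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(is.list(spectra))
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  for (s in spectra) {
    validate_spectrum(s)
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$spectrum_id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (!is.na(s$charge)) sprintf("CHARGE=%d+", s$charge),
      sprintf("%.6f %.6f", s$mz, s$intensity),
      "END IONS",
      ""
    )
    out <- c(out, block)
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Each row describes one reference sample: an identifier, its source file
#' name, the most specific (terminal) ontology term it was labeled with, and
#' any number of free metadata columns (e.g., raw/cooked, origin), which are
#' preserved.
#'
#' @param path delimited text file with a header. Mandatory columns:
#'   `terminal_term` and at least one of `sample_id` / `filename` (when
#'   `sample_id` is absent, `filename` doubles as the identifier).
#' @param sep field delimiter; tab by default, `","` for CSV.
#' @return a `data.frame` with columns `sample_id`, `filename`,
#'   `terminal_term`, followed by any extra metadata columns, all character.
#'   Duplicate sample ids are an error.
#' @export
read_metadata_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("metadata table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  missing <- setdiff("terminal_term", names(df))
  if (!any(c("sample_id", "filename") %in% names(df)))
    missing <- c("sample_id (or filename)", missing)
  if (length(missing))
    stop("metadata table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"sample_id" %in% names(df)) df$sample_id <- df$filename
  if (!"filename" %in% names(df)) df$filename <- df$sample_id
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  core <- c("sample_id", "filename", "terminal_term")
  df <- df[, c(core, setdiff(names(df), core)), drop = FALSE]
  rownames(df) <- NULL
  df
}
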