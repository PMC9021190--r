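# small deterministic fixture shared by the search tests
search_fixture <- function(seed = 42L, n_samples = 60L) {
  cfg <- sim_config(seed = seed, n_samples = n_samples, spectra_per_sample = 2L)
  o <- make_ontology(cfg)
  ref <- make_reference(cfg, o)
  q <- make_query(cfg)
  spiked <- spike_in(ref, q, cfg)
  list(cfg = cfg, ontology = o, ref = spiked$reference, truth = spiked$truth,
       query = q,
       index = build_index(spiked$reference$spectra, spiked$reference$samples,
                           spiked$reference$link))
}

test_that("index construction preprocesses, sorts and validates sample links", {
  set.seed(401)
  spectra <- lapply(1:10, function(i) random_test_spectrum(sprintf("sp%02d", i)))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        filename = paste0("s", 1:4, ".mzML"),
                        terminal_term = "leaf", stringsAsFactors = FALSE)
  link <- setNames(paste0("s", rep(1:4, length.out = 10)),
                   vapply(spectra, function(s) s$spectrum_id, character(1)))
  idx <- build_index(spectra, samples, link)
  expect_length(idx$spectra, 10)
  expect_false(is.unsorted(idx$precursor_mz))
  # preprocessing was applied at build time (sqrt shrinks intensities)
  raw_max <- max(vapply(spectra, function(s) max(s$intensity), numeric(1)))
  idx_max <- max(vapply(idx$spectra, function(s) max(s$intensity), numeric(1)))
  expect_lt(idx_max, raw_max)

  # dangling link errors, naming the spectrum
  bad_link <- link
  bad_link[3] <- "nonexistent"
  expect_error(build_index(spectra, samples, bad_link), "unknown sample_id")
})

test_that("candidate precursor range query equals a linear scan", {
  set.seed(402)
  fx <- search_fixture(seed = 402L, n_samples = 30L)
  for (rep in seq_len(200)) {
    qp <- runif(1, 50, 1100)
    for (p in list(search_params(),
                   search_params(analog_mode = TRUE),
                   search_params(parent_mass_tol = 5))) {
      tol <- if (p$analog_mode) p$max_precursor_shift else p$parent_mass_tol
      want <- which(abs(fx$index$precursor_mz - qp) <= tol)
      expect_identical(candidate_range(fx$index, qp, p), want)
    }
  }
  # worked example: tol 0.1 selects only the nearby precursor
  idx2 <- build_index(list(spectrum("r1", 312.10, c(100, 200), c(1, 1)),
                           spectrum("r2", 312.30, c(100, 200), c(1, 1))))
  expect_equal(candidate_range(idx2, 312.14, search_params()), 1L)
  expect_equal(candidate_range(idx2, 312.14, search_params(analog_mode = TRUE)), c(1L, 2L))
})

test_that("search recovers an identical reference at score 1 and enforces both gates", {
  set.seed(403)
  ref_sp <- spectrum("ref8", 400, seq(110, 390, length.out = 8), rlnorm(8, 2, 1))
  idx <- build_index(list(ref_sp))
  m <- search_spectrum(ref_sp, idx)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 1.0, tolerance = 1e-9)
  expect_equal(m$n_matched_peaks, 8L)

  # a query sharing only 5 of 8 peaks fails the matched-peak gate
  q5 <- spectrum("q5", 400, c(ref_sp$mz[1:5], 500, 600, 700), ref_sp$intensity)
  m5 <- search_spectrum(q5, idx)
  expect_equal(nrow(m5), 0)
  # ...but passes once the gate allows 5 (cosine permitting)
  m5b <- search_spectrum(q5, idx, search_params(min_matched_peaks = 5, min_cosine = 0.1))
  expect_equal(nrow(m5b), 1)
  expect_equal(m5b$n_matched_peaks, 5L)
})

test_that("spike-in search returns exactly the ground-truth samples", {
  fx <- search_fixture()
  m <- search_spectrum(fx$query, fx$index)
  expect_setequal(unique(m$sample_id), fx$truth)
  expect_true(all(m$score >= 0.65))
  expect_true(all(m$n_matched_peaks >= 6))
  # results sorted by score descending
  expect_false(is.unsorted(rev(m$score)))
})

test_that("search equals brute-force scoring of every reference plus the gates", {
  fx <- search_fixture(seed = 404L, n_samples = 20L)
  p <- search_params(min_cosine = 0.3, min_matched_peaks = 3)
  q <- preprocess_spectrum(fx$query, fx$index$prep)
  brute <- do.call(rbind, lapply(seq_along(fx$index$spectra), function(ci) {
    sr <- cosine_similarity(q, fx$index$spectra[[ci]], p$ion_tol)
    ok <- abs(fx$index$precursor_mz[ci] - q$precursor_mz) <= p$parent_mass_tol &&
      sr$score >= p$min_cosine && sr$n_matched_peaks >= p$min_matched_peaks
    if (ok) data.frame(spectrum_id = fx$index$spectrum_id[ci], score = sr$score)
  }))
  got <- search_spectrum(fx$query, fx$index, p)
  expect_setequal(got$spectrum_id, brute$spectrum_id)
  expect_equal(got$score[order(got$spectrum_id)],
               brute$score[order(brute$spectrum_id)], tolerance = 1e-12)
})

test_that("raising either gate never adds matches; identity is a subset of analog", {
  fx <- search_fixture(seed = 405L, n_samples = 40L)
  base <- search_spectrum(fx$query, fx$index,
                          search_params(min_cosine = 0.2, min_matched_peaks = 2))
  for (p in list(search_params(min_cosine = 0.5, min_matched_peaks = 2),
                 search_params(min_cosine = 0.2, min_matched_peaks = 8),
                 search_params())) {
    m <- search_spectrum(fx$query, fx$index, p)
    expect_true(all(m$spectrum_id %in% base$spectrum_id))
  }
  ident <- search_spectrum(fx$query, fx$index, search_params())
  analog <- search_spectrum(fx$query, fx$index, search_params(analog_mode = TRUE))
  expect_true(all(ident$spectrum_id %in% analog$spectrum_id))
})

test_that("library annotation reports every passing isomer entry", {
  set.seed(406)
  base_mz <- seq(120, 380, length.out = 9)
  base_int <- rlnorm(9, 2, 1)
  # three near-identical "isomer" entries plus one unrelated compound;
  # per-peak intensity noise keeps the jittered entries just below cosine 1
  lib <- list(
    spectrum("L-leucine", 132.1, base_mz, base_int),
    spectrum("D-leucine", 132.1, base_mz + 0.01, base_int * rlnorm(9, 0, 0.1)),
    spectrum("L-isoleucine", 132.1, base_mz - 0.01, base_int * rlnorm(9, 0, 0.1)),
    spectrum("unrelated", 132.1, base_mz + 30, base_int)
  )
  lib_idx <- build_index(lib)
  q <- spectrum("unknown", 132.1, base_mz, base_int)
  hits <- library_annotate(q, lib_idx)
  expect_setequal(hits$annotation, c("L-leucine", "D-leucine", "L-isoleucine"))
  expect_equal(hits$annotation[1], "L-leucine")  # exact copy ranks first
  expect_equal(hits$score[1], 1.0, tolerance = 1e-9)

  # no entry above threshold: empty result, not an error
  far <- spectrum("far", 900, seq(500, 880, length.out = 8), rlnorm(8, 2, 1))
  expect_equal(nrow(library_annotate(far, lib_idx)), 0)
})

test_that("summary statistics count distinct spectra, files, samples and terms", {
  fx <- search_fixture(seed = 407L, n_samples = 30L)
  m <- search_spectrum(fx$query, fx$index)
  st <- summary_stats(m, fx$index)
  expect_equal(st$n_matching_spectra, nrow(m))
  expect_equal(st$n_samples, length(unique(m$sample_id)))
  expect_equal(st$n_files,
               length(unique(fx$ref$samples$filename[
                 fx$ref$samples$sample_id %in% m$sample_id])))
  empty <- summary_stats(m[0, ], fx$index)
  expect_equal(unlist(empty), c(n_matching_spectra = 0, n_files = 0,
                                n_samples = 0, n_terminal_terms = 0))
})

test_that("a query empty after preprocessing warns and returns no matches", {
  fx <- search_fixture(seed = 408L, n_samples = 10L)
  near <- spectrum("near_precursor", 200, c(195, 199), c(1, 1))
  idx <- build_index(fx$ref$spectra, fx$ref$samples, fx$ref$link,
                     prep = preprocess_params(remove_precursor_region = TRUE))
  expect_warning(m <- search_spectrum(near, idx), "empty after preprocessing")
  expect_equal(nrow(m), 0)
})
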