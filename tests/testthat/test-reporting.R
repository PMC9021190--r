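report_fixture <- function(seed = 42L, n_samples = 40L) {
  cfg <- sim_config(seed = seed, n_samples = n_samples, spectra_per_sample = 2L)
  o <- make_ontology(cfg)
  spiked <- spike_in(make_reference(cfg, o), make_query(cfg), cfg)
  idx <- build_index(spiked$reference$spectra, spiked$reference$samples,
                     spiked$reference$link)
  list(ontology = o, samples = spiked$reference$samples,
       matches = search_spectrum(make_query(cfg), idx))
}

test_that("matched-files report deduplicates to one row per sample with the best score", {
  samples <- data.frame(sample_id = c("s1", "s2"),
                        filename = c("f1.mzML", "f2.mzML"),
                        terminal_term = c("a", "b"),
                        origin = c("IT", "US"), stringsAsFactors = FALSE)
  matches <- data.frame(query_id = "q", spectrum_id = c("r1", "r2", "r3"),
                        sample_id = c("s1", "s1", "s2"),
                        score = c(0.70, 0.95, 0.80),
                        n_matched_peaks = c(6L, 9L, 7L),
                        precursor_delta = 0, stringsAsFactors = FALSE)
  rep <- matched_files_report(matches, samples)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$sample_id, c("s1", "s2"))  # sorted by best score desc
  expect_equal(rep$best_score, c(0.95, 0.80))
  expect_equal(rep$best_n_matched_peaks[1], 9L)
  expect_equal(rep$origin, c("IT", "US"))

  # empty matches: header-only table with the same columns
  empty <- matched_files_report(matches[0, ], samples)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("best_score", "origin") %in% names(empty)))

  matches$sample_id[1] <- "ghost"
  expect_error(matched_files_report(matches, samples), "ghost")
})

test_that("tree export mirrors the prevalence table and the ontology shape", {
  o <- chain_ontology()
  s <- chain_samples()
  prev <- prevalence_table(c("s1", "s3"), s, o)
  tree <- tree_export(prev, o, n_samples = 4, n_matched = 2)
  expect_equal(tree$name, "plant")
  expect_equal(tree$total, 4)
  expect_equal(tree$matched, 2)
  expect_equal(tree$fraction, 0.5)
  fruit <- tree$children[[1]]
  expect_equal(fruit$name, "fruit")
  tomato <- fruit$children[[1]]
  expect_equal(tomato$total, 3)
  expect_equal(tomato$matched, 2)
  cherry <- tomato$children[[1]]
  expect_equal(cherry$fraction, 1)
  expect_length(cherry$children, 0)

  # every node's total >= max of its children's totals; zero matches zero out
  # every fraction
  tree0 <- tree_export(prevalence_table(character(0), s, o), o, 4, 0)
  walk <- function(node) {
    expect_equal(node$fraction, 0)
    for (ch in node$children) {
      expect_gte(node$total, ch$total)
      walk(ch)
    }
  }
  walk(tree0)

  expect_error(tree_export(data.frame(term = "durian", n_matched = 0,
                                      n_total = 1, fraction = 0), o, 4, 0),
               "durian")
})

test_that("zero-sample terms stay in the tree with zero counts", {
  o <- ontology(c("cherry_tomato", "tomato", "fruit", "pear"),
                c("tomato", "fruit", "plant", "fruit"))
  prev <- prevalence_table("s1", chain_samples(), o)  # nobody is a pear
  expect_false("pear" %in% prev$term)
  tree <- tree_export(prev, o, 4, 1)
  fruit <- tree$children[[1]]
  pear <- fruit$children[[which(vapply(fruit$children, `[[`, "", "name") == "pear")]]
  expect_equal(pear$total, 0)
  expect_equal(pear$fraction, 0)
})

test_that("multi-parent terms appear under each parent with identical counts", {
  d <- ontology(c("x", "x", "b", "c"), c("b", "c", "r", "r"))
  samples <- data.frame(sample_id = "only", filename = "only",
                        terminal_term = "x", stringsAsFactors = FALSE)
  prev <- prevalence_table("only", samples, d)
  tree <- tree_export(prev, d, 1, 1)
  xs <- lapply(tree$children, function(ch) ch$children[[1]])
  expect_equal(vapply(xs, `[[`, "", "name"), c("x", "x"))
  expect_equal(vapply(xs, `[[`, 0L, "total"), c(1L, 1L))
})

test_that("the report bundle is byte-deterministic and consistent with the tables", {
  fx <- report_fixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reports(fx$matches, fx$samples, fx$ontology, d1)
  write_reports(fx$matches, fx$samples, fx$ontology, d2)
  for (f in c("prevalence.tsv", "matched_files.tsv", "summary.json", "tree.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # prevalence.tsv rows equal prevalence_table output
  prev_disk <- read.table(file.path(d1, "prevalence.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  prev_mem <- prevalence_table(unique(fx$matches$sample_id), fx$samples, fx$ontology)
  expect_equal(prev_disk$term, prev_mem$term)
  expect_equal(prev_disk$n_matched, prev_mem$n_matched)
  expect_equal(prev_disk$n_total, prev_mem$n_total)
  expect_equal(prev_disk$percent, round(100 * prev_mem$fraction, 1))
  # tree.json counts agree with the prevalence table for every term
  tree <- jsonlite::read_json(file.path(d1, "tree.json"))
  check <- function(node) {
    if (node$name %in% prev_mem$term) {
      r <- prev_mem[prev_mem$term == node$name, ]
      expect_equal(node$total, r$n_total)
      expect_equal(node$matched, r$n_matched)
    } else {
      expect_equal(node$total, 0)
    }
    for (ch in node$children) check(ch)
  }
  check(tree)
  # summary statistics agree with the matches
  sm <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(sm$statistics$n_matching_spectra, nrow(fx$matches))
  expect_equal(sm$statistics$n_samples_matched, length(unique(fx$matches$sample_id)))
  expect_equal(sm$provenance$parameters$min_cosine, 0.65)
})

test_that("an empty search still writes four valid files", {
  fx <- report_fixture(seed = 7L, n_samples = 10L)
  d <- withr::local_tempdir()
  write_reports(fx$matches[0, ], fx$samples, fx$ontology, d)
  expect_equal(nrow(read.table(file.path(d, "matched_files.tsv"), header = TRUE,
                               sep = "\t")), 0)
  prev <- read.table(file.path(d, "prevalence.tsv"), header = TRUE, sep = "\t")
  expect_true(all(prev$n_matched == 0))
  tree <- jsonlite::read_json(file.path(d, "tree.json"))
  expect_equal(tree$matched, 0)
})
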