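#' Simulation configuration
#'
#' Parameters of the synthetic fixture generator, which emulates a food
#' reference repository at desk scale: an ontology tree, samples labeled at
#' its leaves, background MS/MS spectra per sample, and a spike-in of a
#' target compound into a known subset of samples so search recovery has
#' exact ground truth.
#'
#' Defaults: 200 samples with 4 spectra each under a depth-3, branching-3
#' ontology (27 leaves); 10-30 fragment peaks per spectrum uniform over
#' 100-1000 Da; log-normal raw intensities (meanlog 8, sdlog 1, arbitrary
#' units, matching the heavy-tailed abundance of real fragment ions);
#' spike-in into 10% of samples with 0.02 Da peak jitter.
#'
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @param ontology_depth,branching shape of the generated ontology tree.
#' @param n_samples number of reference samples.
#' @param spectra_per_sample background spectra per sample.
#' @param peaks_range length-2 integer range of peaks per background spectrum.
#' @param mz_range length-2 numeric range (Da) for fragment and precursor m/z.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model.
#' @param mz_jitter_sd standard deviation (Da) of spike-in peak m/z jitter.
#' @param spike_fraction fraction of samples receiving the spiked compound.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 42L,
                       ontology_depth = 3L,
                       branching = 3L,
                       n_samples = 200L,
                       spectra_per_sample = 4L,
                       peaks_range = c(10L, 30L),
                       mz_range = c(100, 1000),
                       intensity_meanlog = 8,
                       intensity_sdlog = 1,
                       mz_jitter_sd = 0.02,
                       spike_fraction = 0.1) {
  stopifnot(ontology_depth >= 1L, branching >= 1L, n_samples >= 1L,
            spectra_per_sample >= 1L, length(peaks_range) == 2L,
            peaks_range[1] >= 1L, peaks_range[2] >= peaks_range[1],
            length(mz_range) == 2L, mz_range[1] > 0, mz_range[2] > mz_range[1],
            mz_jitter_sd >= 0, spike_fraction >= 0, spike_fraction <= 1)
  structure(list(seed = as.integer(seed),
                 ontology_depth = as.integer(ontology_depth),
                 branching = as.integer(branching),
                 n_samples = as.integer(n_samples),
                 spectra_per_sample = as.integer(spectra_per_sample),
                 peaks_range = as.integer(peaks_range),
                 mz_range = as.numeric(mz_range),
                 intensity_meanlog = as.numeric(intensity_meanlog),
                 intensity_sdlog = as.numeric(intensity_sdlog),
                 mz_jitter_sd = as.numeric(mz_jitter_sd),
                 spike_fraction = as.numeric(spike_fraction)),
            class = "sim_config")
}

#' Generate a perfect ontology tree
#'
#' Depth `d` and branching `b` give `b^d` leaves and `(b^(d+1)-1)/(b-1)`
#' terms. Term names encode the path from the root (`food`, `food.2`,
#' `food.2.1`, ...), so the structure is self-describing and deterministic.
#'
#' @param cfg a [sim_config()].
#' @return a `"food_ontology"`.
#' @export
make_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  child <- character(0); parent <- character(0)
  level <- "food"
  for (d in seq_len(cfg$ontology_depth)) {
    nxt <- unlist(lapply(level, function(p) paste(p, seq_len(cfg$branching), sep = ".")),
                  use.names = FALSE)
    child <- c(child, nxt)
    parent <- c(parent, rep(level, each = cfg$branching))
    level <- nxt
  }
  if (length(child) == 0L) return(ontology(character(0), character(0), roots = "food"))
  ontology(child, parent)
}

ontology_leaves <- function(o) {
  kids <- ontology_children(o)
  sort(o$terms[lengths(kids[o$terms]) == 0L])
}

random_spectrum <- function(id, cfg) {
  n <- sample(cfg$peaks_range[1]:cfg$peaks_range[2], 1L)
  spectrum(id,
           precursor_mz = stats::runif(1, cfg$mz_range[1], cfg$mz_range[2]),
           mz = stats::runif(n, cfg$mz_range[1], cfg$mz_range[2]),
           intensity = stats::rlnorm(n, cfg$intensity_meanlog, cfg$intensity_sdlog))
}

#' Generate a synthetic reference repository
#'
#' Assigns `n_samples` samples uniformly at random to the ontology's leaf
#' terms and draws `spectra_per_sample` background spectra per sample:
#' uniform precursor and fragment m/z over `mz_range`, log-normal
#' intensities. Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param o a `"food_ontology"` (typically from [make_ontology()]).
#' @return a list with `spectra` (list of `"spectrum"`), `samples`
#'   (metadata `data.frame` with a `cooked` example metadata column) and
#'   `link` (named character vector spectrum_id -> sample_id).
#' @export
make_reference <- function(cfg, o) {
  stopifnot(inherits(cfg, "sim_config"), inherits(o, "food_ontology"))
  set.seed(cfg$seed)
  leaves <- ontology_leaves(o)
  sample_ids <- sprintf("sample_%03d", seq_len(cfg$n_samples))
  samples <- data.frame(
    sample_id = sample_ids,
    filename = paste0(sample_ids, ".mzML"),
    terminal_term = sample(leaves, cfg$n_samples, replace = TRUE),
    cooked = sample(c("raw", "cooked"), cfg$n_samples, replace = TRUE),
    stringsAsFactors = FALSE
  )
  spectra <- vector("list", cfg$n_samples * cfg$spectra_per_sample)
  link <- character(length(spectra))
  names(link) <- character(length(spectra))
  k <- 0L
  for (si in seq_len(cfg$n_samples)) {
    for (r in seq_len(cfg$spectra_per_sample)) {
      k <- k + 1L
      id <- sprintf("%s_scan%02d", sample_ids[si], r)
      spectra[[k]] <- random_spectrum(id, cfg)
      link[k] <- sample_ids[si]
      names(link)[k] <- id
    }
  }
  list(spectra = spectra, samples = samples, link = link)
}

#' Generate a target query spectrum
#'
#' A reproducible "compound" spectrum for spike-in studies: 12 fragment
#' peaks spread over `mz_range` (far fewer than the windowed top-k filter
#' would remove, so preprocessing keeps all of them), log-normal
#' intensities, fixed precursor at the midpoint of `mz_range`. Deterministic
#' under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param n_peaks number of fragment peaks.
#' @return a `"spectrum"` with id `"query_compound"`.
#' @export
make_query <- function(cfg, n_peaks = 12L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 7L)
  spectrum("query_compound",
           precursor_mz = mean(cfg$mz_range),
           mz = stats::runif(n_peaks, cfg$mz_range[1], cfg$mz_range[2]),
           intensity = stats::rlnorm(n_peaks, cfg$intensity_meanlog, cfg$intensity_sdlog))
}

rnorm_truncated <- function(n, sd, bound) {
  if (sd == 0 || bound == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

#' Spike a query compound into a subset of reference samples
#'
#' A seeded random subset of samples of size
#' `round(spike_fraction * n_samples)` each receives one copy of the query
#' spectrum with per-peak m/z jitter (normal, truncated to half the ion
#' tolerance so every spiked peak stays matchable — recovery is sharp, not
#' probabilistic) and multiplicative log-normal intensity noise. The
#' precursor receives the same truncated jitter against the parent-mass
#' tolerance. `hard_mode` removes the truncation for ROC-style studies.
#'
#' @param reference list from [make_reference()].
#' @param query a `"spectrum"` to spike.
#' @param cfg a [sim_config()].
#' @param ion_tol ion tolerance (Da) the jitter truncation protects.
#' @param parent_mass_tol parent-mass tolerance (Da) protecting the
#'   precursor jitter.
#' @param intensity_noise_sdlog sdlog of the multiplicative intensity noise.
#' @param hard_mode disable jitter truncation.
#' @return a list with the modified `reference` (spiked spectra appended and
#'   linked) and `truth` — the character vector of spiked sample ids.
#' @export
spike_in <- function(reference, query, cfg,
                     ion_tol = 0.1, parent_mass_tol = 0.1,
                     intensity_noise_sdlog = 0.1, hard_mode = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(query, "spectrum"))
  n_spike <- round(cfg$spike_fraction * cfg$n_samples)
  if (n_spike == 0L) return(list(reference = reference, truth = character(0)))
  set.seed(cfg$seed + 1L)  # own stream: make_reference consumed cfg$seed's
  truth <- sort(sample(reference$samples$sample_id, n_spike))
  for (sid in truth) {
    id <- paste0(sid, "_spike")
    mz_bound <- if (hard_mode) Inf else ion_tol / 2
    pm_bound <- if (hard_mode) Inf else parent_mass_tol / 2
    sp <- spectrum(
      id,
      precursor_mz = query$precursor_mz + rnorm_truncated(1, cfg$mz_jitter_sd, pm_bound),
      mz = query$mz + rnorm_truncated(length(query$mz), cfg$mz_jitter_sd, mz_bound),
      intensity = query$intensity * stats::rlnorm(length(query$mz), 0, intensity_noise_sdlog)
    )
    reference$spectra[[length(reference$spectra) + 1L]] <- sp
    reference$link[id] <- sid
  }
  list(reference = reference, truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `ref.mgf`, `samples.tsv`, `onto.tsv`, `query.mgf`, `link.tsv` and
#' `truth.txt` into `out_dir`: a repository, its ontology and metadata, a
#' spike-in query, and the ground-truth sample list. Byte-identical for a
#' fixed configuration.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return the ground-truth sample ids, invisibly.
#' @export
write_fixture <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- make_ontology(cfg)
  ref <- make_reference(cfg, o)
  query <- make_query(cfg)
  spiked <- spike_in(ref, query, cfg)

  write_mgf(spiked$reference$spectra, file.path(out_dir, "ref.mgf"))
  write_mgf(list(query), file.path(out_dir, "query.mgf"))
  write_tsv_stable(spiked$reference$samples, file.path(out_dir, "samples.tsv"))
  write_tsv_stable(data.frame(spectrum_id = names(spiked$reference$link),
                              sample_id = unname(spiked$reference$link),
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "link.tsv"))
  edges <- do.call(rbind, lapply(o$terms, function(t)
    if (length(o$parents[[t]]))
      data.frame(child = t, parent = o$parents[[t]], stringsAsFactors = FALSE)))
  con <- file(file.path(out_dir, "onto.tsv"), open = "wb")
  writeLines(c(paste0("#root\t", ontology_roots(o)),
               if (!is.null(edges)) paste(edges$child, edges$parent, sep = "\t")),
             con, sep = "\n")
  close(con)
  con <- file(file.path(out_dir, "truth.txt"), open = "wb")
  writeLines(spiked$truth, con, sep = "\n")
  close(con)
  invisible(spiked$truth)
}
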