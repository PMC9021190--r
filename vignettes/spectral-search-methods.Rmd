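---
title: "Methods: spectral matching, ontology aggregation, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral matching, ontology aggregation, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectront)
```

# The search model

`spectront` answers one question: given a query MS/MS spectrum, which
samples of an ontology-labeled reference repository contain a spectral
match, and how do those matches distribute over the ontology? The pipeline
has four stages — preprocessing, pairwise scoring, threshold gating, and
ontology aggregation — each with a small number of tunable parameters.

## Preprocessing

Both query and reference spectra pass through the same cleanup before any
comparison (symmetry is required for the cosine to be meaningful; applying
the filter to only one side would bias the norms):

1. *Optional* precursor-region removal: peaks within
   `precursor_exclusion_width` (default 17 Da) of the precursor m/z are
   dropped. Off by default — it is a common repository-search practice for
   suppressing residual precursor signal, but not part of the standard
   cleanup, so it is exposed as a switch rather than silently applied.
2. Windowed top-k filtering (`window_top_k` = 6, `window_half_width` =
   50 Da): a peak survives iff it is among the 6 most intense peaks within
   ±50 Da of *its own* m/z. We read the "±50 Da window (100 Da effective
   sliding window)" semantics as a per-peak centered survival test rather
   than fixed 100-Da bins: per-peak centering is what "sliding" implies,
   and it makes the operation independent of any bin origin and provably
   idempotent (a survivor's window can only lose competitors). Ranking ties
   break by lower m/z, then input order, so the filter is deterministic.
3. Square-root intensity transform: damps base-peak dominance so the cosine
   reflects shared fragments rather than a single tall ion, and makes
   searches across instruments and collision energies comparable.

A spectrum left with zero peaks is flagged rather than erroring; the search
layer skips it with a warning and an empty result (an empty result is a
valid outcome, not a failure).

## Scoring: exact maximum-weight peak matching

Fragment peaks of the query and a candidate may pair when their m/z agree
within the ion tolerance `ion_tol` (0.1 Da default, inclusive comparison,
absolute Da — no ppm mode in this version). In analog mode a pair may
instead be offset by the precursor mass difference, which lets fragments
that carry a structural modification still align (the *modified cosine*).
Each peak may be used at most once, through only one of its eligible ways.

How to resolve conflicting candidate pairs is the one place where "cosine
score" is underdetermined, and implementations differ (greedy
highest-product-first is common). We define the score as the **exact**
maximum over all one-to-one matchings of the summed intensity products,
normalized by the product of the full preprocessed intensity norms:

* it is deterministic and implementation-independent — any correct solver
  must produce the same number;
* it is testable against brute-force enumeration (the suite checks exact
  agreement on thousands of random dense pairs);
* it upper-bounds every greedy variant, so gate thresholds behave
  conservatively (a spectrum rejected here would be rejected by any greedy
  scorer too).

The solver decomposes the eligibility graph into connected components and
runs a lexicographic bitmask dynamic program per component (maximize the
weight sum; among optima minimize the total |Δm/z|; remaining ties prefer
fewer pairs then lower partner index — a physically sensible, fully
deterministic order). Components whose smaller side exceeds 20 peaks —
which requires pathologically dense spectra at 0.1 Da tolerance — fall back
to a shortest-augmenting-path assignment solver that is exact on the weight
objective (only the |Δm/z| tie-break is not guaranteed there); the two
solvers are tested against each other. Because the denominator uses the
full intensity vectors, a cosine of 1 means *all* signal is shared:
self-matches score exactly 1 and any unmatched positive-intensity peak
strictly lowers the score.

## Gating and the search

A candidate must satisfy all of: reference precursor within
`parent_mass_tol` (0.1 Da; in analog mode within `max_precursor_shift`,
100 Da), `score >= min_cosine` (0.65), and `n_matched_peaks >=
min_matched_peaks` (6). These defaults form a coherent, field-standard
identity-search setting for positive-mode Q-TOF small-molecule data; the
peak-count gate is what protects against spurious high cosines from
low-information spectra with 1–3 fragments. "Parent mass" is interpreted as
precursor m/z with an absolute Da tolerance; charge is parsed from MGF but
never used in scoring. All passing matches are returned (no top-N cap),
sorted by score, then smaller |precursor delta|, then reference id.
Raising either gate can only remove matches, and identity-mode results are
always a subset of analog-mode results at the same gates — both properties
are asserted in the test suite.

Library annotation is the same machinery pointed at an annotated spectral
library: every entry passing the gates is reported, because isomers
(leucine/isoleucine stereoisomers being the canonical example) are often
indistinguishable by MS/MS and suppressing all but the best hit would
overstate confidence.

## Ontology aggregation

The ontology is a DAG: terms may have several parents (a berry is also a
fleshy fruit), which the edge-list format and the ancestor closure support
directly. Each sample carries its terminal term plus all ancestors; for
every term, prevalence is the number of carrying samples with ≥ 1 matching
spectrum divided by the number of carrying samples. All counting is on
distinct-sample sets, so diamond-shaped parentage never double counts —
the suite checks this on random DAGs and an explicit diamond. Fractions are
stored exact; the TSV report renders one decimal, on-screen percentages
round half away from zero, and the JSON tree keeps the exact ratio. Terms
with zero samples are omitted from the prevalence table but kept in the
tree with zero counts so the rendered hierarchy stays complete; the tree
view duplicates a multi-parent term under each parent with identical
counts, because the visualization is a tree layout of the DAG.

# The synthetic testbed

`sim_config()` defines the study conditions for everything the test suite
and acceptance script measure: 200 samples, 4 background spectra each,
under a depth-3 / branching-3 ontology (27 leaves); 10–30 fragment peaks
per spectrum uniform over 100–1000 Da; log-normal intensities (meanlog 8,
sdlog 1 — heavy-tailed, like real fragment abundances in arbitrary
detector units); spike-in of a 12-peak target compound into 10% of samples
with 0.02 Da m/z jitter. These sizes keep every end-to-end check in
seconds while leaving the matching combinatorics non-trivial.

The spike-in jitter is truncated at half the ion tolerance (and the
precursor jitter at half the parent-mass tolerance), so every spiked peak
is guaranteed matchable and recovery is *sharp*: expected sensitivity is
exactly 1 with zero false positives, and root prevalence is exactly the
spike fraction. A `hard_mode` flag removes the truncation for ROC-style
experiments where partial recovery is the object of study. With uniform
background peaks over a 900 Da range, the probability that a background
spectrum both lands within the 0.1 Da precursor window and shares 6 peaks
within tolerance is negligible, which is what makes the zero-false-positive
expectation safe.

Determinism: `make_reference` seeds the RNG with `seed`; `spike_in` seeds
its own stream at `seed + 1` (the reference generation has consumed the
first stream) and `make_query` at `seed + 7`, so each artifact is
individually reproducible and the whole fixture is byte-identical across
runs and platforms.

What the generator does **not** emulate: isotope envelopes, adducts,
in-silico fragmentation chemistry, retention time, correlated noise, or
class-dependent chemistry across ontology branches. Passing tests therefore
demonstrate the *contracts* — exact scoring, correct gating, correct
aggregation, exact recovery under matchable perturbations — not
chromatographic realism or real-data sensitivity, which depend on upstream
feature extraction outside this package's scope.

# Numerical and format choices

* Tolerance comparisons are inclusive (`<=`); all m/z arithmetic is double
  precision and scores are asserted to 1e-9 against enumeration.
* MGF dialect: `PEPMASS` may carry a second (intensity) value, ignored;
  `CHARGE` tokens like `2+` parse to an integer and may be absent (charge
  is metadata only). Duplicate m/z peaks are preserved, never merged —
  merging is an upstream processing choice, and one-to-one matching handles
  duplicates correctly. The writer emits a fixed field order at 6 decimal
  places, so write-then-read is the identity on canonical spectra and
  outputs are byte-stable.
* Sample metadata is TSV by default (CSV via an option); `filename` stands
  in for `sample_id` when the latter is absent, and this version treats one
  file as one sample — a multi-file sample would count as matched if any
  of its files matches.
* Reports are pure functions of (matches, samples, ontology, parameters):
  stable sort orders and fixed numeric formatting make repeated runs
  byte-identical, and `summary.json` records the effective parameters so a
  search can be replayed exactly from its own provenance block.
* Configuration merging is strict: defaults, then file, then command-line
  flags, with unknown keys rejected by name — silent typos in threshold
  names would otherwise change scientific results invisibly.

# Known limitations

* No ppm tolerance mode; at very high m/z an absolute 0.1 Da window is
  generous relative to instrument accuracy.
* The exact matching is exponential in the size of a single eligibility
  component in the worst case; the dense-component fallback keeps it
  polynomial but drops the tie-break guarantee (scores are unaffected).
* Analog mode reports pairwise neighbors only; building a molecular
  network from the pairwise scores is out of scope.
* Negative ion mode data is accepted (the engine is polarity-agnostic) but
  mixing polarities in one repository will produce chemically meaningless
  matches; curate the reference accordingly.
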