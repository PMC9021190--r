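Package: spectront
Title: Repository-Scale MS/MS Spectral Search with Food Ontology Prevalence Reporting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A search engine for tandem mass spectrometry (MS/MS) spectra
    against a reference repository of spectra tied to ontology-labeled
    samples. Queries are matched by cosine similarity over an exact
    one-to-one fragment-peak assignment within an ion tolerance, with an
    analog (modified-cosine) mode that additionally pairs peaks offset by
    the precursor mass difference. Spectra are preprocessed by windowed
    top-k peak filtering and a square-root intensity transform. Matched
    samples are aggregated over a food ontology (a DAG with ancestor
    inheritance) into per-term prevalence tables, matched-file metadata
    reports, and a hierarchical tree export for pie-chart visualization.
    Includes MGF input/output, a synthetic fixture generator with spike-in
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
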