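Package: recipefs
Title: Declarative Validation, Curation and Aggregation of File Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compiles human-readable TOML 'recipes' describing how a
    directory tree of heterogeneous research data should look into
    executable templates. A template traverses the tree top-down or
    bottom-up, dispatches depth-scoped condition-action-counteraction
    rules to every file and directory, and feeds a filter-map-reduce
    aggregation engine (counts, byte totals, sorted file lists, CSV
    concatenation, image stacking, maximum-intensity projection,
    per-slice descriptive statistics and pixelwise colocalization
    metrics). Execution can be sharded across workers with
    worker-private journals and accumulators that are merged exactly
    once, so results are independent of scheduling. Includes a seeded
    synthetic fixture generator with ground-truth manifests, a gallery
    of example recipes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RcppTOML,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
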