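---
title: "Recipes over file trees: the validation and aggregation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recipes over file trees: the validation and aggregation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipefs)
```

## The problem and the model

A dataset's layout — where files live, how they are named, what their
contents must look like — is usually an informal convention. `recipefs`
models that convention as an explicit, machine-enforceable object: a
TOML *recipe* compiled into an executable *template*. The template
traverses a directory tree, applies depth-scoped
condition–action–counteraction rules to every node, and feeds a
filter–map–reduce aggregation layer. The recipe is simultaneously
documentation (a reviewer can read it) and executable specification (a
machine can enforce it at terabyte scale), which is the core idea the
package is built around.

Three design commitments follow from that idea:

* **Fail closed.** Unknown TOML keys are hard errors, every symbol must
  resolve before anything executes, and validation reports *all*
  problems, not the first. A contract with silently ignored clauses is
  no contract. `validate_document()` returns diagnostics (with
  nearest-name suggestions for typos); `compile_template()` refuses any
  document that has one.
* **Determinism.** Sibling order is bytewise (C locale), not filesystem
  order; "left to right" in a rule means recipe order; stacking keys use
  natural sort. Identical recipe + identical tree gives identical
  journals, aggregates and sink bytes on any platform and any worker
  count.
* **Lossless by default.** `remove` quarantines into a mirrored sibling
  directory (`<root>.quarantine`) unless destruction is enabled in both
  the recipe (`destructive_allowed`) and the run options
  (`--allow-destructive`); copy and move never overwrite (collision
  suffixes `_1`, `_2`, … before the extension); every mutation is
  journaled; `--dry-run` journals effects without applying them.

## The recipe dialect

The dialect is documented in full at the top of `R/recipe.R`; the
choices worth explaining:

* **All literal arguments are TOML strings**, coerced against each
  symbol's declared signature at validation time
  (`["size_at_least", "1024"]`). A single homogeneous-array shape for
  every call keeps the grammar trivial to read and diff, and arguments
  are still typed — a non-numeric string where an integer is declared is
  a validation diagnostic, before anything runs.
* **Calls are wrapped arrays, names are bare strings.**
  `conditions = [["has_extension", ".csv"], "is_file"]`. Negation is the
  prefix token `not `; composites (`all_of`, `any_of`, `not`) nest
  without limit.
* **Aliases** (`[global.shared_definitions]`) are zero-argument names
  expanded by substitution at compile time, so the execution engine
  never sees one; cycles are a validation diagnostic.
* **Scope blocks**: `[template.level_k]` applies at depth `k` (the input
  root's children are depth 1; the root itself is not a node),
  `[template.any]` elsewhere. A level rule *replaces* the `any` rule on
  its level rather than both firing: single-rule-per-node semantics are
  predictable, and "both" is expressible inside one rule with
  composites. At most one rule block per scope (TOML table uniqueness
  enforces this for free).
* **Default `condition_mode = "all"`**: validation contracts are
  naturally conjunctive; `"any"` is available explicitly.
* **`act_on_success = false`** swaps the action and counteraction
  sequences at compile time — a recipe that *reacts to violations* reads
  the same as one that reacts to conformity.
* Regex is opt-in (`regex_enabled`); the default `name_matches` is a
  fixed substring, which is what most naming contracts need and cannot
  be mis-escaped. Extension matching is case-insensitive
  (conventions), name matching is case-sensitive (contracts). Regex
  patterns are best written as TOML literal strings (`'^z[0-9]+\.tif$'`)
  so backslashes survive.

Paths: `input_root` resolves against the recipe file's directory (or is
overridden at run time); relative *output* destinations — action targets
and sinks — resolve against the parent of the resolved input root. The
recipes shipped in the installed package are read-only, so outputs must
land in the workspace around the data being curated, and this rule puts
them there without configuration.

## Execution semantics

The walker snapshots the tree once, before any rule fires. Files created
or moved during a run are therefore never visited in the same run (no
self-feeding loops), and the serial and sharded execution paths see
provably identical node sets. A node that vanishes between snapshot and
dispatch (e.g. its parent directory was quarantined) journals a warning
and counts as visited; conditions are containment-wrapped the same way,
so one unreadable file degrades one predicate to `FALSE` with a
journaled warning instead of killing a long run. User-registered
conditions get the same wrapper.

A failing predicate increments `failure_count` only when the rule
declares **no** counteractions: counteractions *are* the author's
failure handling, so a handled failure is not also counted.

Aggregators observe every visited node — filtered only by their own
condition — *before* the node's rule runs, so a rule that renames or
removes a file cannot hide it from aggregation.

### The sharded scheduler

`execute_parallel()` implements the lock-free contract structurally:
nodes are partitioned round-robin in walk order across `workers` shards;
each worker owns a private journal, private aggregator accumulators and
private counters; nothing mutable is shared during the run; shards merge
exactly once at completion. R executes single-threaded in-process, so
cross-worker interleaving is simulated by a seeded scheduler that
repeatedly picks a random non-empty worker queue — a faithful model of
an arbitrary pool schedule, with per-worker FIFO order preserved. The
`schedule_seed` argument perturbs the interleaving; the test suite
varies it (together with worker counts 1–8) and asserts byte-identical
finalized aggregates, journals and sink files, which is the testable
form of the lock-free claim. Reducer merges are commutative and
associative; order-sensitive reducers (lists, tables, stacks) keep their
elements keyed and canonicalize at finalization; journals sort by
`(walk_index, action_seq)`.

Early exit (`quit`, `quit_on_fail`) is sticky and exact in serial runs:
no node after the quitting one is dispatched. Under parallelism the
guarantee is deliberately weaker: once the signal is observed no further
node is *scheduled*, but nodes already in flight may complete — a hard
prefix guarantee would require global synchronisation, which is exactly
what the shard design avoids. Quit-bearing recipes are therefore tested
against this weaker contract rather than byte-identity.

Collision suffixes (`_1`, `_2`, …) are assigned in processing order, so
a run in which two *differently named* sources collide at one
destination is schedule-dependent by nature; `flatten_to` avoids the
problem entirely by deriving its output name from the full relative path
(`a/b/c.tif` → `a_b_c.tif`), which cannot collide.

## The aggregation layer

Each aggregator declares `filter` (a condition; default `is_file`),
`mapper` (default chosen by reducer: `node_path`, `file_size`,
`load_image` or `load_table`), `reducer`, an optional `sort_key` regex
whose first capture group over the file name becomes the element's key
(default: the relative path), and a `sink`.

Numerical and imaging choices:

* Images are 8-bit grayscale, 0–255, uncompressed TIFF (2D or multipage
  3D) and PNG (2D); volumes carry the slice axis first, so
  `vol[i, , ]` is slice `i`. Uncompressed encoders keep fixture bytes
  reproducible.
* `describe_images` uses the **population** standard deviation
  (`sqrt(mean((x - mean(x))^2))`) — defined for a single-pixel slice —
  and quartiles from `stats::quantile` (default type 7). Objects are
  8-connected components of the nonzero mask *within* each slice
  (two-pass union-find; no linking across slices, since the statistics
  are explicitly per-slice).
* `coloc` reports Pearson r, Spearman rho with midranks, Manders M1/M2
  and the jointly-above-threshold overlap fraction. Thresholds default
  to 0 with per-aggregator overrides (`threshold_a`, `threshold_b`);
  there is no automatic (Costes-style) threshold estimation —
  deterministic defaults keep results exactly reproducible. Both images
  constant ⇒ correlations are reported as `NA` with a journaled note;
  Manders stays defined while its denominator is positive. The reducer
  expects exactly two images after filtering and pairs them in natural
  key order.
* `concat_tables` requires *identical* headers (same names, same order)
  and adds a `source` provenance column — silent schema drift is
  precisely the failure mode the tool exists to catch.
* `max_project` folds with elementwise `pmax` (projecting 3D
  contributions first), so its shard merge is commutative and
  associative by construction; the neutral element is the empty
  accumulator and projecting zero images is an error rather than a
  fabricated zero image.
* Sinks write atomically (temp file + rename): an interrupted run leaves
  no partial artifact. `text_list` output is sorted with `\n` endings;
  `csv_table` is RFC-4180 CSV with a header; a 4D series sent to an
  `image_file` sink is written as TIFF pages in `(t, z)` order.

## The fixture generator

`generate_tree()` exists so that every other module is testable without
external data: it emits a seeded tree *and* the manifest that describes
it exactly (paths, kinds, sizes, image shapes and patterns, CSV headers,
planted defects). The manifest — not the tree — is the oracle the tests
compare against. Randomness comes from a self-contained linear
congruential generator, so fixtures neither disturb nor depend on R's
global RNG, and identical spec + seed reproduce identical bytes.

`naming = "messy"` plants a fixed, documented defect corpus at the root
— one file per family: a space in the name, an uppercase name, a double
extension, a hidden file, a non-ASCII name, a 2D TIFF where volumes are
expected, and a CSV missing a required column. Each defective file
violates exactly one family, so a validation recipe's `failure_count`
equals a simple manifest count. Blob images place rectangular blobs
separated by a 1-pixel moat, so the planted count *is* the 8-connected
object count, with positions and sizes recorded for the statistics
oracle; `ramp` images are strictly increasing, giving closed-form
correlation signs.

What the generator does not emulate: real microscopy intensity
statistics, deep/wide production trees, permission errors, symlinks, or
concurrent writers. Passing tests demonstrate the engine's contracts
(dispatch, ordering, aggregation algebra, journaling, safety), not
robustness to every pathology of a live filesystem.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use: 42 gallery recipes, each
against its seeded scenario; a ~1,100-node tree for the counting
scenario; worker counts {1, 2, 4, 8} with perturbed schedules over five
fixture seeds for the byte-identity sweep; 50 seeded trees for
early-exit soundness; 1,000 random composites (depth ≤ 4) against a
truth-table oracle; 100 seeded blob slices against generator bookkeeping
and an independent queue-based flood fill. These sizes exercise every
code path many times over while keeping a full run comfortable on one
CPU.

## Limitations

* Content support is deliberately narrow: grayscale TIFF/PNG images,
  CSV tables, everything else opaque. `register_user_symbol()` is the
  seam for new datatypes; HDF5/JSON/SQLite readers and an SQLite sink
  are out of scope.
* Parallelism is a deterministic sharded scheduler in one R process;
  the shard architecture would carry over to forked workers unchanged,
  but the package does not fork.
* Colocalization offers fixed thresholds only, and exactly one image
  pair per aggregator.
* The TOML reader targets TOML 0.5 via `RcppTOML`; heterogeneous arrays
  are not part of the dialect (all literals are strings by design).
* Remote transports, messaging integrations and container packaging are
  out of scope.
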