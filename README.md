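# recipefs

Declarative validation, curation and aggregation of research data trees.

Interdisciplinary imaging projects accumulate directory trees mixing TIFF
stacks, PNGs, CSV measurement tables and plain files, organised by
conventions that live in people's heads. When a pipeline expects
`plate/<n>/z<k>.tif` and receives `Plate 1/Z 10.TIF`, the cost surfaces
days later as a crashed cluster job or, worse, silently wrong results.
`recipefs` lets data producers and consumers write that expectation down
as a **recipe** — a short TOML document — and turns it into an executable
**template** that validates, repairs and summarises an arbitrary tree at
scale. The recipe is the contract: humans review it, machines enforce it.

A recipe declares:

* a `[global]` section — input root, traversal order (top-down or
  bottom-up), parallelism, reusable condition aliases, and named
  **aggregators**;
* rule blocks `[template.any]` / `[template.level_k]` — each a
  *condition–action–counteraction* triplet dispatched to every node at
  the matching depth (the root's children are depth 1; a level rule beats
  the `any` rule). Conditions combine with `all_of` / `any_of` / `not`
  to arbitrary depth and are evaluated left to right with short-circuit;
  actions run in recipe order. `quit` / `quit_on_fail` stop the whole
  traversal early.

Aggregators are filter–map–reduce pipelines that observe every visited
node independently of rule outcomes: counts, byte totals, sorted batch
lists, CSV concatenation with schema enforcement and provenance, stacking
of keyed 2D slices into 3D volumes (or 3D into 4D series) ordered by
natural sort (`z2` before `z10`), maximum-intensity projection
`P(y,x) = max_z V(z,y,x)`, per-slice descriptive statistics with
8-connected object metrics, and pixelwise colocalization:

* Pearson `r = Σ(aᵢ−ā)(bᵢ−b̄) / √(Σ(aᵢ−ā)² Σ(bᵢ−b̄)²)`
* Spearman `ρ` (rank Pearson, midranks for ties)
* Manders `M1 = Σᵢ aᵢ·1[bᵢ>τ_b] / Σᵢ aᵢ`, `M2` symmetric, plus the
  jointly-above-threshold overlap fraction.

Execution is sharded: every worker owns a private journal and private
aggregator accumulators, nothing mutable is shared during the run, and
shards are merged exactly once at completion. Because merges are
commutative/associative and order-sensitive outputs are canonicalized by
sort key, finalized results are bit-identical for any worker count and
any schedule.

## A worked example

The minimal counting recipe (also shipped as
`inst/recipes/gallery/03_count_and_sizes.toml`):

```toml
[global]
input_root = "data"
parallel = true

[[global.aggregators]]
name = "file_count"
reducer = "count"

[[global.aggregators]]
name = "total_bytes"
reducer = "sum_size"
```

Run it against a synthetic tree with a known manifest:

```r
library(recipefs)
root <- file.path(tempdir(), "demo")
manifest <- generate_tree(tree_spec(seed = 3), root)
code <- dc_run(system.file("recipes", "gallery", "03_count_and_sizes.toml",
                           package = "recipefs"),
               input_override = root)
```

which prints

```
status: ok
visited: 10
failures: 0
file_count: 8
total_bytes: 2213
```

`visited` counts every file and directory below the root; `file_count`
and `total_bytes` are the two aggregates, and they equal the manifest's
own sums (`sum(manifest$kind == "file")`, `sum(manifest$size)`), which is
exactly what the test suite asserts. The exit code is `0` (clean run),
`1` (validation failures), `2` (recipe error, diagnostics with line
numbers on stderr), `3` (runtime error) or `4` (aborted by
`quit_on_fail`).

The same engine drives a command line:

```sh
inst/cli/recipefs run recipe.toml --input /data --workers 8 --dry-run
inst/cli/recipefs validate-recipe recipe.toml
inst/cli/recipefs list-symbols
inst/cli/recipefs generate-fixture --out /tmp/tree --seed 7 --naming messy
```

`--dry-run` journals every intended effect without touching a byte;
`remove` quarantines to a mirrored sibling directory unless destruction
is enabled in **both** the recipe and the command line.

The gallery under `inst/recipes/gallery/` holds 42 annotated recipes —
counting, validation contracts, renaming, quarantine, early exit, image
stacking/projection/statistics, colocalization, table concatenation —
each executed end-to-end by the test suite against seeded fixtures with
ground-truth manifests.

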