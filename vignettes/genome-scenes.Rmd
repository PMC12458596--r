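---
title: "From 3D genome structures to resolved scenes: the chromoscene methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 3D genome structures to resolved scenes: the chromoscene methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscene)
```

## The data model

A 3D genome structure — whether inferred from single-cell Hi-C or produced
by a polymer simulation — is at heart an ordered list of spatial points,
sometimes annotated with genomic coordinates. chromoscene models it as a
columnar *bin table*: one row per bin with a chromosome name, a genomic
interval, a spatial position, and any number of named data columns. The
invariants are deliberately few and checkable: intervals are non-degenerate
(`end > start`), per-chromosome rows are sorted and non-overlapping,
coordinates are finite, and data-column names avoid the six reserved ones.
`validate_structure()` reports violations as data instead of throwing, so a
pipeline can triage malformed inputs.

Two representational choices ripple through everything else:

* **All genomic coordinates are 0-based half-open**, the BED convention.
  Every reader converts on ingest (GTF's 1-based inclusive intervals become
  `[start - 1, end)`), so interval logic is written exactly once. Half-open
  semantics also give an unambiguous meaning to "touching": a feature ending
  at 100 and a bin starting at 100 share no base and never select or
  aggregate together.
* **Structures without genomic coordinates still work.** A bare point cloud
  gets synthetic 1-bp bins on the pseudo-chromosome `"chr?"`, which makes
  every downstream operation total. The bin index then doubles as a
  coordinate, and the inferred resolution of such a structure is simply 1.

The *resolution* of a structure is the modal bin width, with ties broken
toward the smallest width. The tie-break is a design choice: smaller is the
conservative direction for aggregation (features are never smeared over a
wider bin than the data supports), and determinism matters more than the
particular convention.

Chromosome names are opaque strings. `"chr1"` and `"1"` are different
chromosomes, and haplotype-tagged names such as `"1(pat)"` from diploid
models pass through untouched; `rename_chroms()` is the explicit bridge
between conventions. Silent aliasing was rejected because a selection that
silently matches nothing (or the wrong thing) is the most expensive kind of
bug in comparative work across structure ensembles.

### File formats

`.3dg` files store only bin start positions, so bin widths must be
inferred: per chromosome, the minimum positive gap between consecutive
positions. The minimum (not the mode) is used because models routinely omit
unmappable bins — gaps are inflated, never deflated, so the smallest gap is
the resolution. An explicit `resolution_hint` overrides inference.
Arrow IPC (Feather) is the lossless interchange format; TSV output prints
12 significant digits, giving read-back agreement within 1e-9 relative.
GFF3 is deliberately unsupported rather than approximately parsed; GTF
covers the annotation workflow.

## Selection

Three selection operators return *bin masks* — logical vectors tagged with
the structure identity and a provenance string recording the generating
query. Masks compose with `&`, `|`, `!` and `combine_masks(..., "and-not")`,
and `apply_mask()` materializes the surviving bins.

* **Genomic ranges.** A bin is selected when its interval intersects any
  query interval (half-open, exact chromosome match; >= 1 bp by default, an
  optional `min_overlap` fraction is available). Query strings follow
  `"chrom[:start-end]"` with comma-separated multiples, digit-grouping
  commas, and k/M/G suffixes. One parsing subtlety: a comma followed by
  exactly three digits and a non-digit is treated as digit grouping, all
  other commas separate queries — so a bare 3-digit chromosome name
  immediately after a grouped number cannot be written in one string; pass
  a data frame for such cases. A query chromosome absent from the structure
  warns rather than errors, because replaying one query across an ensemble
  of structures with differing chromosome sets is a supported workflow.
* **Spheres.** Closed ball (`distance <= radius`). A genomic locus used as
  the center resolves to the stored point of the containing bin, not an
  interpolated position — no interpolation model is defined for chromatin
  fibers, and inventing one inside a selection primitive would be invisible
  magic.
* **Cutting planes.** With unit normal n̂ and offset c, the signed value
  `v = n̂·p − c` splits bins into `v >= 0` (positive side) and `v < 0`.
  Ties go to the positive side so the two sides always partition the
  structure exactly. A slab of finite thickness is expressed by composing
  two planes with `&` — the half-space is the primitive, the slab is not.

Interval overlap runs on GenomicRanges/IRanges; the test suite keeps naive
double-loop oracles alongside, and all three operators are checked against
them on random structures up to 1000 bins.

## The encoding grammar

A *view config* declares how bins become graphics: a mark (`sphere` or
`box`), a color channel, a scale (radius) channel, and an optional link
channel. Channels are either constants or *field encodings* that map a data
column (or the pseudo-fields `coordinate` — per-chromosome bin index — and
`chrom`) through a scale:

* Continuous color: `t = clamp((v − lo)/(hi − lo), 0, 1)`, then
  piecewise-linear interpolation between equally spaced colormap stops in
  plain RGB, rounded half-up per channel, alpha 255. Plain RGB (rather than
  a perceptual space) keeps the mapping bit-reproducible and makes the
  endpoint identities exact: `v = lo` yields the first stop, `v = hi` the
  last, for every colormap. Out-of-domain values clamp instead of erroring —
  the right default for exploratory use. An all-equal column with no
  explicit domain degenerates; it maps to the first stop with a warning.
* Continuous scale: `radius = rmin + t·(rmax − rmin)` with `rmin > 0`
  enforced. Because `t` is clamped to `[0,1]`, an encoded scale can only
  shrink marks relative to drawing everything at `rmax` — which is why
  scale encoding doubles as an occlusion-reduction device.
* Categorical color: categories ordered by first appearance, palette cycled
  modularly.

Built-in scales: `viridis-8` (8 stops), `greys-2`, and a 12-color
categorical palette; stop values are embedded constants. When no scale
channel is given, marks take `default_radius()`: half the median distance
between genomically consecutive bins, so marks roughly touch along the
fiber. Boxes use edge = 2 × radius, matching the sphere's diameter — the
format prescribes no cube convention, so this is our documented choice.

`resolve()` materializes everything into a *resolved scene* — per-bin
position, mark, radius, rgba — plus link segments between bins that are
genomically adjacent (`end[i] == start[i+1]`) on one chromosome. Gaps break
chains; links never span chromosomes. Resolution is deterministic:
identical inputs give byte-identical scenes. View configs serialize to
JSON with a strict schema (unknown keys are rejected, catching typos like
`colour`).

A worked consequence of the endpoint identities: encoding `coordinate`
with a two-stop scale paints each chromosome's first and last bin exactly
the two endpoint colors — chromosome ends (telomeres) become visually
identifiable at a glance when bins per chromosome are equal, since the
domain endpoints are then attained on every chromosome.

## Annotation aggregation

`bin_features()` turns interval annotations into encodable columns:
feature `count` per bin, `coverage` (union of bin-clipped intersections
divided by bin width, always in `[0,1]`), or `score_mean`. Both count and
coverage are provided because "gene density" can reasonably mean either
genes per bin or covered base pairs. Strand is ignored; density is a
strand-symmetric quantity. Empty bins get 0 rather than NA so the column
feeds straight into an encoding without a missing-data channel
(`score_mean` additionally records which bins were empty in an attribute).
`radial_position()` adds the distance of each bin to the structure
centroid — the statistic needed to state observations like "gene-rich
regions concentrate toward the interior".

## Export

`to_mesh()` tessellates marks: icospheres (20·4^s faces at subdivision s;
icospheres, not UV-spheres, for near-uniform triangles), 12-triangle
cuboids, and 8-sided open tubes for links (radius 0.25 × default radius,
colored per end by the linked marks). Subdivision is capped at 5 as a
mesh-size guard. Ascii PLY with per-vertex uchar RGBA is the primary
output — diffable, and round-tripped by the package's own reader in tests;
OBJ is provided without colors (a limitation of that format).
`render_preview()` draws an orthographic projection with filled discs,
far-to-near (painter's algorithm), to a deterministic PNG. It is a static
sanity view, not a renderer: no lighting, no perspective, no occlusion
beyond paint order.

## The synthetic generator

`simulate_structure()` grows each chromosome as a random walk with fixed
step length ℓ, started uniformly inside a confining sphere of radius R;
steps leaving the sphere are rejected and redrawn (bounded at 10^4 retries).
This emulates the two features of real chromatin models that the rest of
the package cares about — an ordered fiber with a characteristic
consecutive-bin distance, confined in a nucleus-like volume — and nothing
else: there is no self-avoidance, no territory formation, no contact-map
realism. Passing tests on these fixtures therefore demonstrates the
correctness of the data handling, selection geometry, encodings and
exports, not biological fidelity of any particular structure.

`simulate_features()` plants a controllable spatial signal: per bin, a
Poisson-distributed feature count with mean `2·exp(−γ·d/R)`, where `d` is
the bin's radial position. γ = 0 is the spatially uniform null; larger γ
concentrates features toward the interior, mimicking the gene-density
gradient seen in real genome structures. The defaults (4 chromosomes,
250 bins, 100 kb resolution, ℓ = 1, R = 10, seed 42) describe a desk-scale
single-cell-like model; committed fixture files use seed 42. The feature
stream derives from `seed + 1` so structure and annotation are
independently reproducible.

Test problem sizes are chosen for statistical power, not convenience: the
sign-recovery property (Spearman correlation between aggregated count and
radial position is negative when γ = 5) holds at 2 × 50 bins and is checked
over 100 seeded replicates, while the sharper inner-vs-outer-decile
depletion needs the Poisson sums of a 4 × 150-bin structure to be reliably
ordered and is checked there.

## Numerical and degenerate-input choices

* Resolution ties → smallest width; plane ties → positive side; sphere
  boundary → included. All three make partitions and repeated runs
  deterministic.
* Color interpolation rounds half-up to integers in 0..255.
* A 0-bin structure is representable (e.g. an all-false mask) and flagged
  by validation rather than forbidden; downstream writers handle it (a
  0-element PLY is valid).
* Degenerate encoding domains warn and collapse to the scale origin (first
  stop / `rmin`) instead of erroring.
* TSV numeric output: `.` decimal, 12 significant digits, no scientific
  notation below 1e6, `\n` line endings — so diffs of written structures
  are meaningful.

## Known limitations

* No interactive or GPU rendering; the PNG preview is intentionally basic.
* No spatial index — selections are linear scans, fine at desk scale
  (10^3–10^5 bins), not engineered for whole-genome ensembles at 1 kb.
* PDB-stored genome models and GFF3 annotations are unsupported, stated
  rather than approximated.
* Structures in a scene are treated as independent coordinate frames; no
  alignment or registration is attempted.
* Perceptually uniform color interpolation is deferred; the grammar
  accepts user-supplied stop matrices if a perceptual ramp is needed.
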