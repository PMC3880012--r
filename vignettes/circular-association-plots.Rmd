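---
title: "Methods: circular layout, label resolution, filtering and bundling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular layout, label resolution, filtering and bundling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcomics)
```

This vignette is the package's own account of the methods it implements:
the geometric model behind the circular view, the label-resolution and
filtering semantics, the numerical and design choices made where the
problem left them open, and what the synthetic fixtures do and do not
establish about real data.

## The circular model

A genome with chromosomes of lengths $L_1,\dots,L_n$ (base pairs) is mapped
onto a circle. Each chromosome occupies an arc whose angular span is
proportional to its length after reserving a fixed gap $g$ between
consecutive arcs:

$$\mathrm{span}_i \;=\; \bigl(360^\circ - n\,g\bigr)\,\frac{L_i}{\sum_j L_j}.$$

The first chromosome starts at 12 o'clock (90° in mathematical convention)
and layout proceeds clockwise — the common convention in circular genome
plots. The gap is fixed per chromosome rather than proportional so that
small chromosomes (yeast chromosome I, fly chromosome 4) remain visibly
separated instead of vanishing into their neighbours' gaps. The default
$g = 1^\circ$ keeps 96% of the circumference usable for a 24-chromosome
genome; `build_arcmap()` rejects configurations where $n\,g \ge 360^\circ$.

A locus `chr:start:end` (1-based, inclusive; `start = end` is one base) is
anchored at its midpoint $\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$.
A single anchor angle per node is required to draw a chord, and the span
midpoint is the natural unbiased choice. Position $p$ maps to fraction
$(p - \tfrac12)/L$ of its arc, so base 1 sits at the arc start and base $L$
at the arc end, each within half a base of arc — the half-open pixel-center
convention that avoids double-covering arc boundaries at chromosome ends.
Within a chromosome the mapping is strictly increasing and never emits an
angle inside a gap.

Associations are drawn as quadratic Bézier chords between their two
anchors at `edge_radius`. The control point sits at $0.2 \times$
`edge_radius` from the circle centre along the bisecting direction of the
two anchors (the centre itself when the anchors are diametrically
opposed). This pulls long-range chords through the middle of the disc
while keeping short-range chords close to the perimeter, which is how the
eye distinguishes inter- from intra-chromosomal structure.

## Label resolution

Node labels mix three grammars, tried in order:

1. positional `chr:start:end`;
2. exact gene-index lookup (after whitespace trimming);
3. case-insensitive symbol lookup.

Gene symbols fold case because symbol capitalisation conventions differ
across organisms (human `TP53`, mouse `Trp53`); ENSEMBL accessions and
numeric ENTREZ ids are matched verbatim because identifier namespaces are
case-defined and a folded match could silently cross namespaces. A label
that matches no rule is *unmapped*: resolution never raises on a single
label, it reports. Only when no edge at all has two resolvable endpoints
does `resolve_set()` fail hard, naming the most frequent unmapped labels —
at that point there is nothing to plot and silence would hide a systematic
input problem (wrong organism, wrong index).

Phenotype endpoints are declared with the `^PHENO` source-type suffix. They
are unmapped *by design* — a disease state has no locus — and are drawn as
tick glyphs outside the reference ring at their mapped partner's angle, so
phenotype associations stay visible without fabricating coordinates. The
`^GENO`/`^GEXP`/`^PROT` suffixes only affect color encoding. The `^`
separator was chosen because it cannot collide with `:` in positional
labels or `|` in composite prefixes.

Composite references concatenate member genomes on one circle with
`prefix.chrom` renaming. The `prefix|label` form restricts lookup to one
member; an un-prefixed label resolves against members in order with the
first hit winning, and any label found in several members is flagged in
the mapping report rather than guessed about silently. For un-prefixed
positional labels the first member whose chromosome actually contains the
interval wins, which makes mixed-coordinate ortholog files usable without
prefixes whenever the coordinates themselves disambiguate.

Built-in references ship as static chromosome-length tables for ten
organisms at fixed builds; the human reference carries a coarse arm-level
band track (p / centromere / q per chromosome, synthesised from standard
centromere midpoints — see the file name `human_cytoband_armlevel.tsv`)
rather than the full 862-band table, which is why the built-in outer ring
shows arms, not sub-bands. Gene indexes are deliberately pluggable: tables
of genome-scale gene annotation belong to the user's annotation source,
not to a plotting package, and `attach_gene_index()` accepts any
`label, chrom, start, end` TSV.

## Input formats

Extensions map delimiters totally: `.txt` space, `.tsv` tab, `.csv` comma,
`.sif` SIF. A trailing third column is a weight when it parses as a real
number and a color otherwise — numeric parsing is unambiguous, so numbers
win. In extended SIF the fourth field of a three-node line can also be a
second target, so there the color grammar must be closed: only `#rgb` /
`#rrggbb` hex and named colors count as colors, anything else is a target.
Multi-target SIF lines cannot carry weights; the alternative (guessing
whether a trailing number is a weight or a node called `0.5`) is
unresolvable, so the package forbids it and documents the restriction.
Comments (`#`) and blank lines are skipped in all dialects; both `\n` and
`\r\n` are accepted.

Writers are exact inverses: weights are rendered with enough decimal
digits to reparse to the identical double (15 significant digits,
escalating to 17 when needed), so `parse(write(x))` preserves the edge
multiset. This is what makes "export the filtered set, share it, re-import
it" a lossless workflow, and it is property-tested over 1000 random
records per dialect.

## Filtering, the render limit, and bundling

Weight filters apply one of `<, <=, >, >=, ==, abs>=, abs<=` to the edge
weight; the absolute-value forms exist because correlation networks are
signed and "strong either way" is the common query. Edges without a weight
are dropped by weight filters — a weight filter asserts "the weight
satisfies P", which an absent weight cannot. Label filters keep edges
touching (mode `any`) or joining (mode `both`) a label set, normalised
exactly as in resolution; `any` is the default because pathway-membership
queries usually ask for a gene's neighbourhood, not its induced subgraph.
An empty label set is an error, not a no-op, to distinguish "filter by
nothing" from "no filter". Filters preserve edge order, recompute the
mapping report, and commute with each other (property-tested).

The render limit (default 2000 curves) is strictly a view-layer
truncation: filters always see the complete association set, and only the
drawable mapped–mapped curve list is cut to the first `n` in input order
at render time. The test suite includes a crafted ten-edge set on which
filter-then-limit and limit-then-filter demonstrably differ, pinning the
implemented order.

Bundling partitions each chromosome into consecutive fixed windows of
`window_bp` starting at base 1; an edge's key is the unordered pair of its
endpoints' (chromosome, window) cells, so `A→B` merges with `B→A` —
association edges are undirected here. A fixed grid (rather than a sliding
or agglomerative window) was chosen because it is deterministic and
transitive: "within one window" is then a well-defined equivalence
relation, and an independent brute-force grouping can verify the partition
exactly. An optional threshold exempts edges with $|w|$ at or above it
from bundling (absolute value, consistent with the `abs>=` filter idiom),
so headline edges stay individually visible. Bundles render as single
curves with stroke width $\log_2(\mathrm{count}+1)$ — a sub-linear law so
hundred-edge bundles do not blot out the disc; the logarithmic base is a
documented aesthetic choice, not a fitted constant.

## Rendering choices

Edge stroke precedence is explicit color, then the weight colormap, then
neutral grey. The weight colormap is diverging pink–grey–green (negative →
positive), with its domain symmetric at $[-\max|w|, +\max|w|]$ over the
rendered set so that zero always maps to grey and hue encodes sign even in
skewed sets. Annotation rings stack inward from the reference ring in
upload order (outermost = first uploaded); bars scale to
$|v|/\max|v|$ of the band thickness, histograms grow from a mid-band
baseline (positive outward), heatmap cells span the target's arc interval.
Stain colors use the standard Giemsa grey ramp with centromeres in red.
The SVG embeds a metadata element with the package version and the filter
provenance chain, and deliberately contains no timestamps or generated
ids, so re-rendering identical inputs yields byte-identical files — the
property that makes plots diffable and cache-friendly. Coordinates are
written with four decimals, which at the default 1000-unit canvas is far
below visual resolution while keeping output text stable.

Degenerate inputs are handled explicitly: a set whose edges are all
filtered away still renders the reference ring; rings whose targets all
fail to resolve are skipped with a warning; a ring stack too deep for the
disc (`ring_radii()`) is a configuration error suggesting thinner rings
rather than a silent overlap.

## What the fixtures emulate — and what they do not

The generators produce seeded, reproducible inputs: random genomes
(uniform chromosome lengths in a configurable range), gene indexes in
which every locus carries a symbol, an ENSEMBL-like and an ENTREZ-like
alias (so all three resolution branches are exercised), association sets
with weights drawn uniform on $[-1, 1]$ (emulating correlation edges),
optional explicit colors and phenotype endpoints at configurable
fractions, and a four-ring "correlation study" scenario with a
pathway-like gene subset for end-to-end runs. Defaults follow the study
conditions the package targets: a dense upload is exercised at 2500–50 000
edges against the 2000-curve default limit, oracle comparisons use
1000-edge sets, and layout properties are checked over 100 random genomes
— sizes chosen so the full suite runs in minutes on one CPU while still
covering the regimes that matter.

What passing these tests shows: the geometry, parsing, filtering,
bundling and export layers are exact under their stated contracts, for
any input those contracts admit. What it does not show: anything about
the biological plausibility of real association sets — real weights are
not uniform, real gene densities are not homogeneous along chromosomes,
and real label sets carry aliasing and versioning noise that a synthetic
index cannot reproduce. The fixtures validate the machine, not the data.

## Known limitations

* Gene-index lookups are exact (after case folding for symbols): no alias
  expansion, no fuzzy matching, no build liftover.
* The built-in human band track is arm-level; full cytoband resolution
  requires attaching a user-supplied table.
* Edge curves use a single control-point law; there is no per-edge
  curvature tuning or interactive hit-testing — the SIF export exists
  precisely to hand dense networks to dedicated network viewers.
* Composite label ambiguity is resolved by member order; files mixing many
  shared symbols across members should use explicit `prefix|` labels.
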