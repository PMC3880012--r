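# arcomics

Circular genome plots of omics association networks, as a headless R
library with a command-line front end.

Genome-wide analyses — expression/copy-number correlation, structural
rearrangement calls, protein–protein interaction screens, cross-species
ortholog mapping — produce *association sets*: lists of edges between pairs
of genomic features, optionally ranked by a weight such as a correlation or
p-value, or tagged with an explicit color. `arcomics` ingests such edge
lists from plain text, resolves heterogeneous node labels to genomic
coordinates, and draws the network in chromosomal context as a circular
(Circos-style) plot, alongside tabular and network-format exports.

The core model is simple: for an organism with chromosomes of lengths
$L_1, \dots, L_n$, each chromosome $i$ is drawn as a circumference arc of
angular span

$$\mathrm{span}_i = \left(360^\circ - n\,g\right) \frac{L_i}{\sum_j L_j},$$

where $g$ is a fixed inter-chromosome gap (default 1°), starting at 12
o'clock and running clockwise. A node at locus `chr:start:end` is anchored
at the linear interpolation of its midpoint within its chromosome's arc,
and each association becomes a quadratic chord between its two anchors.
Concentric annotation rings (bar, histogram, heatmap) pair values or colors
with genes or chromosome segments; phenotype (`^PHENO`) nodes, which have no
genomic position, are drawn as tick glyphs outside the reference ring at
their partner's anchor.

Key capabilities:

* **Label resolution** — node labels may freely mix gene symbols
  (case-insensitive), ENSEMBL/ENTREZ identifiers (verbatim), and positional
  `chr:start:end` labels (1-based, inclusive); unresolvable labels are
  reported, never fatal, unless nothing at all can be drawn.
* **Ten built-in references** — human, fly, mouse, worm, yeast, zebrafish,
  Arabidopsis, rice, tomato, *E. coli* — plus custom references from a
  two-column chromosome table and composite multi-organism circles
  (`prefix.chrom` namespacing, `prefix|label` lookup) for ortholog or
  strain-to-strain comparisons.
* **Four input dialects** — space (`.txt`), tab (`.tsv`), comma (`.csv`)
  edge lists with an optional trailing weight-or-color column, and SIF
  (`.sif`) extended with the same optional column.
* **Filtering on the full set** — weight operators `<, <=, >, >=, ==,
  abs>=, abs<=` and gene-label-set filters (any/both endpoint modes);
  rendering truncates to the first 2000 drawable curves by default, but
  filters always act on the complete association set first.
* **Edge bundling** — fixed genomic windows merge co-located edges into
  single curves with log-scaled widths, with an optional |weight| threshold
  that exempts strong edges.
* **Reproducible output** — SVG with no timestamps (identical inputs give
  byte-identical files), grid TSV/HTML, and TSV/SIF exports that re-import
  as identical sets.

## Worked example

```r
library(arcomics)

ref  <- fixture_reference(1, n_chrom = 3, n_genes = 50)   # seeded synthetic genome
recs <- parse_inline_edges(
  "G0001,G0002,0.95;G0003,chr2:100000:200000,-0.8;G0004,fatigue^PHENO")
set  <- resolve_set(recs, ref)
set
#> <assoc_set> 3 edges on reference 'fixture1'
#>   labels: 6 total, 5 mapped, 1 unmapped (1 phenotype)
glance(set)
#> # A tibble: 1 × 8
#>   total mapped unmapped pheno edges drawable_edges self_edges duplicate_edges
#> 1     6      5        1     1     3              3          0               0
```

Six distinct labels appear on the three edges; five resolve to loci and one
(`fatigue`) is a phenotype node, so all three edges are drawable: two as
chords, one as a glyph tick. Filtering keeps the strong correlation only:

```r
glance(filter_weight(set, "abs>=", 0.9))
#> # A tibble: 1 × 8
#>   total mapped unmapped pheno edges drawable_edges self_edges duplicate_edges
#> 1     2      2        0     0     1              1          0               0

export_svg(render_circular(set, ref), "network.svg")
render_grid(set)
#> # A tibble: 3 × 8
#>   labelA typeA locusA               labelB             typeB locusB weight color
#> 1 G0001  <NA>  chr3:242104:247446   G0002              <NA>  chr2:…   0.95 <NA>
#> 2 G0003  <NA>  chr2:754240:758096   chr2:100000:200000 <NA>  chr2:…  -0.8  <NA>
#> 3 G0004  <NA>  chr1:1335099:1341497 fatigue            PHENO unmap…  NA    <NA>
```

The grid view lists every edge with both resolved loci (`unmapped` where no
locus exists); its weight and label columns re-parse to the same set.

The same pipeline runs from a shell via the bundled script:

```sh
inst/cli/arcomics references --tsv
inst/cli/arcomics plot --organism human --associations edges.tsv \
    --weight-op "abs>=" --weight 0.92 --genes pathway.txt \
    --svg out.svg --grid out.grid.tsv
```

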