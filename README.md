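# circosviz

Circular visualization of genomic structural variants, for people who
have caller output and want a picture. `circosviz` converts the evidence
produced by paired-end / mate-pair sequencing pipelines — structural
variant link calls (SVDetect, Pindel), copy-number segments
(Control-FREEC), binned read coverage and half-mapped read pairs from
SAM/BAM, and gene annotation tables — into the complete plain-text file
set (karyotype, data tracks, configuration) consumed by the
[Circos](http://circos.ca) renderer, so that an interpretable image of
rearrangements takes a handful of calls rather than hand-written
configuration files. It is aimed at microbial / small-genome
resequencing analyses: find a rearrangement, zoom in, delineate its
borders.

## The model

The image architecture is fixed. Around a circular ideogram sit three
optional concentric rings — gene annotations (highlight style, Watson
strand grey, Crick dark green), read coverage (histogram of alignment
counts in windows of `win` = 10 kb), and copy-number status (heatmap:
copy number 0 light blue, 2 orange, ≥ 3 red on a light-yellow
baseline) — with links in the center. The circle splits into one or two
magnified **views** of a chromosome of interest (linear magnification
`ext_fraction`; only links with at least one foot in a view are drawn)
and a whole-genome part, ending with an optional **NM** ("No Match")
pseudo-chromosome.

Two computations are the core:

* **Link significance gradients.** Each SV type maps to a hue family;
  within a type, the shade for a link supported by $x$ read pairs is

  $$s = 1 + \left\lfloor \frac{x - x_{\min}}{x_{\max} - x_{\min} + 1}\, k \right\rfloor, \qquad k = 5,$$

  so darkness is non-decreasing in support — darker links are more
  significant.

* **NM clustering.** Read pairs with exactly one mapped mate (the
  signature of a foreign-DNA insertion) are anchored at the mapped
  mate's position, sorted, and clustered by single linkage with maximum
  gap `frag_size` (330 bp, the fragment length); every cluster of at
  least `threshold` (50) anchors becomes a red-gradient link from its
  genomic span to the NM arc, with support = cluster size.

## Worked example

The package ships a deterministic simulator, so a complete run needs no
external data:

```r
library(circosviz)

fx  <- simulate_fixture_set("demo", seed = 7)   # genome, SAM, caller files
kar <- append_nm(fx$karyotype)                  # add the NM pseudo-chromosome
kar
#> karyotype: 3 chromosome(s), 285,600 bp total
#>   id label length       color
#> 1 ec    ec 200000 102,102,102
#> 2 p1    p1  80000 204,102,102
#> 3 NM    NM   5600 150,150,150

# half-mapped pairs -> clustered, thresholded, red-gradient NM links
nm <- nm_paint(nm_adapt(fx$paths$sam), kar, frag_size = 330, threshold = 50)
as.data.frame(nm)
#>   chrA startA   endA chrB startB endB type support       color
#> 1   ec  59770  59998   NM      1 2800   NM      70     139,0,0
#> 2   ec 169773 169995   NM   2801 5600   NM      55 255,196,196

# SVDetect calls -> green/pink gradient links
links <- links_paint(svd_links_adapt(fx$paths$svdetect),
                     type_conv(c("TRANSLOC", "INV_TRANSLOC"), c(2, 4)))
as.data.frame(links)
#>   chrA startA  endA chrB startB   endB         type support      color
#> 1   ec  40000 40330   ec 150000 150330     TRANSLOC      40   11,90,11
#> 2   ec  90000 90330   p1  30000  30330 INV_TRANSLOC      25 199,21,133

cfg <- plot_config("ec", view1 = c(1, NA), ext_fraction = 5,
                   out_dir = "demo/circos")
chromosome_image(cfg, kar, links = links, nm = nm,
                 coverage = coverage_adapt(fx$paths$sam, karyotype = kar),
                 cnv   = cnv_paint(freec_cnv_adapt(fx$paths$freec)),
                 annot = annot_paint(tab_annot_adapt(fx$paths$annot,
                                                     column_map(1, 4, 5, 7, 3))))
list.files("demo/circos")
#>  [1] "annot.txt"     "circos.conf"   "cnv.txt"       "coverage.txt"
#>  [5] "ideogram.conf" "karyotype.txt" "links.txt"     "nm_links.txt"
#>  [9] "run.log"       "ticks.conf"
```

Reading the numbers: the simulator planted two foreign-insertion sites
with 70 and 55 supporting pairs (plus one with 10, correctly suppressed
by the threshold of 50) — they surface as the two NM links, the
70-support cluster in the darkest red (`139,0,0`). The planted
translocation (40 pairs, green family) and inverted translocation
(25 pairs, pink family) each appear once; being the only link of their
type, each takes its family's darkest shade. The emitted directory is
a complete Circos input set (`circos <path>/circos.conf` renders it if
Circos is installed); `run.log` records every argument and input. A
command-line surface mirroring these steps is available as
`exec/circosviz` (`circosviz --help`).

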