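---
title: "Composing Circos images of structural variation with circosviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing Circos images of structural variation with circosviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circosviz)
```

## The problem

Paired-end and mate-pair sequencing detect large genomic rearrangements
through read pairs that map to abnormal relative positions: mates on
different chromosomes or at unexpected distances signal translocations,
inversions and insertions, and pairs in which one mate maps nowhere on
the reference signal integration of foreign DNA. Caller outputs are flat
tables of such events, hard to interpret because each event joins two
loci that may be megabases apart. A circular ideogram solves this:
chromosomes become arcs, events become chords ("links"), and contextual
tracks (read coverage, copy-number status, gene annotations) become
concentric rings. The Circos renderer draws such images but demands a
large set of hand-written configuration and data files; `circosviz`
generates that complete file set programmatically from caller outputs,
within a deliberately fixed image architecture, so that producing an
interpretable image takes a handful of function calls rather than
configuration engineering.

## The image architecture

The architecture is fixed, not configurable, which is what keeps the
interface small:

* **Three optional concentric rings.** Outermost (0.90–0.98 of the
  ideogram radius), gene annotations in highlight style, Watson-strand
  features grey and Crick-strand features dark green. Middle
  (0.80–0.88r), read coverage as a dark-grey histogram of alignment
  counts in fixed-width windows. Innermost (0.70–0.78r), copy-number
  status as a heatmap: copy number 0 light blue, 2 orange, 3 or more
  red, on a light-yellow baseline. The ring *order* is part of the
  architecture; the radial band values are this package's choice since
  only the order is semantically meaningful.
* **Links in the center** (below 0.70r), thin lines of fixed thickness.
  Each SV type is assigned a hue family (green, blue, pink, ... — index
  1, red, is reserved for NM links) and within a type darkness encodes
  significance: shade $s$ for support $x$ is
  $s = 1 + \lfloor (x - x_{\min}) / (x_{\max} - x_{\min} + 1) \cdot k \rfloor$
  with $k = 5$ shades binned linearly over the observed support range.
  Darker links are supported by more read pairs. Five discrete shades
  are used because a continuous ramp is indistinguishable at line
  thickness 2; the degenerate all-equal case takes the darkest shade so
  a lone, unambiguous call is never drawn faintly.
* **Two circle parts.** One or two magnified "views" of a chromosome of
  interest occupy the first part of the circle; the second part shows
  every chromosome full length (the chromosome of interest appears
  there too, so views always have their genomic context), with the NM
  pseudo-chromosome last. Only links with at least one foot inside a
  view are displayed.
* **The NM pseudo-chromosome** ("No Match") is an artificial arc
  anchoring the second foot of half-mapped pair clusters. Its length
  carries no biology — it only needs arc to attach link feet — so it
  defaults to 2% of the genome length. Cluster feet are placed on it
  left to right in discovery order with equal widths; their positions
  are an indexing device, not coordinates.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `win` | 10000 | bp | coverage window width; alignments are counted by leftmost mapped position |
| `frag_size` | 330 | bp | sequencing fragment length; the maximum gap joining consecutive NM anchors into one cluster |
| `threshold` | 50 | read pairs | minimum cluster size for an NM link to be reported |
| `ext_fraction` | 10 | — | linear magnification applied to view regions when apportioning circumference |
| `flag_view_outer` | `TRUE` | — | when `FALSE`, the annotation ring is clipped to the view intervals |
| `gap_degrees` | 1 | degrees | gap at every segment boundary of the circular layout |

Three of these deserve justification because their published defaults
come without stated semantics:

* `frag_size` is read as a **maximum gap between consecutive anchors**
  (single-linkage), not a maximum cluster diameter. All mapped mates of
  one insertion site fall within one fragment length of the insertion
  point, so consecutive-gap clustering reconstructs the site exactly and
  stays linear-time after sorting; diameter clustering would split
  well-covered sites arbitrarily.
* `threshold` is read as a **display filter on cluster size**: a
  minimum number of supporting pairs for an NM link to be drawn. A
  threshold that did not change the displayed set would have no
  observable effect, so this is the only consistent reading. The color
  gradient is then computed over the supports that survive.
* `ext_fraction` is the **linear magnification** of view regions: a
  100 kb view at `ext_fraction = 5` consumes circumference as if it
  were 500 kb. Sweeps are displayed-length-proportional shares of
  360° minus one `gap_degrees` per boundary, so sweeps plus gaps close
  the circle exactly (verified to 1e-9° in the tests).

## Coordinate and format conventions

All coordinates are 1-based inclusive base pairs everywhere inside the
package — SAM's convention — and exactly one conversion exists: the
Circos karyotype line writes start 0, per Circos convention. The
`.circus` intermediate format is tab-delimited, headerless, UTF-8, LF:
links are `chrA startA endA chrB startB endB type support [color]`;
segments are `chr start end value [color]` for numeric tracks and
`chr start end strand label [color]` for annotations, the fourth column
(`+`, `-` or `.`) disambiguating on read. The format is fixed so that
emission is byte-deterministic and golden-file comparisons are exact.
Colors are emitted as literal `r,g,b` tokens from one palette table in
`R/paint.R`; those RGB values are this package's concrete choice for
the named colors of the architecture.

Coverage counts **reads by leftmost position**, not per-base depth: at
10 kb windows the two are visually indistinguishable, counting is
O(reads), and it yields the exact conservation property (window sums
equal the number of counted alignments: mapped, primary,
non-supplementary) that the tests pin. Secondary and supplementary
alignments are excluded from both coverage and NM extraction to avoid
double-counting pairs; an optional `min_mapq` filter defaults to 0.

## Adapters

Adapters are line-local — one record per data line, `#`-lines skipped,
no invented coordinates. The SVDetect column layout
(chrA, startA, endA, chrB, startB, endB, type, support) is declared and
remappable because field order differs across SVDetect versions. The
Pindel parser reads record header lines only (class D/TD/INV mapped to
DEL/DUP/INV, `ChrID`, the two `BP` breakpoints as two-base feet, the
first `Supports` count); per-read evidence lines are ignored. Annotation
tables are read through a user `column_map()` of (chr, start, end,
strand, label) indices since "GTF-like" files vary; strand tokens
outside `+`/`-` normalize to `.`.

## What the synthetic generator emulates — and what it does not

`simulate_pairs()` produces the evidence classes the pipeline consumes:
uniform background concordant pairs at a fixed fragment length (330 bp,
100 bp reads), discordant pairs joining the two loci of planted
(inverted) translocations, half-mapped pairs (correct SAM flags on both
mates) anchored within one fragment length of planted insertion sites,
and extra concordant pairs inside CNV gains. All randomness flows from
one explicit seed through a scoped RNG, so fixture files are
byte-stable and never touch the caller's random state. The default
demonstration fixture (`simulate_fixture_set()`) uses a 200 kb + 80 kb
two-replicon genome, 5,000 background pairs, insertion sites of 70 and
55 pairs and events of 40/25 supporting pairs — sizes chosen so a full
pipeline run takes seconds while every cluster sits well clear of, or
well under, the reporting threshold.

The generator does **not** emulate sequencing error, quality variation,
indel-containing alignments, GC coverage bias, or mapping ambiguity.
Passing tests therefore demonstrate that the bookkeeping — extraction,
clustering, filtering, layout, emission — is exact on clean evidence;
they do not demonstrate robustness of upstream variant callers, which
are outside this package's scope (it consumes their outputs).

## Numerical and degenerate-input choices

* Window partition: last window truncated at the chromosome end;
  zero-valued windows are emitted so windows always tile the chromosome.
* Clustering ties: anchors sorted by (chromosome, position); equal
  positions always join one cluster.
* Degenerate support range: darkest shade (see above).
* Empty inputs: empty record lists serialize to empty files and read
  back as empty lists; painting an empty set is a no-op.
* Views: an `NA` end resolves to the chromosome end; two views must
  share the chromosome of interest and must not overlap; a length-one
  layout segment maps its single position to its start angle.
* The emitted file set is validated as the last emission step by an
  internal cross-reference checker (every referenced chromosome exists,
  every coordinate within length) before the run log is written.

## Known limitations

The package writes Circos inputs; it does not run the renderer, so
errors only Circos would catch (font availability, housekeeping limits)
surface at render time. Multi-gigabyte SAM files are read into memory;
the intended scale is microbial genomes or targeted regions. BEDPE/VCF
adapters and Hi-C-style contact links would fit the link model but are
not implemented. The sizes quoted above (fixture genome, trial counts
of the randomized checks) are also the sizes exercised by the test
suite and acceptance script.
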